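#' Enumerate simplified direction-pattern labels
#'
#' A simplified pattern label has one field per consecutive time interval,
#' each `d` (down), `c` (constant) or `u` (up), joined by `-`; with four
#' intervals there are 3^4 = 81 possible labels. A restriction (e.g. a
#' curated subset of plausible patterns) is returned verbatim after
#' validation.
#'
#' @param restriction Optional character vector, a subset of the full
#'   enumeration to use instead.
#' @param n_intervals Number of consecutive-time-point intervals (default 4).
#' @return Character vector of labels in lexicographic order (or the
#'   restriction verbatim).
#' @examples
#' length(enumerate_labels())       # 81
#' enumerate_labels(n_intervals = 2)  # 9 labels
#' @export
enumerate_labels <- function(restriction = NULL, n_intervals = 4) {
  states <- c("c", "d", "u")
  grid <- do.call(expand.grid,
                  c(rep(list(states), n_intervals),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  full <- sort(apply(grid[, rev(seq_len(n_intervals)), drop = FALSE],
                     1, paste, collapse = "-"))
  if (is.null(restriction)) return(full)
  bad <- setdiff(restriction, full)
  if (length(bad))
    stop("malformed pattern label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  restriction
}

# label implied by a 5-point value vector (exact comparisons)
label_of_values <- function(v) {
  d <- diff(v)
  paste(ifelse(d > 0, "u", ifelse(d < 0, "d", "c")), collapse = "-")
}

#' Build theoretical model profiles
#'
#' For each simplified label, constructs one candidate 5-point intensity
#' profile per fold magnitude: starting at 1.0, an `u` step multiplies by
#' the fold, a `d` step divides by it, and a `c` step keeps the value (the
#' fold is uniform within a profile). Duplicate value vectors are removed
#' and the static all-equal profile is always included. With
#' `combinatorial = TRUE`, every combination of per-step folds is generated
#' instead.
#'
#' @param labels Simplified labels to cover (default: all 81).
#' @param magnitudes Fold magnitudes, each `> 1` (default 1.5, 2, 4, 8).
#' @param combinatorial Use the full per-step fold grid rather than one
#'   uniform fold per profile.
#' @return A `profile_set`: data.frame with `id`, `label`, value columns
#'   `v1..v5` and attribute `normalized` (profiles scaled to sum 1).
#' @examples
#' ps <- build_model_profiles("u-c-c-u", 2)
#' ps[ps$id != "static", paste0("v", 1:5)]  # 1 2 2 2 4
#' @export
build_model_profiles <- function(labels = enumerate_labels(),
                                 magnitudes = c(1.5, 2, 4, 8),
                                 combinatorial = FALSE) {
  labels <- enumerate_labels(labels)
  non_static <- setdiff(labels, "c-c-c-c")
  if (length(non_static) && (!length(magnitudes) || any(magnitudes <= 1)))
    stop("fold magnitudes must be a non-empty grid of values > 1",
         call. = FALSE)
  rows <- list()
  add <- function(id, label, v)
    rows[[length(rows) + 1L]] <<- c(list(id = id, label = label),
                                    as.list(v))
  for (lab in non_static) {
    steps <- strsplit(lab, "-", fixed = TRUE)[[1]]
    var_steps <- which(steps != "c")
    if (combinatorial && length(var_steps)) {
      grid <- do.call(expand.grid, rep(list(magnitudes), length(var_steps)))
      for (r in seq_len(nrow(grid))) {
        f <- rep(1, 4)
        f[var_steps] <- as.numeric(grid[r, ])
        v <- cumprod(c(1, ifelse(steps == "u", f, ifelse(steps == "d", 1 / f, 1))))
        add(paste0(lab, "_f", paste(signif(as.numeric(grid[r, ]), 6),
                                    collapse = "x")), lab, v)
      }
    } else {
      for (f0 in magnitudes) {
        v <- cumprod(c(1, ifelse(steps == "u", f0,
                                 ifelse(steps == "d", 1 / f0, 1))))
        add(paste0(lab, "_f", signif(f0, 6)), lab, v)
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r$id, label = r$label,
               v1 = r[[3]], v2 = r[[4]], v3 = r[[5]], v4 = r[[6]], v5 = r[[7]],
               stringsAsFactors = FALSE)))
  static <- data.frame(id = "static", label = "c-c-c-c",
                       v1 = 1, v2 = 1, v3 = 1, v4 = 1, v5 = 1,
                       stringsAsFactors = FALSE)
  df <- if (is.null(df)) static else rbind(static, df)
  vals <- as.matrix(df[paste0("v", 1:5)])
  dup <- duplicated(apply(vals, 1, paste, collapse = "\r"))
  df <- df[!dup, , drop = FALSE]
  as_profile_set(df)
}

as_profile_set <- function(df) {
  vals <- as.matrix(df[paste0("v", 1:5)])
  if (any(vals < 0)) stop("model profile values must be nonnegative",
                          call. = FALSE)
  # labels must match the sign structure of the values
  for (r in seq_len(nrow(df))) {
    if (label_of_values(vals[r, ]) != df$label[r])
      stop("model '", df$id[r], "' label does not match its value directions",
           call. = FALSE)
  }
  # deterministic order: label, then id (drives argmin tie-breaking)
  o <- order(df$label, df$id)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  vals <- as.matrix(df[paste0("v", 1:5)])
  norm <- vals / rowSums(vals)
  attr(df, "normalized") <- norm
  class(df) <- c("profile_set", "data.frame")
  df
}

#' Filter model profiles by dynamic range
#'
#' Retains profiles whose range spans at least `min_range_frac` of their
#' maximum, i.e. `(max - min) / max >= min_range_frac` (the alternative
#' `(max - min) / min` convention is available via `base = "min"`). The
#' static profile is always retained.
#'
#' @param profiles A `profile_set` from [build_model_profiles()].
#' @param min_range_frac Threshold in `(0, 1]` (default 0.5).
#' @param base Denominator convention, `"max"` (default) or `"min"`.
#' @return The filtered `profile_set`.
#' @export
filter_model_profiles <- function(profiles, min_range_frac = 0.5,
                                  base = c("max", "min")) {
  base <- match.arg(base)
  if (!is.numeric(min_range_frac) || min_range_frac <= 0 || min_range_frac > 1)
    stop("min_range_frac must be in (0, 1]", call. = FALSE)
  vals <- as.matrix(profiles[paste0("v", 1:5)])
  hi <- apply(vals, 1, max)
  lo <- apply(vals, 1, min)
  denom <- if (base == "max") hi else lo
  keep <- (hi - lo) / denom >= min_range_frac | profiles$id == "static" |
    hi == lo  # any all-equal profile is the static model
  as_profile_set(as.data.frame(profiles)[keep, , drop = FALSE])
}

#' Bhattacharyya distance between two probability vectors
#'
#' `-ln(sum_i sqrt(p_i q_i))`: zero iff the vectors are identical, symmetric,
#' and infinite when the supports are disjoint.
#'
#' @param p,q Nonnegative vectors of equal length, each summing to 1 within
#'   `1e-9` (normalization is the caller's duty).
#' @return The distance (nonnegative, possibly `Inf`).
#' @examples
#' bhattacharyya_distance(c(1, 0, 0, 0, 0), rep(0.2, 5))  # -log(sqrt(0.2))
#' @export
bhattacharyya_distance <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("p and q must be nonnegative and each sum to 1", call. = FALSE)
  bc <- sum(sqrt(p * q))
  if (bc <= 0) return(Inf)
  max(0, -log(min(bc, 1)))
}

#' Assign the nearest model profile to one time course
#'
#' Normalizes the 5-point profile to sum 1 and assigns the model with the
#' smallest Bhattacharyya distance; ties break to the lexicographically
#' smallest label, then smallest id. An all-zero profile is labeled
#' `"not detected"`.
#'
#' @param profile Numeric 5-vector of mean net riBAQ values (`>= 0`).
#' @param models A `profile_set`.
#' @return A list with `model_id`, `distance` and `label`.
#' @export
assign_pattern <- function(profile, models) {
  if (length(profile) != 5 || any(profile < 0))
    stop("profile must be a nonnegative 5-vector", call. = FALSE)
  if (!nrow(models)) stop("model set is empty", call. = FALSE)
  res <- classify_profile_rows(rbind(profile), models)
  list(model_id = res$model_id, distance = res$distance, label = res$label)
}

# vectorized nearest-model assignment for a proteins x 5 matrix
classify_profile_rows <- function(m, models) {
  norm_models <- attr(models, "normalized")
  rs <- rowSums(m)
  out <- data.frame(model_id = rep(NA_character_, nrow(m)),
                    distance = rep(NA_real_, nrow(m)),
                    label = rep("not detected", nrow(m)),
                    stringsAsFactors = FALSE)
  pos <- which(rs > 0)
  if (length(pos)) {
    P <- m[pos, , drop = FALSE] / rs[pos]
    # Bhattacharyya coefficient to every model in one product
    C <- sqrt(P) %*% t(sqrt(norm_models))
    best <- max.col(C, ties.method = "first")  # models ordered label, id
    bc <- C[cbind(seq_along(pos), best)]
    if (any(bc <= 0))
      warning("some profiles overlap no model profile (infinite distance)")
    out$model_id[pos] <- models$id[best]
    out$distance[pos] <- ifelse(bc > 0, pmax(0, -log(pmin(bc, 1))), Inf)
    out$label[pos] <- models$label[best]
  }
  out
}

#' Classify every protein's time course against the model profiles
#'
#' Averages replicates per protein, genotype and time point, normalizes each
#' profile and assigns the nearest model under the Bhattacharyya distance.
#'
#' @param ribaq Long net-riBAQ table from [quantify_ribaq()], or a named
#'   list of proteins x time matrices from [profile_matrix()].
#' @param models A `profile_set`; default: all 81 labels over folds
#'   1.5/2/4/8, range-filtered at 50%.
#' @return A `pattern_fit` object: a data.frame of assignments (`protein`,
#'   `genotype`, `model_id`, `distance`, `label`) with the model set and
#'   mean profiles attached; has `print`, `summary` and `plot` methods.
#' @export
classify_profiles <- function(ribaq,
                              models = filter_model_profiles(build_model_profiles())) {
  profs <- if (is.data.frame(ribaq)) profile_matrix(ribaq) else ribaq
  res <- list()
  for (g in names(profs)) {
    a <- classify_profile_rows(profs[[g]], models)
    a <- cbind(data.frame(protein = rownames(profs[[g]]), genotype = g,
                          stringsAsFactors = FALSE), a)
    res[[g]] <- a
  }
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  attr(out, "models") <- models
  attr(out, "profiles") <- profs
  class(out) <- c("pattern_fit", "data.frame")
  out
}

#' @export
print.pattern_fit <- function(x, ...) {
  cat(sprintf("Pattern assignments: %d proteins x %d genotype(s), %d models\n",
              length(unique(x$protein)), length(unique(x$genotype)),
              nrow(attr(x, "models"))))
  nd <- tapply(x$label == "not detected", x$genotype, sum)
  for (g in names(nd))
    cat(sprintf("  %s: %d not detected\n", g, nd[[g]]))
  invisible(x)
}

#' @export
summary.pattern_fit <- function(object, top = 10, ...) {
  out <- list()
  for (g in unique(object$genotype)) {
    tab <- sort(table(object$label[object$genotype == g]), decreasing = TRUE)
    out[[g]] <- utils::head(tab, top)
  }
  cat("Most populated simplified patterns per genotype:\n")
  for (g in names(out)) {
    cat("\n", g, ":\n", sep = "")
    print(out[[g]])
  }
  invisible(out)
}

#' @export
plot.pattern_fit <- function(x, top = 8, ...) {
  gens <- unique(x$genotype)
  op <- graphics::par(mfrow = c(1, length(gens)), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  for (g in gens) {
    tab <- sort(table(x$label[x$genotype == g]), decreasing = TRUE)
    graphics::barplot(utils::head(tab, top), las = 2, main = g,
                      ylab = "proteins", ...)
  }
  invisible(x)
}

#' Read / write a model-profile table
#'
#' Tab-separated exchange format with columns `id`, `v0`, `v1`, `v5`,
#' `v10`, `v30`, `label`, so an externally curated model set can be used
#' verbatim.
#'
#' @param profiles A `profile_set`.
#' @param path File path.
#' @return `read_model_profiles` returns a `profile_set`.
#' @export
write_model_profiles <- function(profiles, path) {
  df <- as.data.frame(profiles)
  out <- data.frame(id = df$id, v0 = df$v1, v1 = df$v2, v5 = df$v3,
                    v10 = df$v4, v30 = df$v5, label = df$label)
  write_tsv(out, path)
}

#' @rdname write_model_profiles
#' @export
read_model_profiles <- function(path) {
  d <- read_tsv(path)
  need <- c("id", "v0", "v1", "v5", "v10", "v30", "label")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("model-profile table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  as_profile_set(data.frame(id = d$id, label = d$label,
                            v1 = d$v0, v2 = d$v1, v3 = d$v5,
                            v4 = d$v10, v5 = d$v30,
                            stringsAsFactors = FALSE))
}
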