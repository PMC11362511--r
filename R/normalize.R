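#' Internal reference scaling (IRS) batch normalization
#'
#' Removes between-set batch effects without a shared bridge channel by
#' scaling each protein's channels so that its per-set totals agree with a
#' pseudo-reference. For each protein within one genotype's sets, the set
#' total `T_s` is the sum of the ten channel values, the pseudo-reference
#' `R` is the geometric mean of the positive `T_s`, and every channel of set
#' `s` is multiplied by `R / T_s`. Sets where the protein has zero total are
#' left untouched. The transform is idempotent: a second application yields
#' unit factors.
#'
#' @param matrix An [intensity_matrix()]; channels should be imputed or
#'   present for proteins passing the detection rule.
#' @param within `"genotype"` (default, sets of one genotype are scaled
#'   together) or `"global"`.
#' @return The normalized matrix, with the factor table (`protein`, `set`,
#'   `factor`, `pseudo_reference`) attached as attribute `irs_factors`.
#' @export
irs_normalize <- function(matrix, within = c("genotype", "global")) {
  within <- match.arg(within)
  x <- matrix$intensities
  d <- matrix$design
  groups <- if (within == "genotype") unique(d$genotype) else "all"
  fac_rows <- list()
  for (g in groups) {
    dg <- if (within == "genotype") d[d$genotype == g, ] else d
    sets <- unique(dg$set_id)
    if (length(sets) < 2) {
      warning("IRS needs at least 2 sets in group '", g,
              "'; returning identity transform")
      next
    }
    totals <- sapply(sets, function(s) {
      cols <- dg$sample_id[dg$set_id == s]
      rowSums(x[, cols, drop = FALSE], na.rm = TRUE)
    })
    lt <- log(totals)
    lt[!is.finite(lt)] <- NA
    npos <- rowSums(!is.na(lt))
    pseudo <- ifelse(npos > 0, exp(rowMeans(lt, na.rm = TRUE)), 0)
    for (si in seq_along(sets)) {
      s <- sets[si]
      f <- ifelse(totals[, si] > 0, pseudo / totals[, si], 1)
      cols <- dg$sample_id[dg$set_id == s]
      x[, cols] <- x[, cols, drop = FALSE] * f
      fac_rows[[length(fac_rows) + 1L]] <- data.frame(
        protein = rownames(x), set = s, factor = f,
        pseudo_reference = pseudo, stringsAsFactors = FALSE)
    }
  }
  matrix$intensities <- x
  attr(matrix, "irs_factors") <-
    if (length(fac_rows)) do.call(rbind, c(fac_rows, make.row.names = FALSE))
    else NULL
  matrix
}

#' Seeded chained-equations imputation of missing channel intensities
#'
#' Missing reporter entries (`NA`, and zeros treated as censored) are filled
#' by chained-equations imputation on log-intensities, each channel
#' regressed on the others. The regression has two parts. First, the
#' strongest predictors of a channel are the same reporter tag's channels in
#' the genotype's sibling replicate sets: a missing entry is predicted as
#' the mean over sibling sets of the protein's observed same-tag value plus
#' a per-protein set-to-set offset (the mean log difference over channels
#' observed in both sets), which absorbs batch factors. Entries with no
#' sibling donor are then filled by the secondary regressor — row-centered
#' k-nearest-neighbour (neighbours by Euclidean distance between
#' row-centered log profiles, imputing the target's row mean plus the mean
#' neighbour deviation) or linear least squares — sweeping channels until
#' convergence or `max_sweeps`. Entries exempted by the six-sample rule
#' ([condition_detection_rule()]) remain exactly zero and unflagged. The
#' procedure is deterministic given the seed.
#'
#' @param matrix An [intensity_matrix()] of raw (pre-scaling) intensities.
#' @param seed Integer seed.
#' @param method Secondary regressor: `"knn"` (default) or `"linear"`.
#' @param k Number of neighbours for the kNN regressor.
#' @param max_sweeps Maximum chained-equation sweeps (default 10).
#' @param tol Convergence tolerance on the maximum absolute change of
#'   imputed log-intensities between sweeps.
#' @return The matrix with missing entries filled and flagged in `$imputed`.
#' @export
impute_missing <- function(matrix, seed = 1L, method = c("knn", "linear"),
                           k = 10, max_sweeps = 10, tol = 1e-6) {
  method <- match.arg(method)
  set.seed(as.integer(seed))
  x <- matrix$intensities
  d <- matrix$design
  ex <- exemption_mask(matrix)
  x[ex & is.na(x)] <- 0  # exempt cells are structural zeros
  miss <- (is.na(x) | x == 0) & !ex
  if (!any(miss)) {
    matrix$intensities <- x
    return(matrix)
  }
  observed <- !miss & !ex & x > 0
  n_obs <- colSums(observed)
  if (any(n_obs == 0))
    stop("channel '", colnames(x)[which(n_obs == 0)[1]],
         "' has no observed values; cannot impute", call. = FALSE)

  L <- suppressWarnings(log(x))
  L[!observed] <- NA
  Lorig <- L

  # --- primary regressor: sibling replicate sets, same reporter tag ----
  for (g in unique(d$genotype)) {
    sets <- unique(d$set_id[d$genotype == g])
    if (length(sets) < 2) next
    cols_of <- lapply(sets, function(s) d$sample_id[d$set_id == s])
    names(cols_of) <- sets
    for (s in sets) {
      for (ci in seq_along(cols_of[[s]])) {
        j <- cols_of[[s]][ci]
        tgt <- which(miss[, j])
        if (!length(tgt)) next
        ests <- vapply(setdiff(sets, s), function(s2) {
          donor <- Lorig[tgt, cols_of[[s2]][ci]]
          A <- Lorig[tgt, cols_of[[s]], drop = FALSE]
          B <- Lorig[tgt, cols_of[[s2]], drop = FALSE]
          donor + rowMeans(A - B, na.rm = TRUE)
        }, numeric(length(tgt)))
        est <- rowMeans(matrix(ests, nrow = length(tgt)), na.rm = TRUE)
        fill <- is.finite(est)
        L[tgt[fill], j] <- est[fill]
      }
    }
  }

  # --- secondary regressor: chained sweeps over remaining entries ------
  rem <- miss & is.na(L)
  Lfill <- L
  for (j in seq_len(ncol(L))) {
    nas <- is.na(Lfill[, j])
    if (any(nas)) Lfill[nas, j] <- stats::median(Lorig[, j], na.rm = TRUE)
  }
  if (any(rem)) {
    for (sweep in seq_len(max_sweeps)) {
      delta <- 0
      rmean <- rowMeans(Lfill)
      Lc <- Lfill - rmean
      for (j in seq_len(ncol(L))) {
        tgt <- which(rem[, j])
        if (!length(tgt)) next
        donors <- which(observed[, j])
        old <- Lfill[tgt, j]
        if (method == "knn") {
          P <- Lc[tgt, -j, drop = FALSE]
          Q <- Lc[donors, -j, drop = FALSE]
          D2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
          kk <- min(k, length(donors))
          newv <- vapply(seq_along(tgt), function(i) {
            nb <- order(D2[i, ])[seq_len(kk)]
            rmean[tgt[i]] + mean(Lc[donors[nb], j])
          }, numeric(1))
        } else {
          X <- cbind(1, Lfill[donors, -j, drop = FALSE])
          cf <- qr.coef(qr(X), Lfill[donors, j])
          cf[is.na(cf)] <- 0
          newv <- as.vector(cbind(1, Lfill[tgt, -j, drop = FALSE]) %*% cf)
        }
        delta <- max(delta, max(abs(newv - old)))
        Lfill[tgt, j] <- newv
        Lc[tgt, j] <- newv - rmean[tgt]
      }
      if (delta < tol) break
    }
    L[rem] <- Lfill[rem]
  }

  x[miss] <- exp(L[miss])
  matrix$intensities <- x
  matrix$imputed <- matrix$imputed | miss
  matrix
}
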