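# proteinGroups-dialect TSV: "Reporter intensity corrected <k> <set>" columns
# (k = 0..9 in reporter mass order), per-set "iBAQ <set>" columns, and the
# three "+"/empty quality flags.

reporter_col <- function(k, set_id)
  sprintf("Reporter intensity corrected %d %s", k, set_id)

# case-insensitive column lookup with MaxQuant-version aliases
find_col <- function(cols, name,
                     aliases = c("Only identified by site" = "Only identified by site",
                                 "Potential contaminant" = "Contaminant")) {
  cand <- c(name, unname(aliases[name]))
  cand <- cand[!is.na(cand)]
  hit <- which(tolower(cols) %in% tolower(cand))
  if (length(hit)) hit[1] else NA_integer_
}

#' Write a synthetic dataset as a proteinGroups-dialect table
#'
#' @param matrix An [intensity_matrix()].
#' @param path Output TSV path.
#' @param gene_names Optional character vector of gene names.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(matrix, path, gene_names = NULL) {
  x <- matrix$intensities
  d <- matrix$design
  out <- data.frame(`Protein IDs` = rownames(x),
                    `Gene names` = if (is.null(gene_names)) rownames(x)
                                   else gene_names,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in unique(d$set_id)) {
    ds <- d[d$set_id == s, ]
    for (j in seq_len(nrow(ds))) {
      k <- match(ds$channel[j], TMT10_TAGS) - 1L
      out[[reporter_col(k, s)]] <- num_chr(x[, ds$sample_id[j]])
    }
    out[[paste("iBAQ", s)]] <- num_chr(matrix$ibaq[, s])
  }
  out[["Reverse"]] <- ""
  out[["Potential contaminant"]] <- ""
  out[["Only identified by site"]] <- ""
  write_tsv(out, path)
}

#' Read a proteinGroups-dialect table against a channel design
#'
#' Parses a MaxQuant-style tab-separated protein groups table. Reporter
#' columns are resolved case-insensitively by the design's channel tags
#' (reporter index 0..9 in mass order) and set ids; empty intensity cells
#' are read as missing, zeros as zero. Unknown columns are preserved in the
#' returned table.
#'
#' @param path Input TSV path.
#' @param design Channel design ([channel_design()]).
#' @return A list with `table` (the parsed data.frame, flag columns
#'   normalized) and `matrix` (an [intensity_matrix()]).
#' @export
read_protein_groups <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_design(design)
  tab <- read_tsv(path)
  cols <- names(tab)
  idc <- find_col(cols, "Protein IDs")
  if (is.na(idc)) stop("missing required column 'Protein IDs'", call. = FALSE)
  proteins <- as.character(tab[[idc]])

  sets <- unique(design$set_id)
  x <- matrix(NA_real_, length(proteins), nrow(design),
              dimnames = list(proteins, design$sample_id))
  ibaq <- matrix(NA_real_, length(proteins), length(sets),
                 dimnames = list(proteins, sets))
  has_global_ibaq <- FALSE
  for (s in sets) {
    ds <- design[design$set_id == s, ]
    for (j in seq_len(nrow(ds))) {
      k <- match(ds$channel[j], TMT10_TAGS) - 1L
      if (is.na(k + 1))
        stop("unresolvable channel tag '", ds$channel[j], "'", call. = FALSE)
      cc <- find_col(cols, reporter_col(k, s))
      if (is.na(cc))
        stop("missing required column '", reporter_col(k, s), "'",
             call. = FALSE)
      x[, ds$sample_id[j]] <- as.numeric(tab[[cc]])
    }
    ic <- find_col(cols, paste("iBAQ", s))
    if (is.na(ic)) {
      ic <- find_col(cols, "iBAQ")
      if (is.na(ic))
        stop("missing required column 'iBAQ ", s, "'", call. = FALSE)
      has_global_ibaq <- TRUE
    }
    ibaq[, s] <- as.numeric(tab[[ic]])
  }
  if (has_global_ibaq)
    warning("single global iBAQ column reused across all sets")
  if (any(x[!is.na(x)] < 0))
    stop("negative reporter intensities in ", path, call. = FALSE)
  for (fl in c("Reverse", "Potential contaminant", "Only identified by site")) {
    fc <- find_col(cols, fl)
    tab[[fl]] <- if (is.na(fc)) "" else {
      v <- as.character(tab[[fc]]); v[is.na(v)] <- ""; v
    }
    bad <- !tab[[fl]] %in% c("", "+")
    if (any(bad))
      stop("flag column '", fl, "' contains values other than '+' or empty",
           call. = FALSE)
  }
  ibaq[is.na(ibaq)] <- 0
  list(table = tab, matrix = intensity_matrix(x, ibaq, design))
}

#' Filter a protein groups table
#'
#' Drops reverse hits, potential contaminants and groups only identified by
#' site (any `+` flag), then proteins whose every reporter intensity across
#' all samples is zero or missing. The counts dropped per rule are attached
#' as attribute `dropped` and reported via `message`.
#'
#' @param table Parsed protein groups data.frame (from
#'   [read_protein_groups()]`$table`).
#' @return The filtered data.frame.
#' @export
filter_protein_groups <- function(table) {
  flags <- c("Reverse", "Potential contaminant", "Only identified by site")
  miss <- setdiff(flags, names(table))
  if (length(miss))
    stop("flag column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  flagged <- Reduce(`|`, lapply(flags, function(f) table[[f]] == "+"))
  dropped <- vapply(flags, function(f) sum(table[[f]] == "+"), integer(1))
  out <- table[!flagged, , drop = FALSE]
  rcols <- grep("^Reporter intensity corrected ", names(out),
                ignore.case = TRUE)
  if (length(rcols)) {
    xm <- as.matrix(as.data.frame(lapply(out[rcols], as.numeric)))
    all_zero <- rowSums(!is.na(xm) & xm > 0) == 0
  } else all_zero <- rep(FALSE, nrow(out))
  n_zero <- sum(all_zero)
  out <- out[!all_zero, , drop = FALSE]
  message(sprintf(
    "filter_protein_groups: dropped %d flagged (%s), %d all-zero; %d remain",
    sum(flagged), paste(sprintf("%s=%d", c("reverse", "contaminant", "by-site"),
                                dropped), collapse = ", "),
    n_zero, nrow(out)))
  attr(out, "dropped") <- c(flagged = sum(flagged), all_zero = n_zero,
                            stats::setNames(dropped, c("reverse", "contaminant",
                                                       "only_by_site")))
  rownames(out) <- NULL
  out
}

#' Write the simulator's ground truth as TSV
#'
#' @param sim A `surftime_sim` from [generate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  tr <- sim$truth
  tps <- sim$config$time_points
  rows <- list()
  for (g in colnames(tr$labels)) {
    df <- data.frame(protein_id = rownames(tr$labels), genotype = g,
                     true_label = tr$labels[, g], stringsAsFactors = FALSE)
    fm <- tr$folds[, g, ]
    colnames(fm) <- paste0("fold_", tps)
    df <- cbind(df, fm)
    df$membrane <- tr$membrane
    df$absent <- tr$absent[, g]
    df$de <- tr$de
    rows[[g]] <- df
  }
  write_tsv(do.call(rbind, c(rows, make.row.names = FALSE)), path)
}
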