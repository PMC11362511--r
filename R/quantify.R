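#' Protein x channel intensity container
#'
#' Lightweight container for TMT reporter intensities: a proteins-by-channels
#' matrix (columns keyed by `"<set_id>.<channel>"`), a per-protein per-set
#' iBAQ matrix, the channel design, and logical matrices flagging imputed
#' entries. Missing observations are `NA`; MaxQuant-style reporter zeros are
#' treated as censored (missing) by the imputation step except where the
#' six-sample detection rule exempts them.
#'
#' @param intensities Numeric matrix, proteins x channels, values `>= 0` or
#'   `NA`; column names must match `design$sample_id`.
#' @param ibaq Numeric matrix, proteins x sets, values `>= 0`; column names
#'   must match the design's `set_id`s.
#' @param design Channel design from [channel_design()] or [read_design()].
#' @param imputed Optional logical matrix of imputed entries.
#' @return A list of class `intensity_matrix`.
#' @export
intensity_matrix <- function(intensities, ibaq, design, imputed = NULL) {
  validate_design(design)
  if (!all(colnames(intensities) == design$sample_id))
    stop("intensity columns do not match design sample ids", call. = FALSE)
  sets <- unique(design$set_id)
  if (!all(sets %in% colnames(ibaq)))
    stop("ibaq columns do not cover all design sets", call. = FALSE)
  obs <- intensities[!is.na(intensities)]
  if (any(obs < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (any(ibaq[!is.na(ibaq)] < 0)) stop("iBAQ must be nonnegative", call. = FALSE)
  if (is.null(imputed))
    imputed <- matrix(FALSE, nrow(intensities), ncol(intensities),
                      dimnames = dimnames(intensities))
  structure(list(intensities = intensities, ibaq = ibaq, design = design,
                 imputed = imputed), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d channels (%d sets)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$design$set_id))))
  cat(sprintf("  missing: %d, imputed: %d\n",
              sum(is.na(x$intensities)), sum(x$imputed)))
  invisible(x)
}

#' riBAQ-TMT scaling of one channel vector
#'
#' Rescales the ten reporter intensities of one protein in one TMT set so
#' that their sum equals the protein's iBAQ value in that set, converting
#' reporter ion intensities into absolute-scale riBAQ-TMT abundances.
#'
#' @param channels Numeric 10-vector of nonnegative reporter intensities
#'   (`NA` allowed; the scaling then conserves the iBAQ over the observed
#'   channels).
#' @param ibaq Nonnegative iBAQ value for the protein in this set.
#' @return Scaled 10-vector summing to `ibaq`, or all-`NA` when the channel
#'   sum is zero but `ibaq > 0` (the protein is not quantifiable in the set).
#' @examples
#' compute_ribaq_tmt(rep(1, 10), 100)  # rep(10, 10)
#' @export
compute_ribaq_tmt <- function(channels, ibaq) {
  if (length(channels) != 10)
    stop("expected 10 channel intensities", call. = FALSE)
  if (any(channels[!is.na(channels)] < 0) || is.na(ibaq) || ibaq < 0)
    stop("channels and ibaq must be nonnegative", call. = FALSE)
  s <- sum(channels, na.rm = TRUE)
  if (s == 0) {
    if (ibaq > 0) return(rep(NA_real_, 10))  # not quantifiable in this set
    return(channels)
  }
  channels * (ibaq / s)
}

#' Apply riBAQ-TMT scaling to every protein and set
#'
#' @param matrix An [intensity_matrix()].
#' @return The matrix with each protein's channels rescaled per set so that
#'   the (observed) channel sum equals the per-set iBAQ.
#' @export
apply_ribaq_scaling <- function(matrix) {
  x <- matrix$intensities
  for (s in unique(matrix$design$set_id)) {
    cols <- matrix$design$sample_id[matrix$design$set_id == s]
    xs <- x[, cols, drop = FALSE]
    rs <- rowSums(xs, na.rm = TRUE)
    ib <- matrix$ibaq[, s]
    f <- ifelse(rs > 0, ib / rs, 1)
    xs <- xs * f
    xs[rs == 0 & ib > 0, ] <- NA_real_
    x[, cols] <- xs
  }
  matrix$intensities <- x
  matrix
}

#' Per-channel mole-fraction normalization
#'
#' Divides each channel column by its column total so values are relative
#' riBAQ mole fractions summing to 1 within each channel.
#'
#' @param matrix An [intensity_matrix()] with riBAQ-TMT scaling applied.
#' @return The matrix with each column summing to 1.
#' @export
to_relative_ribaq <- function(matrix) {
  x <- matrix$intensities
  tot <- colSums(x, na.rm = TRUE)
  zero <- which(tot == 0)
  if (length(zero))
    stop("channel '", colnames(x)[zero[1]], "' has zero total intensity",
         call. = FALSE)
  matrix$intensities <- sweep(x, 2, tot, "/")
  matrix
}

#' Control-channel subtraction with the detection rule
#'
#' Subtracts the non-labeled control intensity from the paired labeled
#' intensity. A resulting zero or negative net intensity means the protein
#' is not detected in that sample; the net is then reported as 0.
#'
#' @param labeled,control Nonnegative numeric vectors (recycled pairwise).
#' @return A list with `net` (nonnegative, 0 where undetected) and
#'   `detected` (logical, `net > 0`).
#' @examples
#' subtract_control(2.5, 1.0)  # net 1.5, detected
#' subtract_control(1.0, 1.0)  # net 0, not detected
#' @export
subtract_control <- function(labeled, control) {
  if (any(labeled[!is.na(labeled)] < 0) || any(control[!is.na(control)] < 0))
    stop("labeled and control intensities must be nonnegative", call. = FALSE)
  net <- labeled - control
  detected <- !is.na(net) & net > 0
  net[!detected] <- 0
  list(net = net, detected = detected)
}

#' Six-sample condition detection rule
#'
#' A protein counts as absent in a condition (one genotype at one time
#' point) when none of the six samples of that condition — three labeled and
#' three control channels — has signal. Absent conditions are exempt from
#' imputation and their intensities stay zero.
#'
#' @param values Numeric vector of the six per-condition intensities
#'   (possibly `NA`).
#' @return `FALSE` iff all six values are missing or zero, else `TRUE`.
#' @export
condition_detection_rule <- function(values) {
  if (length(values) != 6)
    stop("expected exactly six per-condition intensities (3 labeled + 3 controls)",
         call. = FALSE)
  any(!is.na(values) & values > 0)
}

# logical matrix of cells exempted by the six-sample rule, per condition
exemption_mask <- function(matrix) {
  x <- matrix$intensities
  d <- matrix$design
  ex <- base::matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  for (g in unique(d$genotype)) {
    for (t in unique(d$time_min)) {
      cols <- d$sample_id[d$genotype == g & d$time_min == t]
      xs <- x[, cols, drop = FALSE]
      if (ncol(xs) != 6) next  # rule defined for triplicate designs
      absent <- rowSums(!is.na(xs) & xs > 0) == 0
      ex[absent, cols] <- TRUE
    }
  }
  ex
}

#' Quantify net riBAQ time courses
#'
#' Full channel-level quantitation: six-sample detection-rule exemptions and
#' seeded imputation of missing reporter entries, riBAQ-TMT scaling, IRS
#' batch normalization within genotype, optional per-channel mole-fraction
#' normalization, and finally control subtraction with the zero/negative
#' detection clamp. Imputation runs before scaling because the scaling
#' factor `iBAQ / sum(observed channels)` would otherwise inflate the
#' observed channels of incomplete proteins.
#'
#' @param matrix An [intensity_matrix()] of raw reporter intensities.
#' @param impute Impute missing channel entries (default `TRUE`).
#' @param irs Apply IRS batch normalization (default `TRUE`).
#' @param relative Apply [to_relative_ribaq()] before subtraction (default
#'   `FALSE`; column normalization rescales time points by different factors
#'   and distorts per-protein time-course shapes).
#' @param seed Integer seed forwarded to the imputation.
#' @param ... Passed on to [impute_missing()].
#' @return A long-format `data.frame` with one row per (protein, genotype,
#'   replicate, time point): columns `protein`, `genotype`, `replicate`,
#'   `time_min`, `net_ribaq`, `detected`, `imputed`. The IRS factor table
#'   and the imputation flag matrix are attached as attributes
#'   `irs_factors` and `imputed`.
#' @export
quantify_ribaq <- function(matrix, impute = TRUE, irs = TRUE,
                           relative = FALSE, seed = 1L, ...) {
  mat <- matrix
  if (impute) mat <- impute_missing(mat, seed = seed, ...)
  mat <- apply_ribaq_scaling(mat)
  irs_factors <- NULL
  if (irs) {
    mat <- irs_normalize(mat)
    irs_factors <- attr(mat, "irs_factors")
  }
  if (relative) mat <- to_relative_ribaq(mat)
  d <- mat$design
  x <- mat$intensities
  x[is.na(x)] <- 0  # unimputed missing values carry no signal
  lab <- d[d$labeled, ]
  ctl <- d[!d$labeled, ]
  key <- function(dd) paste(dd$set_id, dd$time_min)
  ctl <- ctl[match(key(lab), key(ctl)), ]
  sub <- subtract_control(as.vector(x[, lab$sample_id]),
                          as.vector(x[, ctl$sample_id]))
  imp <- mat$imputed[, lab$sample_id, drop = FALSE] |
    mat$imputed[, ctl$sample_id, drop = FALSE]
  np <- nrow(x)
  out <- data.frame(
    protein = rep(rownames(x), times = nrow(lab)),
    genotype = rep(lab$genotype, each = np),
    replicate = rep(lab$replicate, each = np),
    time_min = rep(lab$time_min, each = np),
    net_ribaq = sub$net,
    detected = sub$detected,
    imputed = as.vector(imp),
    stringsAsFactors = FALSE
  )
  attr(out, "irs_factors") <- irs_factors
  attr(out, "imputed") <- mat$imputed
  out
}

#' Average replicate time-course profiles
#'
#' Collapses a long net-riBAQ table to one 5-point profile per protein and
#' genotype by averaging replicates; undetected time points contribute 0.
#'
#' @param ribaq Long table from [quantify_ribaq()].
#' @return Named list (one matrix per genotype) of proteins x time-point
#'   mean net riBAQ.
#' @export
profile_matrix <- function(ribaq) {
  out <- list()
  tps <- sort(unique(ribaq$time_min))
  for (g in unique(ribaq$genotype)) {
    r <- ribaq[ribaq$genotype == g, ]
    m <- tapply(r$net_ribaq, list(r$protein, r$time_min), mean)
    m <- m[, as.character(tps), drop = FALSE]
    m[is.na(m)] <- 0
    out[[g]] <- m
  }
  out
}
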