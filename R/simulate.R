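#' Configuration for the synthetic time-course dataset generator
#'
#' Describes a two-genotype TMT10plex surfaceome time-course design with
#' known ground truth. Defaults emulate the study conditions: two genotypes
#' with three replicate sets each, five time points (0, 1, 5, 10, 30 min)
#' per set with paired labeled/control channels, log-normal protein
#' abundances (log10 mean 6, sd 1), a control (non-labeled) background at a
#' fixed 1/2.5 fraction of baseline, per-set multiplicative batch factors,
#' and mixed random plus intensity-dependent missingness.
#'
#' @param n_proteins Number of simulated proteins (excluding the optional
#'   spiked enzyme).
#' @param genotypes Genotype names; the second genotype hosts the truly
#'   absent (knocked-out) proteins and the differential resting-state fold
#'   changes.
#' @param sets_per_genotype Replicate TMT sets per genotype.
#' @param time_points Five strictly increasing stimulation times (minutes);
#'   the first is the resting state.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise applied per channel.
#' @param batch_sigma Standard deviation (log scale) of the per-set batch
#'   factor.
#' @param labeled_control_ratio Expected labeled:control intensity ratio of
#'   the spiked enzyme-like background protein; ordinary proteins receive a
#'   control background equal to `baseline / labeled_control_ratio`.
#' @param pattern_weights Named probability vector over simplified
#'   direction-pattern labels (shared by all genotypes), or a named list of
#'   such vectors keyed by genotype. Must sum to 1 per genotype.
#' @param fold_range Length-2 vector, minimum and maximum per-step fold
#'   magnitude for non-constant steps; min must exceed 1. One fold is drawn
#'   per protein and genotype and applied uniformly to its non-constant
#'   steps.
#' @param missing_rate_mcar Probability that any channel entry is missing
#'   completely at random.
#' @param missing_intensity_alpha Strength in `[0, 1]` of the
#'   intensity-dependent missingness component (logistic in standardized
#'   log-intensity; lower intensity means higher missingness).
#' @param membrane_fraction Fraction of proteins flagged as membrane.
#' @param absent_fraction Fraction of proteins truly absent (no specific
#'   labeling signal) in the second genotype.
#' @param de_fraction Fraction of proteins with a true resting-state
#'   abundance difference between genotypes.
#' @param de_fold Magnitude of that true fold difference.
#' @param include_spike Add a spiked enzyme-like protein whose labeled
#'   signal is pure background at `labeled_control_ratio` times the control.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_dataset()], [inject_missingness()]
#' @export
sim_config <- function(n_proteins = 1000,
                       genotypes = c("WT", "KO"),
                       sets_per_genotype = 3,
                       time_points = c(0, 1, 5, 10, 30),
                       noise_cv = 0.1,
                       batch_sigma = 0.2,
                       labeled_control_ratio = 2.5,
                       pattern_weights = default_pattern_weights(),
                       fold_range = c(2, 4),
                       missing_rate_mcar = 0.02,
                       missing_intensity_alpha = 0.2,
                       membrane_fraction = 0.13,
                       absent_fraction = 0.01,
                       de_fraction = 0,
                       de_fold = 4,
                       include_spike = TRUE,
                       seed = 1L) {
  cfg <- list(n_proteins = n_proteins, genotypes = genotypes,
              sets_per_genotype = sets_per_genotype,
              time_points = time_points, noise_cv = noise_cv,
              batch_sigma = batch_sigma,
              labeled_control_ratio = labeled_control_ratio,
              pattern_weights = pattern_weights, fold_range = fold_range,
              missing_rate_mcar = missing_rate_mcar,
              missing_intensity_alpha = missing_intensity_alpha,
              membrane_fraction = membrane_fraction,
              absent_fraction = absent_fraction,
              de_fraction = de_fraction, de_fold = de_fold,
              include_spike = isTRUE(include_spike),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default pattern-label weights for the simulator
#'
#' A realistic mixture dominated by the static pattern, with the dynamic
#' patterns prominent in the surfaceome time-course study (early-up,
#' late-up, down-then-recover families).
#'
#' @return Named numeric vector summing to 1 over simplified labels.
#' @export
default_pattern_weights <- function() {
  c("c-c-c-c" = 0.40, "u-c-c-u" = 0.12, "c-c-c-u" = 0.12,
    "d-u-u-u" = 0.12, "d-d-d-u" = 0.10, "c-c-u-u" = 0.06,
    "u-d-d-d" = 0.04, "d-d-u-u" = 0.04)
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_proteins))
    stop_field("n_proteins", "must be a positive integer")
  if (length(cfg$genotypes) < 1 || anyDuplicated(cfg$genotypes))
    stop_field("genotypes", "must be non-empty and unique")
  if (!is_count(cfg$sets_per_genotype))
    stop_field("sets_per_genotype", "must be a positive integer")
  if (length(cfg$time_points) != 5 || any(diff(cfg$time_points) <= 0))
    stop_field("time_points", "must be five strictly increasing minutes")
  if (!is.numeric(cfg$noise_cv) || cfg$noise_cv < 0)
    stop_field("noise_cv", "must be >= 0")
  if (!is.numeric(cfg$batch_sigma) || cfg$batch_sigma < 0)
    stop_field("batch_sigma", "must be >= 0")
  if (!is.numeric(cfg$labeled_control_ratio) || cfg$labeled_control_ratio <= 1)
    stop_field("labeled_control_ratio", "must be > 1")
  pw <- cfg$pattern_weights
  if (!is.list(pw)) pw <- stats::setNames(rep(list(pw), length(cfg$genotypes)),
                                          cfg$genotypes)
  for (g in cfg$genotypes) {
    w <- pw[[g]]
    if (is.null(w) || is.null(names(w)) || any(w < 0) || any(w > 1) ||
        abs(sum(w) - 1) > 1e-8)
      stop_field("pattern_weights",
                 sprintf("must be named probabilities in [0,1] summing to 1 for genotype '%s'", g))
    bad <- setdiff(names(w), enumerate_labels())
    if (length(bad))
      stop_field("pattern_weights",
                 paste("contains malformed label(s):", paste(bad, collapse = ", ")))
  }
  if (length(cfg$fold_range) != 2 || cfg$fold_range[1] <= 1 ||
      cfg$fold_range[2] < cfg$fold_range[1])
    stop_field("fold_range", "must be c(min, max) with min > 1")
  for (f in c("missing_rate_mcar", "missing_intensity_alpha",
              "membrane_fraction", "absent_fraction", "de_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop_field(f, "must be a probability in [0, 1]")
  }
  if (!is.numeric(cfg$de_fold) || cfg$de_fold <= 1)
    stop_field("de_fold", "must be > 1")
  if (!is_count(abs(cfg$seed) + 1))
    stop_field("seed", "must be an integer")
  invisible(cfg)
}

# per-genotype weight lookup
pattern_weights_for <- function(cfg, genotype) {
  pw <- cfg$pattern_weights
  if (is.list(pw)) pw[[genotype]] else pw
}

# fold profile (length 5, starting at 1) implied by a simplified label
fold_profile <- function(label, fold) {
  steps <- strsplit(label, "-", fixed = TRUE)[[1]]
  v <- 1
  out <- numeric(5)
  out[1] <- v
  for (k in 1:4) {
    v <- switch(steps[k], u = v * fold, d = v / fold, c = v)
    out[k + 1] <- v
  }
  out
}

#' Generate a synthetic TMT time-course dataset with ground truth
#'
#' Simulates per-channel reporter intensities for every (genotype,
#' replicate) TMT set. For ordinary proteins the labeled channel at time
#' `t` is `baseline * fold(t) * batch * noise + background * batch * noise`
#' and the paired control channel is `background * batch * noise`, with
#' `background = baseline / labeled_control_ratio`. Truly absent proteins
#' carry only background in their labeled channels; the optional spiked
#' enzyme-like protein carries `labeled_control_ratio * background`, so its
#' labeled:control ratio is the configured ratio at every time point. The
#' per-set iBAQ of each protein is the exact sum of its ten channel
#' intensities before missingness.
#'
#' @param config A [sim_config()].
#' @return A list of class `surftime_sim` with elements
#'   \describe{
#'     \item{matrix}{an [intensity_matrix()] (missingness already injected
#'       when the config requests it)}
#'     \item{design}{the channel design table}
#'     \item{truth}{ground truth: baselines, backgrounds, per-genotype true
#'       labels and fold profiles, per-set batch factors, annotation flags,
#'       absent/DE masks, the spike id, and the complete pre-missingness
#'       intensities (`original`)}
#'   }
#' @examples
#' sim <- generate_dataset(sim_config(n_proteins = 50, seed = 7))
#' dim(sim$matrix$intensities)
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  design <- channel_design(config$genotypes, config$sets_per_genotype,
                           config$time_points)
  n <- config$n_proteins
  proteins <- sprintf("P%05d", seq_len(n))
  if (config$include_spike) proteins <- c(proteins, "SPIKE_ENZYME")
  np <- length(proteins)
  spike <- if (config$include_spike) np else 0L

  baseline <- 10^stats::rnorm(np, mean = 6, sd = 1)
  background <- baseline / config$labeled_control_ratio

  G <- length(config$genotypes)
  labels <- matrix("", np, G, dimnames = list(proteins, config$genotypes))
  folds <- array(1, c(np, G, 5),
                 dimnames = list(proteins, config$genotypes, NULL))
  absent <- matrix(FALSE, np, G, dimnames = list(proteins, config$genotypes))
  for (gi in seq_len(G)) {
    g <- config$genotypes[gi]
    w <- pattern_weights_for(config, g)
    labels[, gi] <- sample(names(w), np, replace = TRUE, prob = w)
    # per-profile fold magnitudes are drawn from the canonical model grid
    # restricted to fold_range, so that a noiseless time course always has
    # an exactly matching theoretical model; a range containing no grid
    # value falls back to continuous uniform draws
    grid <- c(1.5, 2, 4, 8)
    grid <- grid[grid >= config$fold_range[1] & grid <= config$fold_range[2]]
    fmag <- if (length(grid))
      grid[sample.int(length(grid), np, replace = TRUE)]
    else stats::runif(np, config$fold_range[1], config$fold_range[2])
    for (i in seq_len(np))
      folds[i, gi, ] <- fold_profile(labels[i, gi], fmag[i])
  }
  # truly absent proteins in the second genotype (e.g. the knocked-out gene)
  n_absent <- floor(config$absent_fraction * n)
  if (G >= 2 && n_absent > 0) {
    idx <- sample(seq_len(n), n_absent)
    absent[idx, 2] <- TRUE
    labels[idx, 2] <- "not detected"
    folds[idx, 2, ] <- 1
  }
  # true resting-state fold differences in the second genotype
  de <- rep(FALSE, np)
  de_sign <- rep(0L, np)
  n_de <- floor(config$de_fraction * n)
  if (G >= 2 && n_de > 0) {
    cand <- setdiff(seq_len(n), which(absent[, 2]))
    idx <- sample(cand, min(n_de, length(cand)))
    de[idx] <- TRUE
    de_sign[idx] <- sample(c(-1L, 1L), length(idx), replace = TRUE)
  }
  if (spike) {
    labels[spike, ] <- "c-c-c-c"
    folds[spike, , ] <- 1
  }
  membrane <- stats::runif(np) < config$membrane_fraction
  if (spike) membrane[spike] <- FALSE

  sets <- unique(design$set_id)
  batch <- exp(stats::rnorm(length(sets), 0, config$batch_sigma))
  names(batch) <- sets
  sdlog <- cv_to_sdlog(config$noise_cv)

  x <- matrix(0, np, nrow(design),
              dimnames = list(proteins, design$sample_id))
  ibaq <- matrix(0, np, length(sets), dimnames = list(proteins, sets))
  for (s in sets) {
    ds <- design[design$set_id == s, ]
    gi <- match(ds$genotype[1], config$genotypes)
    b_eff <- baseline
    if (gi == 2) {
      up <- de & de_sign > 0
      dn <- de & de_sign < 0
      b_eff[up] <- b_eff[up] * config$de_fold
      b_eff[dn] <- b_eff[dn] / config$de_fold
    }
    for (j in seq_len(nrow(ds))) {
      col <- ds$sample_id[j]
      t_idx <- match(ds$time_min[j], config$time_points)
      noise <- if (sdlog > 0)
        exp(stats::rnorm(np, -sdlog^2 / 2, sdlog)) else rep(1, np)
      if (ds$labeled[j]) {
        signal <- b_eff * folds[, gi, t_idx] + background
        signal[absent[, gi]] <- background[absent[, gi]]
        if (spike)
          signal[spike] <- config$labeled_control_ratio * background[spike]
        x[, col] <- signal * batch[s] * noise
      } else {
        x[, col] <- background * batch[s] * noise
      }
    }
    ibaq[, s] <- rowSums(x[, ds$sample_id, drop = FALSE])
  }

  mat <- intensity_matrix(x, ibaq, design)
  truth <- list(baseline = stats::setNames(baseline, proteins),
                background = stats::setNames(background, proteins),
                labels = labels, folds = folds, batch = batch,
                absent = absent, membrane = stats::setNames(membrane, proteins),
                de = stats::setNames(de, proteins),
                de_sign = stats::setNames(de_sign, proteins),
                de_fold = config$de_fold,
                spike = if (spike) "SPIKE_ENZYME" else NULL,
                original = x)
  if (config$missing_rate_mcar > 0 || config$missing_intensity_alpha > 0)
    mat <- inject_missingness(mat, config)
  out <- list(matrix = mat, design = design, truth = truth, config = config)
  class(out) <- "surftime_sim"
  out
}

#' @export
print.surftime_sim <- function(x, ...) {
  cat("Synthetic TMT time-course dataset\n")
  cat(sprintf("  %d proteins x %d channels (%d sets; genotypes: %s)\n",
              nrow(x$matrix$intensities), ncol(x$matrix$intensities),
              length(unique(x$design$set_id)),
              paste(x$config$genotypes, collapse = ", ")))
  cat(sprintf("  noise_cv = %g, batch_sigma = %g, seed = %d\n",
              x$config$noise_cv, x$config$batch_sigma, x$config$seed))
  nm <- sum(is.na(x$matrix$intensities))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", nm,
              100 * nm / length(x$matrix$intensities)))
  invisible(x)
}

#' Inject missing values into an intensity matrix
#'
#' Entries are set to missing by a mixture of a missing-completely-at-random
#' component with rate `missing_rate_mcar` and an intensity-dependent
#' component `alpha * plogis(-2 z)` where `z` is the standardized
#' log-intensity, so lower-intensity entries are missing more often. The
#' missingness mask is recorded in the matrix's `missing_mask` field.
#'
#' @param matrix An [intensity_matrix()].
#' @param config A [sim_config()] supplying `missing_rate_mcar`,
#'   `missing_intensity_alpha` and `seed`.
#' @return The intensity matrix with missing entries set to `NA`.
#' @export
inject_missingness <- function(matrix, config) {
  mcar <- config$missing_rate_mcar
  alpha <- config$missing_intensity_alpha
  if (!is.numeric(mcar) || mcar < 0 || mcar > 1)
    stop_field("missing_rate_mcar", "must be a probability in [0, 1]")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop_field("missing_intensity_alpha", "must be a probability in [0, 1]")
  x <- matrix$intensities
  set.seed(config$seed + 104729L)  # independent stream from generation
  pos <- is.finite(x) & x > 0
  lx <- suppressWarnings(log(x))
  z <- (lx - mean(lx[pos])) / stats::sd(lx[pos])
  p <- mcar + (1 - mcar) * alpha * stats::plogis(-2 * z)
  p[!pos] <- mcar
  drop <- matrix(stats::runif(length(x)) < p, nrow(x), ncol(x))
  x[drop] <- NA
  matrix$intensities <- x
  matrix$missing_mask <- drop
  matrix
}
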