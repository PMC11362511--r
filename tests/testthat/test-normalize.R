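make_two_set_matrix <- function(scale2 = 1, scale3 = NULL, n = 20, seed = 1) {
  # one genotype with 2 (or 3) replicate sets, deterministic values
  nsets <- if (is.null(scale3)) 2 else 3
  design <- channel_design(genotypes = "WT", sets_per_genotype = nsets)
  set.seed(seed)
  base <- matrix(stats::runif(n * 10, 1, 100), n, 10)
  scales <- c(1, scale2, scale3)[seq_len(nsets)]
  x <- do.call(cbind, lapply(scales, function(s) base * s))
  colnames(x) <- design$sample_id
  rownames(x) <- sprintf("P%03d", seq_len(n))
  ibaq <- sapply(unique(design$set_id), function(s)
    rowSums(x[, design$sample_id[design$set_id == s]]))
  intensity_matrix(x, ibaq, design)
}

test_that("identical sets give unit IRS factors and an unchanged matrix", {
  mat <- make_two_set_matrix(scale2 = 1)
  out <- irs_normalize(mat)
  fac <- attr(out, "irs_factors")
  expect_equal(fac$factor, rep(1, nrow(fac)), tolerance = 1e-12)
  expect_equal(out$intensities, mat$intensities, tolerance = 1e-12)
})

test_that("a doubled second set yields the closed-form geometric-mean factors", {
  mat <- make_two_set_matrix(scale2 = 2)
  out <- irs_normalize(mat)
  fac <- attr(out, "irs_factors")
  expect_equal(unique(round(fac$factor[fac$set == "WT_1"], 12)),
               round(sqrt(2), 12))
  expect_equal(unique(round(fac$factor[fac$set == "WT_2"], 12)),
               round(sqrt(2) / 2, 12))
  d <- out$intensities
  expect_equal(d[, 1:10], d[, 11:20], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sets scaled 1, 2, 4 get factors 2, 1, 0.5", {
  mat <- make_two_set_matrix(scale2 = 2, scale3 = 4)
  out <- irs_normalize(mat)
  fac <- attr(out, "irs_factors")
  expect_equal(unique(round(fac$factor[fac$set == "WT_1"], 12)), 2)
  expect_equal(unique(round(fac$factor[fac$set == "WT_2"], 12)), 1)
  expect_equal(unique(round(fac$factor[fac$set == "WT_3"], 12)), 0.5)
})

test_that("IRS is idempotent and removes injected batch effects exactly", {
  cfg <- quiet_cfg(n = 150, seed = 9, batch_sigma = 0.5)
  sim <- generate_dataset(cfg)
  m1 <- irs_normalize(apply_ribaq_scaling(sim$matrix))
  d <- sim$design
  for (g in unique(d$genotype)) {
    sets <- unique(d$set_id[d$genotype == g])
    tot <- sapply(sets, function(s)
      rowSums(m1$intensities[, d$sample_id[d$set_id == s]]))
    expect_lt(max(abs(tot - tot[, 1]) / tot[, 1]), 1e-9)
  }
  m2 <- irs_normalize(m1)
  expect_lt(max(abs(attr(m2, "irs_factors")$factor - 1)), 1e-9)
})

test_that("IRS with a single set warns and returns an identity transform", {
  design <- channel_design(genotypes = "WT", sets_per_genotype = 1)
  x <- matrix(stats::runif(50, 1, 10), 5, 10,
              dimnames = list(sprintf("P%d", 1:5), design$sample_id))
  mat <- intensity_matrix(x, cbind(WT_1 = rowSums(x)), design)
  expect_warning(out <- irs_normalize(mat), "at least 2 sets")
  expect_equal(out$intensities, x)
})

test_that("imputation leaves all-six-exempt conditions at zero and unflagged", {
  sim <- generate_dataset(noisy_cfg(n = 60, seed = 3,
                                    missing_rate_mcar = 0.05,
                                    missing_intensity_alpha = 0))
  mat <- sim$matrix
  d <- mat$design
  # erase protein 1 entirely in one genotype condition (time 0 of genotype 1)
  g <- d$genotype[1]
  cols <- d$sample_id[d$genotype == g & d$time_min == 0]
  expect_length(cols, 6)
  mat$intensities[1, cols] <- NA
  out <- impute_missing(mat, seed = 3)
  expect_equal(unname(out$intensities[1, cols]), rep(0, 6))
  expect_false(any(out$imputed[1, cols]))
  # everything else that was missing is filled and flagged
  other_missing <- is.na(mat$intensities)
  other_missing[1, cols] <- FALSE
  expect_false(anyNA(out$intensities))
  expect_true(all(out$imputed[other_missing]))
})

test_that("imputation is deterministic and never touches observed values", {
  sim <- generate_dataset(noisy_cfg(n = 80, seed = 4, missing_rate_mcar = 0.1))
  o1 <- impute_missing(sim$matrix, seed = 7)
  o2 <- impute_missing(sim$matrix, seed = 7)
  expect_identical(o1$intensities, o2$intensities)
  obs <- !is.na(sim$matrix$intensities) & sim$matrix$intensities > 0
  expect_identical(o1$intensities[obs], sim$matrix$intensities[obs])
})

test_that("mask-and-recover error stays within twice the noise sd at 10% MCAR", {
  cfg <- sim_config(n_proteins = 600, noise_cv = 0.1, fold_range = c(2, 2),
                    missing_rate_mcar = 0.1, missing_intensity_alpha = 0,
                    seed = 5)
  sim <- generate_dataset(cfg)
  out <- impute_missing(sim$matrix, seed = 5)
  mask <- sim$matrix$missing_mask
  err <- log(out$intensities[mask]) - log(sim$truth$original[mask])
  noise_sd <- sqrt(log(1 + 0.1^2))
  expect_lte(sqrt(mean(err^2)), 2 * noise_sd)
})

test_that("a channel with no observed values raises an error naming it", {
  sim <- generate_dataset(noisy_cfg(n = 30, seed = 5))
  mat <- sim$matrix
  mat$intensities[, 3] <- NA
  expect_error(impute_missing(mat, seed = 1),
               colnames(mat$intensities)[3], fixed = TRUE)
})
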