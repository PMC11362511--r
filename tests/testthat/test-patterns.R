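test_that("label enumeration covers the full 3^k universe", {
  full <- enumerate_labels()
  expect_length(full, 81)
  expect_identical(full, sort(full))
  expect_true(all(grepl("^[dcu]-[dcu]-[dcu]-[dcu]$", full)))
  expect_length(enumerate_labels(n_intervals = 2), 9)
  curated <- full[seq_len(61)]
  expect_identical(enumerate_labels(curated), curated)
  expect_error(enumerate_labels(c("c-c-c-x")), "c-c-c-x")
})

test_that("model profiles are built by per-step fold construction", {
  ps <- build_model_profiles("c-c-c-c", c(2, 4))
  expect_identical(nrow(ps), 1L)
  expect_equal(unname(as.numeric(ps[1, paste0("v", 1:5)])), rep(1, 5))

  ps <- build_model_profiles("u-c-c-u", 2)
  row <- ps[ps$id != "static", ]
  expect_equal(unname(as.numeric(row[paste0("v", 1:5)])), c(1, 2, 2, 2, 4))

  k <- 3
  ps <- build_model_profiles(magnitudes = c(1.5, 2, 4)[seq_len(k)])
  expect_identical(nrow(ps), 1L + 80L * as.integer(k))
  expect_error(build_model_profiles("u-c-c-u", numeric(0)), "magnitude")
  expect_error(build_model_profiles("u-c-c-u", c(0.5)), "magnitude")
})

test_that("the range filter keeps the static model and applies (max-min)/max >= 0.5", {
  df <- data.frame(id = c("static", "m1", "m2"),
                   label = c("c-c-c-c", "u-d-c-c", "u-d-c-c"),
                   v1 = c(1, 1, 1), v2 = c(1, 1.2, 2), v3 = c(1, 1.1, 1),
                   v4 = c(1, 1, 1), v5 = c(1, 1, 1))
  df$label <- vapply(seq_len(nrow(df)), function(i)
    paste(ifelse(diff(as.numeric(df[i, paste0("v", 1:5)])) > 0, "u",
                 ifelse(diff(as.numeric(df[i, paste0("v", 1:5)])) < 0, "d", "c")),
          collapse = "-"), character(1))
  ps <- surftime:::as_profile_set(df)
  kept <- filter_model_profiles(ps)
  # (1.2 - 1)/1.2 = 0.167 -> removed; (2 - 1)/2 = 0.5 -> boundary retained
  expect_true("static" %in% kept$id)
  expect_false("m1" %in% kept$id)
  expect_true("m2" %in% kept$id)
})

test_that("Bhattacharyya distance matches its closed forms and axioms", {
  p <- c(0.2, 0.3, 0.1, 0.25, 0.15)
  expect_identical(bhattacharyya_distance(p, p), 0)
  expect_equal(bhattacharyya_distance(c(1, 0, 0, 0, 0), rep(0.2, 5)),
               -log(sqrt(0.2)), tolerance = 1e-12)
  expect_identical(bhattacharyya_distance(c(1, 0, 0, 0, 0),
                                          c(0, 0.5, 0.5, 0, 0)), Inf)
  expect_error(bhattacharyya_distance(c(1, 1, 0, 0, 0), p), "sum to 1")
  set.seed(3)
  for (i in 1:25) {
    a <- stats::runif(5); a <- a / sum(a)
    b <- stats::runif(5); b <- b / sum(b)
    d_ab <- bhattacharyya_distance(a, b)
    expect_gte(d_ab, 0)
    expect_equal(d_ab, bhattacharyya_distance(b, a), tolerance = 1e-12)
    expect_equal(d_ab, -log(sum(sqrt(a * b))), tolerance = 1e-12)
  }
})

test_that("assignment finds exact models, honours the printed example, and flags all-zero", {
  models <- filter_model_profiles(build_model_profiles())
  i <- which(models$id == "u-c-c-u_f2")
  exact <- assign_pattern(as.numeric(models[i, paste0("v", 1:5)]) * 3.7, models)
  expect_identical(exact$model_id, "u-c-c-u_f2")
  expect_identical(exact$distance, 0)
  # decreases over the first interval, increases over the other three
  duu <- assign_pattern(c(10, 5.2, 9.5, 21, 41), models)
  expect_identical(duu$label, "d-u-u-u")
  zero <- assign_pattern(rep(0, 5), models)
  expect_identical(zero$label, "not detected")
  expect_true(is.na(zero$model_id))
})

test_that("assignment is scale invariant", {
  models <- filter_model_profiles(build_model_profiles())
  set.seed(4)
  for (i in 1:20) {
    p <- stats::runif(5, 0, 10)
    a1 <- assign_pattern(p, models)
    a2 <- assign_pattern(p * stats::runif(1, 0.01, 100), models)
    expect_identical(a1$model_id, a2$model_id)
    expect_equal(a1$distance, a2$distance, tolerance = 1e-9)
  }
})

test_that("vectorized assignment equals exhaustive pairwise search on small model sets", {
  models <- filter_model_profiles(
    build_model_profiles(enumerate_labels()[1:12], c(2, 4)))
  expect_lte(nrow(models), 50)
  norm <- attr(models, "normalized")
  set.seed(5)
  for (i in 1:30) {
    p <- stats::runif(5, 0.01, 10)
    pn <- p / sum(p)
    dists <- apply(norm, 1, function(q) bhattacharyya_distance(pn, q))
    best <- which(dists == min(dists))
    got <- assign_pattern(p, models)
    expect_true(got$model_id %in% models$id[best])
    expect_equal(got$distance, min(dists), tolerance = 1e-12)
  }
})

test_that("model-profile tables round-trip through TSV", {
  ps <- filter_model_profiles(build_model_profiles(magnitudes = c(2, 4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_profiles(ps, path)
  back <- read_model_profiles(path)
  expect_equal(as.data.frame(back), as.data.frame(ps), tolerance = 1e-12)
})

test_that("noisy synthetic data recovers at least 90% of true labels", {
  cfg <- sim_config(n_proteins = 400, noise_cv = 0.1, fold_range = c(2, 2),
                    seed = 13)
  sim <- generate_dataset(cfg)
  fit <- classify_profiles(quantify_ribaq(sim$matrix, seed = 13))
  truth <- sim$truth$labels[cbind(fit$protein, fit$genotype)]
  expect_gte(mean(fit$label == truth), 0.9)
})
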