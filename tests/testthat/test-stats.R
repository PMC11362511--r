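test_that("the enrichment factor follows E = nN / (wt ko)", {
  # n equal to the random-assortment expectation gives E = 1
  expect_equal(enrichment_factor(73 * 67 / 4148, 4148, 73, 67), 1)
  expect_equal(enrichment_factor(10, 4148, 73, 67), 41480 / 4891,
               tolerance = 1e-12)
  expect_identical(enrichment_factor(0, 100, 10, 10), 0)
  expect_error(enrichment_factor(0, 100, 0, 10), "wt and ko")
})

test_that("fisher_exact reproduces closed-form tables", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2), "over"),
               1 / choose(20, 10), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integers")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "integers")
})

test_that("fisher_exact matches brute-force enumeration and the stats package", {
  set.seed(6)
  for (i in 1:40) {
    tab <- matrix(stats::rpois(4, 4), 2)
    for (side in c("two_sided", "over", "under")) {
      expect_equal(fisher_exact(tab, side), fisher_brute(tab, side),
                   tolerance = 1e-12)
    }
    expect_equal(fisher_exact(tab, "two_sided"),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("transition tables tabulate overlaps with the display rule", {
  # all proteins moving X -> Y form one cell with n = N and E = 1
  ids <- sprintf("P%02d", 1:30)
  a <- stats::setNames(rep("u-c-c-u", 30), ids)
  b <- stats::setNames(rep("c-c-c-c", 30), ids)
  tt <- transition_table(a, b)
  expect_identical(nrow(tt), 1L)
  expect_identical(tt$n, 30L)
  expect_equal(tt$E, 1)
  expect_error(transition_table(a, b[1:10]), "universe")
})

test_that("a cell needs n >= 5 and p < 0.05 to display", {
  # 4 overlapping proteins out of 400: strong enrichment but below the n cut
  ids <- sprintf("P%03d", 1:400)
  a <- stats::setNames(rep("c-c-c-c", 400), ids)
  b <- a
  a[1:4] <- "u-c-c-u"; b[1:4] <- "d-u-u-u"
  tt <- transition_table(a, b)
  cell <- tt[tt$label_a == "u-c-c-u" & tt$label_b == "d-u-u-u", ]
  expect_identical(cell$n, 4L)
  expect_lt(cell$p_over, 0.001)
  expect_false(cell$display)
  # and with n >= 5 the same configuration displays
  a[1:5] <- "u-c-c-u"; b[1:5] <- "d-u-u-u"
  tt <- transition_table(a, b)
  cell <- tt[tt$label_a == "u-c-c-u" & tt$label_b == "d-u-u-u", ]
  expect_true(cell$display)
})

test_that("independent random labels give median enrichment near 1", {
  set.seed(7)
  ids <- sprintf("P%04d", 1:2000)
  labs <- enumerate_labels()[1:10]
  Es <- replicate(50, {
    a <- stats::setNames(sample(labs, 2000, replace = TRUE), ids)
    b <- stats::setNames(sample(labs, 2000, replace = TRUE), ids)
    tt <- transition_table(a, b)
    stats::median(tt$E)
  })
  expect_equal(mean(Es), 1, tolerance = 0.1)
})

test_that("pattern prominence contrasts ID and riBAQ fractions", {
  ids <- sprintf("P%03d", 1:100)
  assign <- data.frame(protein = ids,
                       label = rep(c("c-c-c-c", "u-c-c-u"), c(90, 10)))
  # equal riBAQ everywhere: fractions agree, no direction
  eq <- pattern_prominence(assign, stats::setNames(rep(1, 100), ids))
  expect_equal(eq$id_fraction, eq$ribaq_fraction, tolerance = 1e-12)
  expect_true(all(eq$direction == "none"))
  expect_equal(sum(eq$id_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(eq$ribaq_fraction), 1, tolerance = 1e-9)
  # label with 10% of IDs but 1% of riBAQ is under-represented in riBAQ
  rib <- stats::setNames(c(rep(1, 90), rep(90 / 99 * 0.1, 10)), ids)
  un <- pattern_prominence(assign, rib)
  row <- un[un$label == "u-c-c-u", ]
  expect_equal(row$id_fraction, 0.1)
  expect_equal(row$ribaq_fraction, 0.01, tolerance = 1e-9)
  expect_identical(row$direction, "under")
  # single label holding everything
  one <- pattern_prominence(data.frame(protein = ids, label = "c-c-c-c"),
                            stats::setNames(stats::runif(100), ids))
  expect_equal(one$id_fraction, 1)
  expect_equal(one$ribaq_fraction, 1)
  expect_error(pattern_prominence(assign, rib, subset = character(0)),
               "empty")
})

test_that("differential exposure applies the Welch test with the dual threshold", {
  same <- differential_exposure(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$log2fc, 0)
  expect_false(same$significant)
  r <- differential_exposure(c(12.0, 12.1, 11.9), c(10.0, 10.1, 9.9))
  expect_equal(r$log2fc, 2)
  expect_equal(r$t, 2 / sqrt(0.01 / 3 + 0.01 / 3), tolerance = 1e-9)
  expect_equal(r$df, 4, tolerance = 1e-9)
  expect_lt(r$p_value, 0.05)
  expect_true(r$significant)
  expect_error(differential_exposure(1, c(1, 2)), "at least 2")
})

test_that("imputation class flags one-sided imputation without touching the test", {
  a <- c(5, 5.2, 4.9); b <- c(1, 1.1, 0.9)
  both <- differential_exposure(a, b, c(FALSE, FALSE, FALSE), rep(FALSE, 3))
  one <- differential_exposure(a, b, c(FALSE, FALSE, FALSE), rep(TRUE, 3))
  expect_identical(both$imputation_class, "both-observed")
  expect_identical(one$imputation_class, "one-imputed")
  expect_identical(both$p_value, one$p_value)
})

test_that("Welch reduces to the textbook t test for equal sizes and variances", {
  set.seed(8)
  a <- stats::rnorm(4); b <- stats::rnorm(4)
  # force exactly equal sample variances by mirroring deviations
  b <- mean(b) + (a - mean(a))
  r <- differential_exposure(a, b)
  expect_equal(r$df, 2 * 4 - 2, tolerance = 1e-9)
  expect_equal(r$p_value, stats::t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("single-linkage Pearson clustering matches a brute-force agglomeration", {
  set.seed(9)
  m <- matrix(stats::rnorm(6 * 40), 6, 40,
              dimnames = list(paste0("s", 1:6), NULL))
  m[2, ] <- m[1, ]            # duplicated sample
  m[4, ] <- -m[3, ] + 2       # perfectly anticorrelated pair
  hc <- hierarchical_cluster(m)
  d <- as.matrix(attr(hc, "dist"))
  expect_equal(d[1, 2], 0, tolerance = 1e-12)
  expect_equal(d[3, 4], 2, tolerance = 1e-12)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  # brute force: heights are the sorted single-linkage merge distances
  brute_heights <- local({
    groups <- as.list(seq_len(6))
    hs <- numeric(0)
    dd <- d
    while (length(groups) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
        dij <- min(dd[groups[[i]], groups[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
      hs <- c(hs, best[1])
      groups[[best[3]]] <- c(groups[[best[3]]], groups[[best[2]]])
      groups[[best[2]]] <- NULL
    }
    hs
  })
  expect_equal(hc$height, brute_heights, tolerance = 1e-12)
  m[5, ] <- 3  # zero-variance sample
  expect_error(hierarchical_cluster(m), "s5")
})

test_that("enrichment under a label-permutation null averages to 1", {
  set.seed(10)
  ids <- sprintf("P%04d", 1:1000)
  base_a <- sample(enumerate_labels()[1:6], 1000, replace = TRUE)
  base_b <- sample(enumerate_labels()[1:6], 1000, replace = TRUE)
  labA <- "c-c-c-c"; labB <- "c-c-c-d"
  wt <- sum(base_a == labA); ko <- sum(base_b == labB)
  Es <- replicate(1000, {
    perm <- sample(base_b)
    n <- sum(base_a == labA & perm == labB)
    enrichment_factor(n, 1000, wt, ko)
  })
  expect_gte(mean(Es), 0.9)
  expect_lte(mean(Es), 1.1)
})

test_that("the pattern heatmap matrix sums riBAQ per label and time", {
  rb <- data.frame(protein = rep(c("A", "B", "C"), each = 2),
                   genotype = "WT",
                   replicate = 1,
                   time_min = rep(c(0, 1), 3),
                   net_ribaq = c(1, 2, 3, 4, 5, 6),
                   detected = TRUE, imputed = FALSE)
  assign <- data.frame(protein = c("A", "B", "C"),
                       label = c("x", "x", "y"))
  hm <- pattern_heatmap_matrix(assign, rb)
  expect_equal(hm["x", "0"], 4)
  expect_equal(hm["x", "1"], 6)
  expect_equal(hm["y", "1"], 6)
})
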