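#' Enrichment factor for overlapping pattern groups
#'
#' `E = (n * N) / (wt * ko)`: the ratio of the observed overlap `n` between
#' a pattern group of size `wt` in one genotype and a group of size `ko` in
#' the other to the overlap expected under random assortment among `N`
#' detected proteins.
#'
#' @param n Overlap count.
#' @param N Total number of detected proteins.
#' @param wt,ko Group sizes in the two genotypes.
#' @return The enrichment factor (1 under random assortment).
#' @examples
#' enrichment_factor(10, 4148, 73, 67)
#' @export
enrichment_factor <- function(n, N, wt, ko) {
  if (any(c(n, N, wt, ko) < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (wt == 0 || ko == 0)
    stop("enrichment factor undefined: wt and ko must be positive",
         call. = FALSE)
  if (n > min(wt, ko) || wt > N || ko > N)
    stop("inconsistent contingency counts", call. = FALSE)
  (n * N) / (wt * ko)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric p-values under fixed margins: one-sided
#' over-representation (`P(X >= n)`), under-representation (`P(X <= n)`),
#' or the two-sided sum of all table probabilities not exceeding the
#' observed one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param side `"two_sided"` (default), `"over"` or `"under"`.
#' @return The p-value.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2), "two_sided")  # 2/252
#' @export
fisher_exact <- function(table, side = c("two_sided", "over", "under")) {
  side <- match.arg(side)
  if (!is.matrix(table) || !all(dim(table) == 2))
    stop("table must be a 2x2 matrix", call. = FALSE)
  v <- as.vector(table)
  if (any(is.na(v)) || any(v < 0) || any(abs(v - round(v)) > 1e-9))
    stop("table entries must be nonnegative integers", call. = FALSE)
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  if (r1 + r2 == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, r1, r2, c1)
  switch(side,
         over = sum(probs[xs >= a]),
         under = sum(probs[xs <= a]),
         two_sided = {
           p_obs <- probs[xs == a]
           # relative slack guards against floating-point ties, as in the
           # classical implementation of the two-sided exact test
           min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
         })
}

#' Pattern-transition table between two genotypes
#'
#' Cross-tabulates each protein's simplified pattern in genotype A against
#' its pattern in genotype B. For every observed (labelA, labelB) pair it
#' reports the overlap `n`, the random-assortment expectation
#' `wt * ko / N`, the enrichment factor `E`, and one-sided Fisher p-values
#' for over- and under-representation. A cell qualifies for display when
#' `n >= 5` and either p-value is below 0.05.
#'
#' @param assign_a,assign_b Data frames with columns `protein` and `label`
#'   (e.g. one genotype's rows of a [classify_profiles()] fit), or named
#'   character vectors of labels. Both must cover the same protein universe.
#' @return Data frame of transition cells, one row per observed pair, with
#'   columns `label_a`, `label_b`, `n`, `expected`, `E`, `p_over`,
#'   `p_under`, `display`.
#' @export
transition_table <- function(assign_a, assign_b) {
  as_named <- function(a) {
    if (is.data.frame(a)) stats::setNames(a$label, a$protein)
    else if (!is.null(names(a))) a
    else stop("assignments must be named by protein", call. = FALSE)
  }
  la <- as_named(assign_a); lb <- as_named(assign_b)
  if (length(la) != length(lb) || !setequal(names(la), names(lb)))
    stop("assignments do not share a protein universe", call. = FALSE)
  lb <- lb[names(la)]
  N <- length(la)
  tab <- table(la, lb)
  wt_tot <- table(la); ko_tot <- table(lb)
  cells <- which(tab > 0, arr.ind = TRUE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    A <- rownames(tab)[cells[i, 1]]; B <- colnames(tab)[cells[i, 2]]
    n <- tab[cells[i, 1], cells[i, 2]]
    wt <- as.integer(wt_tot[[A]]); ko <- as.integer(ko_tot[[B]])
    m <- matrix(c(n, wt - n, ko - n, N - wt - ko + n), 2, byrow = TRUE)
    p_over <- fisher_exact(m, "over")
    p_under <- fisher_exact(m, "under")
    data.frame(label_a = A, label_b = B, n = as.integer(n),
               expected = wt * ko / N,
               E = enrichment_factor(n, N, wt, ko),
               p_over = p_over, p_under = p_under,
               display = n >= 5 && min(p_over, p_under) < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(-out$n), , drop = FALSE]
}

#' Pattern prominence: ID fraction versus riBAQ fraction
#'
#' For each simplified pattern within a protein subset (e.g. the
#' membrane-annotated proteins), compares the fraction of protein IDs
#' carrying the pattern with the fraction of total riBAQ intensity it
#' holds. A pattern is prominent when either fraction reaches `min_frac`.
#' Whether the riBAQ share is significantly smaller or larger than the ID
#' share is assessed by an exact binomial test of the ID count against the
#' riBAQ fraction as null success probability.
#'
#' @param assignments Data frame with `protein` and `label` columns (one
#'   genotype).
#' @param ribaq Named numeric vector: total riBAQ per protein.
#' @param subset Optional protein ids restricting the analysis.
#' @param min_frac Prominence threshold on either fraction (default 0.05).
#' @return Data frame per label: `label`, `n`, `id_fraction`,
#'   `ribaq_fraction`, `prominent`, `p_value`,
#'   `direction` (`"over"`/`"under"`/`"none"`, the direction of the riBAQ
#'   share relative to the ID share).
#' @export
pattern_prominence <- function(assignments, ribaq, subset = NULL,
                               min_frac = 0.05) {
  lab <- stats::setNames(assignments$label, assignments$protein)
  if (is.null(subset)) subset <- names(lab)
  subset <- intersect(subset, names(lab))
  if (!length(subset)) stop("protein subset is empty", call. = FALSE)
  lab <- lab[subset]
  rb <- ribaq[subset]
  rb[is.na(rb)] <- 0
  total <- sum(rb)
  n_sub <- length(subset)
  out <- lapply(sort(unique(lab)), function(L) {
    k <- sum(lab == L)
    idf <- k / n_sub
    rbf <- if (total > 0) sum(rb[lab == L]) / total else 0
    p <- stats::binom.test(k, n_sub, p = min(max(rbf, 0), 1))$p.value
    dir <- if (p < 0.05 && rbf != idf) {
      if (rbf > idf) "over" else "under"
    } else "none"
    data.frame(label = L, n = k, id_fraction = idf, ribaq_fraction = rbf,
               prominent = idf >= min_frac || rbf >= min_frac,
               p_value = p, direction = dir, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Differential extracellular exposure between two groups
#'
#' Two-tailed Welch unequal-variance t test on log2 intensities with the
#' study's significance rule: `|log2FC| > 1` and `p < 0.05`, without
#' multiple-testing adjustment. The imputation class records whether any
#' contributing value was imputed in exactly one of the groups (the
#' volcano-plot "one-imputed" class); it never alters the statistic.
#'
#' @param group_a,group_b Numeric vectors of log2 values, each of length
#'   `>= 2`.
#' @param imputed_a,imputed_b Optional logical vectors flagging imputed
#'   values.
#' @return A list: `log2fc` (`mean(a) - mean(b)`), `p_value`, `t`, `df`,
#'   `significant`, `imputation_class`.
#' @export
differential_exposure <- function(group_a, group_b,
                                  imputed_a = NULL, imputed_b = NULL) {
  if (sum(is.finite(group_a)) < 2 || sum(is.finite(group_b)) < 2)
    stop("each group needs at least 2 finite values", call. = FALSE)
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  fc <- mean(group_a) - mean(group_b)
  any_a <- isTRUE(any(imputed_a)); any_b <- isTRUE(any(imputed_b))
  list(log2fc = fc,
       p_value = tt$p.value,
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       significant = abs(fc) > 1 && tt$p.value < 0.05,
       imputation_class = if (xor(any_a, any_b)) "one-imputed"
                          else "both-observed")
}

#' Differential-exposure table over many proteins
#'
#' @param mat_a,mat_b Numeric matrices, proteins x replicates, of log2
#'   values (row names are protein ids).
#' @param imputed_a,imputed_b Optional logical matrices of the same shape.
#' @param adjust Apply Benjamini-Hochberg adjustment to the p-values
#'   (default `FALSE`, matching an unadjusted per-protein analysis).
#' @return Data frame with one row per protein: `protein`, `log2fc`, `p`,
#'   `significant`, `class` (and `p_adj` when `adjust`).
#' @export
differential_exposure_table <- function(mat_a, mat_b,
                                        imputed_a = NULL, imputed_b = NULL,
                                        adjust = FALSE) {
  stopifnot(nrow(mat_a) == nrow(mat_b))
  rows <- lapply(seq_len(nrow(mat_a)), function(i) {
    a <- mat_a[i, ]; b <- mat_b[i, ]
    if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) return(NULL)
    r <- differential_exposure(a[is.finite(a)], b[is.finite(b)],
                               if (!is.null(imputed_a)) imputed_a[i, ],
                               if (!is.null(imputed_b)) imputed_b[i, ])
    data.frame(protein = rownames(mat_a)[i], log2fc = r$log2fc,
               p = r$p_value, significant = r$significant,
               class = r$imputation_class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (isTRUE(adjust) && !is.null(out))
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Single-linkage hierarchical clustering on Pearson correlation
#'
#' Clusters samples by the distance `1 - Pearson r` between their
#' log-intensity vectors using single-linkage agglomeration.
#'
#' @param m Numeric matrix, samples x proteins, of log2 intensities.
#' @return An [stats::hclust] object (merge order and heights), with the
#'   distance matrix attached as attribute `dist`.
#' @export
hierarchical_cluster <- function(m) {
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  vs <- apply(m, 1, stats::var)
  if (any(vs == 0))
    stop("sample '", rownames(m)[which(vs == 0)[1]],
         "' has zero variance", call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(t(m), method = "pearson"))
  hc <- stats::hclust(d, method = "single")
  attr(hc, "dist") <- d
  hc
}

#' Per-pattern riBAQ heatmap matrix
#'
#' Sums net riBAQ per simplified pattern and time point within a genotype
#' (the data behind the per-pattern time-course heatmaps).
#'
#' @param assignments Data frame with `protein` and `label` (one genotype).
#' @param ribaq Long net-riBAQ table ([quantify_ribaq()]) filtered to the
#'   same genotype.
#' @return Matrix of patterns x time points of summed net riBAQ.
#' @export
pattern_heatmap_matrix <- function(assignments, ribaq) {
  lab <- stats::setNames(assignments$label, assignments$protein)
  ribaq <- ribaq[ribaq$protein %in% names(lab), ]
  ribaq$label <- lab[ribaq$protein]
  m <- tapply(ribaq$net_ribaq, list(ribaq$label, ribaq$time_min), sum)
  m[is.na(m)] <- 0
  m
}
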