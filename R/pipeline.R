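#' Run the full quantitation and classification pipeline
#'
#' Executes simulate (or read) -> filter -> quantify -> normalize ->
#' classify -> stats, writing every intermediate table, a JSON run manifest
#' (package version, seed, config hash, output checksums) and a log to the
#' output directory. The run is idempotent: the same config and seed
#' reproduce byte-identical outputs.
#'
#' @param config A configuration list, or the path to a YAML or JSON file.
#'   Recognized blocks: `seed`; `simulate` (fields of [sim_config()]) or
#'   `input` (`protein_groups` and `design` file paths, optional
#'   `annotations` TSV with `protein_id` and `membrane` columns); `quantify`
#'   (`impute`, `irs`, `relative`); `patterns` (`magnitudes`,
#'   `min_range_frac`, optional `model_table` path).
#' @param outdir Output directory (created if needed); overrides
#'   `config$outdir`.
#' @return Invisibly, a list of class `surftime_run` with the manifest, the
#'   output directory, and the in-memory result tables.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  outdir <- outdir %||% config$outdir %||%
    stop("[config] no output directory given", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  log_lines <- character()
  logit <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  outputs <- character()
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    outputs <<- c(outputs, name)
    path
  }
  fail <- function(stage, e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)

  # --- simulate or read ------------------------------------------------
  truth <- NULL
  membrane <- NULL
  if (!is.null(config$simulate)) {
    sim <- tryCatch({
      args <- config$simulate
      args$seed <- seed
      do.call(sim_config, args)
    }, error = function(e) fail("simulate", e))
    sim <- generate_dataset(sim)
    mat <- sim$matrix
    design <- sim$design
    truth <- sim$truth
    membrane <- names(truth$membrane)[truth$membrane]
    logit("simulate", "%d proteins x %d channels, seed %d",
          nrow(mat$intensities), ncol(mat$intensities), seed)
    emit("design.tsv", function(p) write_design(design, p))
    emit("protein_groups.tsv", function(p) write_protein_groups(mat, p))
    emit("ground_truth.tsv", function(p) write_ground_truth(sim, p))
  } else if (!is.null(config$input)) {
    inp <- config$input
    if (is.null(inp$design))
      stop("[read] config$input$design (design TSV) is required",
           call. = FALSE)
    if (is.null(inp$protein_groups))
      stop("[read] config$input$protein_groups (proteinGroups TSV) is required",
           call. = FALSE)
    design <- tryCatch(read_design(inp$design),
                       error = function(e) fail("read", e))
    pg <- tryCatch(read_protein_groups(inp$protein_groups, design),
                   error = function(e) fail("read", e))
    tab <- filter_protein_groups(pg$table)
    keep <- tab[["Protein IDs"]]
    mat <- pg$matrix
    sel <- rownames(mat$intensities) %in% keep
    mat$intensities <- mat$intensities[sel, , drop = FALSE]
    mat$ibaq <- mat$ibaq[sel, , drop = FALSE]
    mat$imputed <- mat$imputed[sel, , drop = FALSE]
    logit("read", "%d of %d protein groups retained after filtering",
          nrow(mat$intensities), nrow(pg$table))
    if (!is.null(inp$annotations)) {
      ann <- read_tsv(inp$annotations)
      membrane <- ann$protein_id[as.logical(ann$membrane)]
    }
  } else stop("[config] either a 'simulate' or an 'input' block is required",
              call. = FALSE)

  # --- quantify + normalize -------------------------------------------
  q <- config$quantify %||% list()
  ribaq <- tryCatch(
    quantify_ribaq(mat,
                   impute = q$impute %||% TRUE,
                   irs = q$irs %||% TRUE,
                   relative = q$relative %||% FALSE,
                   seed = seed),
    error = function(e) fail("quantify", e))
  logit("quantify", "%d net riBAQ rows (%d detected, %d imputed-flagged)",
        nrow(ribaq), sum(ribaq$detected), sum(ribaq$imputed))
  emit("ribaq.tsv", function(p) write_tsv(ribaq, p))
  irs_fac <- attr(ribaq, "irs_factors")
  if (!is.null(irs_fac))
    emit("irs_factors.tsv", function(p) write_tsv(irs_fac, p))
  impmat <- attr(ribaq, "imputed")
  flags <- which(impmat, arr.ind = TRUE)
  imp_df <- data.frame(
    protein = rownames(impmat)[flags[, 1]],
    sample_id = colnames(impmat)[flags[, 2]], stringsAsFactors = FALSE)
  emit("imputation_flags.tsv", function(p) write_tsv(imp_df, p))

  # --- classify --------------------------------------------------------
  pt <- config$patterns %||% list()
  models <- tryCatch({
    if (!is.null(pt$model_table)) read_model_profiles(pt$model_table)
    else filter_model_profiles(
      build_model_profiles(magnitudes = pt$magnitudes %||% c(1.5, 2, 4, 8)),
      min_range_frac = pt$min_range_frac %||% 0.5)
  }, error = function(e) fail("classify", e))
  fit <- classify_profiles(ribaq, models)
  logit("classify", "%d models; %d assignments", nrow(models), nrow(fit))
  emit("assignments.tsv", function(p) write_tsv(as.data.frame(fit), p))

  # --- stats -----------------------------------------------------------
  genos <- unique(ribaq$genotype)
  trans <- prom <- de <- NULL
  heat <- list()
  tot_ribaq <- tapply(ribaq$net_ribaq, list(ribaq$protein, ribaq$genotype), sum)
  for (g in genos) {
    ag <- fit[fit$genotype == g, ]
    heat[[g]] <- pattern_heatmap_matrix(ag, ribaq[ribaq$genotype == g, ])
    subset_ids <- if (!is.null(membrane)) membrane else ag$protein
    prom_g <- pattern_prominence(ag, tot_ribaq[, g],
                                 subset = intersect(subset_ids, ag$protein))
    prom_g$genotype <- g
    prom <- rbind(prom, prom_g)
  }
  heat_df <- do.call(rbind, lapply(names(heat), function(g) {
    m <- heat[[g]]
    data.frame(genotype = g, label = rep(rownames(m), ncol(m)),
               time_min = rep(colnames(m), each = nrow(m)),
               total_ribaq = as.vector(m), stringsAsFactors = FALSE)
  }))
  emit("pattern_heatmap.tsv", function(p) write_tsv(heat_df, p))
  emit("prominence.tsv", function(p) write_tsv(prom, p))
  if (length(genos) >= 2) {
    a <- fit[fit$genotype == genos[1], ]
    b <- fit[fit$genotype == genos[2], ]
    ids <- if (!is.null(membrane))
      intersect(membrane, intersect(a$protein, b$protein))
      else intersect(a$protein, b$protein)
    trans <- transition_table(a[a$protein %in% ids, c("protein", "label")],
                              b[b$protein %in% ids, c("protein", "label")])
    emit("transitions.tsv", function(p) write_tsv(trans, p))
    de <- resting_de_table(ribaq, genos[1], genos[2])
    emit("de_resting.tsv", function(p) write_tsv(de, p))
    logit("stats", "%d transition cells (%d displayed); %d DE rows",
          nrow(trans), sum(trans$display), if (is.null(de)) 0 else nrow(de))
  }
  link <- cluster_samples(ribaq)
  if (!is.null(link))
    emit("linkage.tsv", function(p) write_tsv(link, p))

  # --- manifest + log --------------------------------------------------
  emit("run.log", function(p) writeLines(log_lines, p))
  manifest <- list(
    package = "surftime",
    version = as.character(utils::packageVersion("surftime")),
    seed = seed,
    config_hash = fnv1a_hash(paste(deparse(config), collapse = "\n")),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res <- list(manifest = manifest, outdir = outdir, ribaq = ribaq,
              fit = fit, transitions = trans, prominence = prom, de = de,
              truth = truth)
  class(res) <- "surftime_run"
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

# Welch comparison of resting-state log2 net riBAQ between two genotypes
resting_de_table <- function(ribaq, geno_a, geno_b) {
  t0 <- min(ribaq$time_min)
  r0 <- ribaq[ribaq$time_min == t0 & ribaq$detected, ]
  mk <- function(g) {
    r <- r0[r0$genotype == g, ]
    m <- tapply(log2(r$net_ribaq), list(r$protein, r$replicate), identity)
    m
  }
  ma <- mk(geno_a); mb <- mk(geno_b)
  common <- intersect(rownames(ma), rownames(mb))
  ok <- common[rowSums(is.finite(ma[common, , drop = FALSE])) >= 2 &
               rowSums(is.finite(mb[common, , drop = FALSE])) >= 2]
  if (!length(ok)) return(NULL)
  imp <- tapply(r0$imputed, list(r0$protein, r0$genotype), any)
  out <- differential_exposure_table(ma[ok, , drop = FALSE],
                                     mb[ok, , drop = FALSE])
  cls <- ifelse(xor(imp[out$protein, geno_a], imp[out$protein, geno_b]),
                "one-imputed", "both-observed")
  out$class <- ifelse(is.na(cls), out$class, cls)
  out
}

# single-linkage clustering of the labeled samples on log2 net riBAQ
cluster_samples <- function(ribaq) {
  key <- paste(ribaq$genotype, ribaq$replicate, ribaq$time_min, sep = ".")
  m <- tapply(log2(ribaq$net_ribaq + 1), list(key, ribaq$protein), identity)
  keep <- apply(m, 1, function(r) stats::var(r, na.rm = TRUE) > 0)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) return(NULL)
  hc <- hierarchical_cluster(m)
  data.frame(step = seq_len(nrow(hc$merge)),
             merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
             height = hc$height, stringsAsFactors = FALSE)
}

#' @export
print.surftime_run <- function(x, ...) {
  cat("surftime pipeline run ->", x$outdir, "\n")
  cat("  outputs:", paste(names(x$manifest$outputs), collapse = ", "), "\n")
  cat("  seed:", x$manifest$seed, " config:", x$manifest$config_hash, "\n")
  invisible(x)
}
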