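#' Construct a TMT10plex channel design
#'
#' Builds the channel-to-condition map for a time-course surfaceome
#' experiment: one 10-channel TMT set per (genotype, replicate), each set
#' carrying one non-labeled control and one labeled sample for each of five
#' time points. The default tag convention assigns the five lightest
#' reporters (126..128C) to the controls at 0, 1, 5, 10 and 30 min and the
#' five heaviest (129N..131) to the labeled samples at the same time points.
#'
#' @param genotypes Character vector of genotype names.
#' @param sets_per_genotype Number of replicate TMT sets per genotype.
#' @param time_points Ordered vector of five stimulation times in minutes.
#' @return A `data.frame` with one row per channel and columns
#'   `set_id`, `genotype`, `replicate`, `channel`, `time_min`, `labeled`
#'   and `sample_id` (`"<set_id>.<channel>"`, the column key used by
#'   intensity matrices).
#' @examples
#' d <- channel_design()
#' table(d$genotype, d$labeled)
#' @export
channel_design <- function(genotypes = c("WT", "KO"),
                           sets_per_genotype = 3,
                           time_points = c(0, 1, 5, 10, 30)) {
  if (length(time_points) != 5 || any(diff(time_points) <= 0))
    stop_field("time_points", "must be five strictly increasing minutes")
  if (!is_count(sets_per_genotype))
    stop_field("sets_per_genotype", "must be a positive integer")
  if (length(genotypes) < 1 || anyDuplicated(genotypes))
    stop_field("genotypes", "must be non-empty and unique")
  rows <- list()
  for (g in genotypes) {
    for (r in seq_len(sets_per_genotype)) {
      set_id <- paste(g, r, sep = "_")
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = set_id, genotype = g, replicate = r,
        channel = TMT10_TAGS,
        time_min = rep(time_points, 2),
        labeled = rep(c(FALSE, TRUE), each = 5),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$sample_id <- paste(out$set_id, out$channel, sep = ".")
  rownames(out) <- NULL
  validate_design(out)
  out
}

validate_design <- function(design) {
  need <- c("set_id", "genotype", "replicate", "channel", "time_min",
            "labeled", "sample_id")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (s in unique(design$set_id)) {
    d <- design[design$set_id == s, ]
    if (nrow(d) != 10)
      stop("design set '", s, "' does not have exactly 10 channels",
           call. = FALSE)
    key <- paste(d$time_min, d$labeled)
    if (anyDuplicated(key))
      stop("design set '", s, "' repeats a (time point, labeled) pair",
           call. = FALSE)
  }
  invisible(design)
}

#' Write / read a channel design table
#'
#' @param design A design `data.frame` from [channel_design()].
#' @param path File path of the tab-separated design table.
#' @return `read_design` returns the design `data.frame`; `write_design`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  write_tsv(design[c("set_id", "genotype", "replicate", "channel",
                     "time_min", "labeled")], path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- read_tsv(path)
  d$labeled <- as.logical(d$labeled)
  d$channel <- as.character(d$channel)
  d$sample_id <- paste(d$set_id, d$channel, sep = ".")
  validate_design(d)
  d
}
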