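# Normalized read-depth genotyping of a candidate deletion. Depth over a
# scan window is normalized by the sample's mean depth over the scan
# *excluding* the putative event, so a diploid base sits at 1, a
# heterozygous deletion at ~0.5 and a homozygous deletion at ~0.

#' Locus specification for deletion genotyping
#'
#' @param scan_region [region()] covered by the per-sample depth track
#'   (e.g. `29:17990000-18000000`).
#' @param exclusion_region [region()] within the scan left out of the
#'   normalization mean (e.g. `29:17993500-17996000`).
#' @param event_region [region()] of the putative deletion; defaults to the
#'   exclusion region when breakpoints are not known more precisely.
#' @return a `locus_spec` object.
#' @export
locus_spec <- function(scan_region, exclusion_region, event_region = NULL) {
  if (is.null(event_region)) event_region <- exclusion_region
  stopifnot(inherits(scan_region, "region"),
            inherits(exclusion_region, "region"),
            inherits(event_region, "region"))
  if (!.region_contains(scan_region, exclusion_region))
    stop("exclusion region must lie within the scan region")
  if (!.region_contains(exclusion_region, event_region))
    stop("event region must lie within the exclusion region")
  structure(list(scan = scan_region, exclusion = exclusion_region,
                 event = event_region), class = "locus_spec")
}

.locus_index <- function(track, reg) {
  if (track$region$chrom != reg$chrom ||
      track$region$start > reg$start || track$region$end < reg$end)
    stop("depth track does not cover ", format(reg))
  (reg$start - track$region$start + 1):(reg$end - track$region$start + 1)
}

#' Normalize a depth track by its out-of-event mean
#'
#' Divides every base by the mean depth over scan minus exclusion, so the
#' mean of the normalized track outside the exclusion is exactly 1. A zero
#' mean outside the exclusion makes normalization impossible; the result is
#' flagged instead of divided.
#'
#' @param track a [depth_track()] covering the scan region.
#' @param locus a [locus_spec()].
#' @return list: `track` (normalized [depth_track()], or `NULL` when the
#'   out-of-event mean is zero), `raw_mean` (the normalization constant),
#'   `ok` (logical).
#' @export
normalize_coverage <- function(track, locus) {
  stopifnot(inherits(track, "depth_track"), inherits(locus, "locus_spec"))
  idx_all <- .locus_index(track, locus$scan)
  idx_exc <- .locus_index(track, locus$exclusion)
  idx_out <- setdiff(idx_all, idx_exc)
  if (!length(idx_out)) stop("exclusion region covers the whole scan region")
  raw_mean <- mean(track$depth[idx_out])
  if (raw_mean <= 0)
    return(list(track = NULL, raw_mean = raw_mean, ok = FALSE))
  norm <- track$depth / raw_mean
  list(track = structure(list(region = track$region, depth = norm),
                         class = "depth_track"),
       raw_mean = raw_mean, ok = TRUE)
}

#' Genotype a deletion from normalized coverage
#'
#' Samples whose raw out-of-event mean depth is below `min_sample_coverage`
#' (5x) are `low_confidence`. Otherwise the mean normalized coverage `m`
#' over the event region is classified with the cutpoints `del_hom_max`
#' and `del_het_max`: `m < 0.25` is `hom_deletion`, `0.25 <= m <= 0.75` is
#' `het_deletion`, `m > 0.75` is `no_deletion` (midpoints between the
#' expected 0 / 0.5 / 1 copy-number levels).
#'
#' @param track a raw [depth_track()] covering the scan region.
#' @param locus a [locus_spec()].
#' @param sample sample label carried into the call.
#' @param params a [pipeline_params()].
#' @return one-row `data.table`: `sample`, `raw_mean`, `norm_event`,
#'   `genotype`.
#' @export
genotype_deletion <- function(track, locus, sample = "sample",
                              params = pipeline_params()) {
  nz <- normalize_coverage(track, locus)
  if (!nz$ok || nz$raw_mean < params$min_sample_coverage) {
    norm_event <- if (nz$ok)
      mean(nz$track$depth[.locus_index(nz$track, locus$event)]) else NA_real_
    return(data.table::data.table(sample = sample, raw_mean = nz$raw_mean,
                                  norm_event = norm_event,
                                  genotype = "low_confidence"))
  }
  m <- mean(nz$track$depth[.locus_index(nz$track, locus$event)])
  gt <- if (m < params$del_hom_max) "hom_deletion"
        else if (m <= params$del_het_max) "het_deletion"
        else "no_deletion"
  data.table::data.table(sample = sample, raw_mean = nz$raw_mean,
                         norm_event = m, genotype = gt)
}

#' Per-population summary of deletion calls
#'
#' Groups confident calls by population and reports the mean normalized
#' event coverage with a normal-approximation 95% confidence interval
#' (`mean +/- 1.96 * SD / sqrt(n)`). With a single confident sample the SD
#' is undefined and the interval is reported zero-width with
#' `ci_degenerate = TRUE`. Populations with no confident call are reported
#' with `n = 0`, not dropped.
#'
#' @param calls `data.table` of [genotype_deletion()] rows plus a
#'   `population` column.
#' @return `data.table`: `population`, `n` (confident samples), `mean`,
#'   `ci_lo`, `ci_hi`, `ci_degenerate`, plus one count column per genotype
#'   class.
#' @export
cohort_summary <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if (!"population" %in% names(calls)) stop("calls need a population column")
  classes <- c("hom_deletion", "het_deletion", "no_deletion", "low_confidence")
  out <- calls[, {
    conf <- genotype != "low_confidence"
    x <- norm_event[conf]
    n <- sum(conf)
    mu <- if (n) mean(x) else NA_real_
    se <- if (n >= 2) stats::sd(x) / sqrt(n) else 0
    tallies <- lapply(classes, function(cl) sum(genotype == cl))
    names(tallies) <- paste0("n_", classes)
    c(list(n = n, mean = mu,
           ci_lo = if (n) mu - 1.96 * se else NA_real_,
           ci_hi = if (n) mu + 1.96 * se else NA_real_,
           ci_degenerate = n < 2), tallies)
  }, by = "population"]
  out[]
}
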