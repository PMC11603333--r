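# Trio-binning phase diagnostics: how much of the offspring's read set can
# be assigned to a parental haplotype, and how evenly, along the genome.
# Each read is counted once, in the window containing its primary-alignment
# start; no length weighting.

#' Count tagged reads per genomic window
#'
#' Tiles the layout at `phase_window` (100 kb by default) and counts
#' paternal / maternal / unassigned read starts per window. All windows are
#' emitted, including empty ones.
#'
#' @param reads `data.table` of tagged reads (`chrom`, `start`, `tag`), as
#'   from [read_tagged_reads()] or [simulate_trio_tags()].
#' @param layout a [genome_layout()].
#' @param phase_window window size in bp.
#' @param autosomes_only restrict to flagged autosomes (reads on other
#'   chromosomes are then an error).
#' @return `data.table` of phase windows: `chrom`, `start`, `end`,
#'   `n_paternal`, `n_maternal`, `n_unassigned`.
#' @export
bin_tagged_reads <- function(reads, layout, phase_window = 1e5,
                             autosomes_only = FALSE) {
  .layout_check(layout)
  reads <- .validate_tagged_reads(reads, layout)
  win <- tile_windows(layout, phase_window, autosomes_only = autosomes_only)
  if (nrow(reads)) {
    lay <- if (autosomes_only) layout[layout$autosome, ] else layout
    if (!all(reads$chrom %in% lay$chrom))
      stop("reads on chromosomes outside the (autosomal) layout")
    reads <- data.table::copy(reads)
    reads[, "start_w" := (reads$start - 1) %/% phase_window * phase_window + 1]
    cnt <- data.table::dcast(
      reads[, list(n = .N), by = c("chrom", "start_w", "tag")],
      chrom + start_w ~ tag, value.var = "n", fill = 0L, drop = FALSE)
    data.table::setnames(cnt, "start_w", "start")
    win <- merge(win, cnt, by = c("chrom", "start"), all.x = TRUE)
  }
  for (tg in .tag_levels) if (!tg %in% names(win)) win[, (tg) := 0L]
  win[, (.tag_levels) := lapply(.SD, function(v) {
    v[is.na(v)] <- 0L; as.integer(v)
  }), .SDcols = .tag_levels]
  data.table::setnames(win, .tag_levels,
                       c("n_paternal", "n_maternal", "n_unassigned"))
  data.table::setkeyv(win, NULL)
  win <- win[order(match(win$chrom, layout$chrom), win$start)]
  win[, c("chrom", "start", "end", "partial",
          "n_paternal", "n_maternal", "n_unassigned"), with = FALSE][]
}

#' Parental read bias ratio of a window
#'
#' `max(n_pat, n_mat) / min(n_pat, n_mat)`. When exactly one of the two
#' parental counts is zero the window is maximally biased and the ratio is
#' `Inf`; when both are zero it is undefined (`NA`).
#'
#' @param n_paternal,n_maternal parental read counts (vectorized).
#' @return numeric ratios `>= 1`, `Inf`, or `NA`.
#' @examples
#' bias_ratio(10, 2)  # 5
#' bias_ratio(0, 7)   # Inf
#' @export
bias_ratio <- function(n_paternal, n_maternal) {
  hi <- pmax(n_paternal, n_maternal)
  lo <- pmin(n_paternal, n_maternal)
  out <- ifelse(hi == 0, NA_real_, ifelse(lo == 0, Inf, hi / lo))
  as.numeric(out)
}

#' Count windows with strong parental bias
#'
#' Windows whose bias ratio is strictly greater than `bias_fold` (default
#' 5). `Inf` (one parental class absent, the other present) counts as
#' biased; undefined windows (`NA`, no parental reads at all) are excluded.
#'
#' @param ratios numeric vector from [bias_ratio()].
#' @param bias_fold threshold (strict `>`).
#' @return integer count.
#' @export
count_biased_windows <- function(ratios, bias_fold = 5) {
  sum(ratios > bias_fold, na.rm = TRUE)
}

#' Summarize phase windows: binnability and parental bias
#'
#' Adds per-window `binnability` (`(n_pat + n_mat) / total`; `NA` for empty
#' windows, which are excluded from histograms) and `bias_ratio`, and
#' computes the genome-wide binnability and the biased-window count.
#'
#' The genome-wide binnability is read-count weighted (total assigned reads
#' over total reads) — the quantity a single "fraction of reads binned"
#' number describes — not a mean of window fractions; set
#' `weighting = "window"` for the unweighted mean over non-empty windows.
#'
#' @param windows output of [bin_tagged_reads()].
#' @param bias_fold bias threshold, see [count_biased_windows()].
#' @param weighting `"read"` (default) or `"window"`.
#' @return a `phase_summary` list: `windows` (augmented table),
#'   `genome_binnability`, `n_biased_windows`, `n_reads`.
#' @export
phase_summary <- function(windows, bias_fold = 5, weighting = c("read", "window")) {
  weighting <- match.arg(weighting)
  w <- data.table::as.data.table(windows)
  tot <- w$n_paternal + w$n_maternal + w$n_unassigned
  assigned <- w$n_paternal + w$n_maternal
  w[, "binnability" := ifelse(tot == 0, NA_real_, assigned / tot)]
  w[, "bias_ratio" := bias_ratio(w$n_paternal, w$n_maternal)]
  gb <- if (weighting == "read") {
    if (sum(tot) == 0) NA_real_ else sum(assigned) / sum(tot)
  } else {
    mean(w$binnability, na.rm = TRUE)
  }
  structure(list(windows = w[],
                 genome_binnability = gb,
                 n_biased_windows = count_biased_windows(w$bias_ratio, bias_fold),
                 n_reads = sum(tot)),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf(
    "<phase_summary> %d windows, %d reads; binnability %.1f%%; %d biased windows\n",
    nrow(x$windows), x$n_reads, 100 * x$genome_binnability, x$n_biased_windows))
  invisible(x)
}
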