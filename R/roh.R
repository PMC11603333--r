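# Coverage-corrected heterozygosity and run-of-homozygosity (ROH) calling.
#
# Heterozygosity in a window is the number of heterozygous bi-allelic SNPs
# divided by the number of *callable* bases — bases whose depth lies
# strictly within (mean/3, 2.5*mean) — so that low- or high-coverage bases
# do not deflate the estimate. ROH are called on 10 kb windows: runs of
# low-heterozygosity windows are merged across isolated heterozygosity
# peaks whenever the merged span's callable-weighted mean heterozygosity
# stays below 0.25x the genome mean.

#' Per-window callable-base counts
#'
#' Counts, per tumbling window, the bases whose depth is strictly within
#' `(mean_coverage * depth_low_factor, mean_coverage * depth_high_factor)`.
#'
#' @param tracks a [depth_track()] or list of them (one per chromosome).
#' @param mean_coverage average genome coverage (> 0).
#' @param window window size in bp.
#' @param params a [pipeline_params()] supplying the depth factors.
#' @return `data.table`: `chrom`, `start`, `end`, `window_bp`, `callable`.
#' @export
callable_mask <- function(tracks, mean_coverage, window,
                          params = pipeline_params()) {
  if (!is.numeric(window) || window < 1) stop("window size must be positive")
  if (!is.numeric(mean_coverage) || mean_coverage <= 0)
    stop("mean_coverage must be > 0")
  if (inherits(tracks, "depth_track")) tracks <- list(tracks)
  lo <- mean_coverage * params$depth_low_factor
  hi <- mean_coverage * params$depth_high_factor
  out <- lapply(tracks, function(tr) {
    pos <- seq(tr$region$start, tr$region$end)
    wi <- (pos - 1) %/% window
    ok <- tr$depth > lo & tr$depth < hi
    agg <- data.table::data.table(wi = wi, ok = ok)[, list(
      callable = sum(ok), n = .N), by = "wi"]
    data.table::data.table(chrom = tr$region$chrom,
                           start = agg$wi * window + 1,
                           end = pmin((agg$wi + 1) * window, tr$region$end),
                           window_bp = agg$n,
                           callable = as.numeric(agg$callable))
  })
  data.table::rbindlist(out)[]
}

#' Coverage-corrected windowed heterozygosity
#'
#' Joins heterozygous-site counts onto a callable mask of the same window
#' size. `het = n_het / callable`; windows whose callable fraction falls
#' below `min_callable_fraction` (60%) are flagged `excluded` and do not
#' enter the genome mean, which is the callable-weighted value
#' `sum(n_het) / sum(callable)` over retained windows.
#'
#' @param het_sites `data.frame` with `chrom`, `pos` of heterozygous
#'   bi-allelic SNPs (post-filtering), or a [variant_table()] plus `sample`.
#' @param mask output of [callable_mask()] at the same window size.
#' @param params a [pipeline_params()].
#' @param sample sample name when `het_sites` is a `variant_table`.
#' @return a `het_windows` `data.table` (`chrom`, `start`, `end`,
#'   `window_bp`, `callable`, `n_het`, `het`, `excluded`) with the genome
#'   mean in `attr(, "genome_mean_het")`.
#' @export
window_heterozygosity <- function(het_sites, mask, params = pipeline_params(),
                                  sample = NULL) {
  if (inherits(het_sites, "variant_table")) {
    if (is.null(sample)) sample <- vcf_samples(het_sites)[1]
    gcol <- paste0("gt.", sample)
    if (is.null(sample) || !gcol %in% names(het_sites))
      stop("variant table lacks a genotype column for the requested sample")
    het_sites <- het_sites[is_het(het_sites[[gcol]]),
                           c("chrom", "pos"), with = FALSE]
  }
  hs <- data.table::as.data.table(het_sites)
  w <- data.table::as.data.table(mask)
  window <- max(w$window_bp)
  if (nrow(hs)) {
    hs <- data.table::copy(hs)
    hs[, "start" := (hs$pos - 1) %/% window * window + 1]
    cnt <- hs[, list(n_het = .N), by = c("chrom", "start")]
    w <- merge(w, cnt, by = c("chrom", "start"), all.x = TRUE, sort = FALSE)
    w[is.na(w$n_het), "n_het" := 0L]
    if (sum(w$n_het) != nrow(hs))
      stop("heterozygous sites fall outside the callable mask windows")
  } else {
    w[, "n_het" := 0L]
  }
  w[, "het" := ifelse(w$callable > 0, w$n_het / w$callable, NA_real_)]
  w[, "excluded" := w$callable / w$window_bp < params$min_callable_fraction]
  gm <- with(w[!w$excluded & w$callable > 0, ], sum(n_het) / sum(callable))
  data.table::setattr(w, "genome_mean_het", gm)
  data.table::setattr(w, "class", unique(c("het_windows", class(w))))
  w[]
}

#' @rdname window_heterozygosity
#' @param x a `het_windows` table.
#' @export
genome_mean_het <- function(x) attr(x, "genome_mean_het", exact = TRUE)

#' Call runs of homozygosity with a relaxed-peak merge rule
#'
#' Operates per chromosome on contiguous runs of non-excluded windows
#' (excluded low-callable windows break runs; ROH are never called through
#' them). Within each run:
#'
#' 1. windows with `het <= ceiling` are seeds, where
#'    `ceiling = roh_het_ceiling_factor * genome_mean_het`;
#' 2. an admissible segment runs from one seed window to a later seed
#'    window, absorbing every intervening heterozygosity peak, provided the
#'    callable-weighted mean heterozygosity of the whole span stays
#'    strictly `< ceiling`;
#' 3. a dynamic program selects the disjoint admissible segments that
#'    maximize the total covered length (ties resolved toward longer,
#'    leftmost segments), and emits them with window-span coordinates.
#'
#' This relaxation admits isolated heterozygosity peaks (e.g. local
#' assembly or alignment errors) into an ROH as long as they do not inflate
#' its overall heterozygosity. Maximizing total covered length (rather
#' than merging candidate runs greedily) makes the call set respond
#' monotonically when heterozygosity is scaled down.
#'
#' @param hw a `het_windows` table at the ROH window size (10 kb).
#' @param genome_mean genome mean heterozygosity; defaults to the value
#'   attached to `hw`.
#' @param params a [pipeline_params()].
#' @return `data.table` of ROH segments: `chrom`, `start`, `end`, `length`,
#'   `n_windows`, `mean_het`; sorted and non-overlapping.
#' @export
call_roh <- function(hw, genome_mean = genome_mean_het(hw),
                     params = pipeline_params()) {
  if (!is.numeric(genome_mean) || is.na(genome_mean))
    stop("genome mean heterozygosity unavailable")
  if (genome_mean <= 0) {
    ok <- hw[!hw$excluded & hw$callable > 0, ]
    if (nrow(ok) && any(ok$n_het > 0))
      stop("genome mean heterozygosity <= 0 with heterozygous windows present")
  }
  ceiling_het <- params$roh_het_ceiling_factor * genome_mean
  segs <- list()
  hw2 <- hw[order(match(hw$chrom, unique(hw$chrom)), hw$start)]
  for (d in split(hw2, by = "chrom", sorted = FALSE)) {
    usable <- !d$excluded & d$callable > 0
    run_id <- cumsum(!usable)
    for (run in split(d[usable], run_id[usable])) {
      if (!nrow(run)) next
      segs[[length(segs) + 1L]] <- .roh_merge_run(run, ceiling_het, genome_mean)
    }
  }
  out <- data.table::rbindlist(segs)
  if (!nrow(out))
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), length = numeric(),
                                  n_windows = integer(), mean_het = numeric()))
  out <- out[order(match(out$chrom, unique(hw2$chrom)), out$start)]
  out[]
}

# Relaxed-peak segment selection within one unbroken run of usable
# windows. `run` has columns start, end, n_het, callable, het.
#
# Dynamic program over seed windows: an admissible segment spans seed
# window j to seed window i (absorbing all intervening peak windows) and
# must keep its callable-weighted mean het strictly below the ceiling; we
# choose the disjoint admissible segments maximizing total covered bp.
# Because scaling every window's het down only enlarges the admissible
# set, total ROH length responds monotonically — a guarantee the simpler
# greedy best-merge-first heuristic does not give.
.roh_merge_run <- function(run, ceiling_het, genome_mean) {
  empty <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), length = numeric(),
                                  n_windows = integer(), mean_het = numeric())
  if (genome_mean <= 0) {
    # degenerate: only an all-zero run is an ROH
    if (any(run$n_het > 0)) return(empty)
    return(data.table::data.table(
      chrom = run$chrom[1], start = run$start[1], end = run$end[nrow(run)],
      length = run$end[nrow(run)] - run$start[1] + 1,
      n_windows = nrow(run), mean_het = 0))
  }
  seed_idx <- which(run$het <= ceiling_het)
  S <- length(seed_idx)
  if (S == 0L) return(empty)
  cum_h <- c(0, cumsum(run$n_het))
  cum_c <- c(0, cumsum(run$callable))
  w_start <- run$start[seed_idx]
  w_end <- run$end[seed_idx]
  # best[i+1]: max covered bp using seeds 1..i; choice[i]: 0 = skip seed i,
  # j >= 1 = emit segment spanning seeds j..i (smallest such j on ties, so
  # equal-value solutions prefer the longer, leftmost segment)
  best <- numeric(S + 1L)
  choice <- integer(S)
  for (i in seq_len(S)) {
    js <- seq_len(i)
    h <- cum_h[seed_idx[i] + 1L] - cum_h[seed_idx[js]]
    cc <- cum_c[seed_idx[i] + 1L] - cum_c[seed_idx[js]]
    ok <- h < ceiling_het * cc
    best_i <- best[i]          # skip seed i
    choice_i <- 0L
    if (any(ok)) {
      val <- best[js[ok]] + (w_end[i] - w_start[js[ok]] + 1)
      k <- which.max(val)      # which.max takes the first (smallest j) on ties
      if (val[k] >= best_i) { best_i <- val[k]; choice_i <- js[ok][k] }
    }
    best[i + 1L] <- best_i
    choice[i] <- choice_i
  }
  segs <- list()
  i <- S
  while (i >= 1L) {
    j <- choice[i]
    if (j == 0L) { i <- i - 1L; next }
    h <- cum_h[seed_idx[i] + 1L] - cum_h[seed_idx[j]]
    cc <- cum_c[seed_idx[i] + 1L] - cum_c[seed_idx[j]]
    segs[[length(segs) + 1L]] <- data.table::data.table(
      chrom = run$chrom[1], start = w_start[j], end = w_end[i],
      length = w_end[i] - w_start[j] + 1,
      n_windows = seed_idx[i] - seed_idx[j] + 1L, mean_het = h / cc)
    i <- j - 1L
  }
  if (!length(segs)) return(empty)
  out <- data.table::rbindlist(rev(segs))
  out[out$mean_het < ceiling_het, ]
}

#' Summarize ROH: totals, long-ROH tally and F_ROH
#'
#' The realized genomic inbreeding coefficient is
#' `F_ROH = sum(length of autosomal ROH >= min_roh_length) / L`, with `L`
#' the total length of the flagged autosomes (`autosome_length_L`,
#' 2,682,350,267 bp for the wisent reference case). `n_long` counts
#' segments strictly longer than `long_roh_length` (2 Mb).
#'
#' @param segments ROH table from [call_roh()] (autosomes only).
#' @param params a [pipeline_params()]; `autosome_length_L` is the F_ROH
#'   denominator.
#' @param breaks histogram break points for segment lengths (bp).
#' @return a `roh_summary` list: `total_roh_bp`, `n_segments`, `n_long`,
#'   `froh`, `length_histogram`.
#' @export
summarize_roh <- function(segments, params = pipeline_params(),
                          breaks = c(0, 1e5, 2e5, 5e5, 1e6, 2e6, 5e6, Inf)) {
  len <- if (nrow(segments)) segments$end - segments$start + 1 else numeric(0)
  qual <- len >= params$min_roh_length
  froh <- sum(len[qual]) / params$autosome_length_L
  if (froh > 1) stop("F_ROH > 1: check autosome_length_L against the layout")
  hist <- table(cut(len, breaks = breaks, right = TRUE))
  structure(list(total_roh_bp = sum(len),
                 n_segments = length(len),
                 n_long = sum(len > params$long_roh_length),
                 froh = froh,
                 length_histogram = hist),
            class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat(sprintf(
    "<roh_summary> %d segments, %.3g bp total; %d longer than 2 Mb; F_ROH = %.4f\n",
    x$n_segments, x$total_roh_bp, x$n_long, x$froh))
  invisible(x)
}
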