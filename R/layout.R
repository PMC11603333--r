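# Genome layout and region handling: the coordinate frame shared by every
# windowed statistic in the package. All in-memory coordinates are 1-based
# inclusive (VCF convention); BED output is converted on write.

#' Genome layout
#'
#' An ordered set of chromosomes with lengths and an autosome flag. The
#' layout defines the coordinate frame for all windowed computations, and
#' the flagged autosomes define the denominator used by [froh()]-style
#' statistics.
#'
#' @param chrom character vector of unique chromosome names, in genome order.
#' @param length integer-ish vector of chromosome lengths in bp, all > 0.
#' @param autosome logical vector (recycled) flagging autosomes; sex
#'   chromosomes and unplaced scaffolds should be `FALSE`.
#'
#' @return A `genome_layout` object (a `data.table` with columns `chrom`,
#'   `length`, `autosome`).
#' @examples
#' genome_layout(c("1", "2", "X"), c(1e6, 8e5, 5e5), c(TRUE, TRUE, FALSE))
#' @export
genome_layout <- function(chrom, length, autosome = TRUE) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length)))
    stop("chromosome lengths must be positive integers")
  autosome <- rep_len(as.logical(autosome), length(chrom))
  lay <- data.table::data.table(chrom = chrom, length = length, autosome = autosome)
  data.table::setattr(lay, "class", c("genome_layout", class(lay)))
  lay[]
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosomes (%d autosomes), %.0f bp total\n",
              nrow(x), sum(x$autosome), sum(x$length)))
  NextMethod()
}

.layout_check <- function(layout) {
  if (!inherits(layout, "genome_layout")) stop("expected a genome_layout")
  invisible(layout)
}

#' Total length of the flagged autosomes
#'
#' @param layout a [genome_layout()].
#' @return total autosomal length in bp.
#' @export
autosome_length <- function(layout) {
  .layout_check(layout)
  sum(layout$length[layout$autosome])
}

.chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

#' Genomic region (1-based, inclusive)
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds, `1 <= start <= end`.
#' @param layout optional [genome_layout()]; when given, `chrom` must exist
#'   and `end` must not exceed the chromosome length.
#' @return a `region` object.
#' @export
region <- function(chrom, start, end, layout = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop("region() is scalar")
  if (!is.finite(start) || !is.finite(end) || start != floor(start) || end != floor(end))
    stop("region bounds must be integers")
  if (start < 1) stop("region start must be >= 1")
  if (start > end) stop(sprintf("region start (%.0f) exceeds end (%.0f)", start, end))
  if (!is.null(layout)) {
    len <- .chrom_length(layout, chrom)
    if (end > len)
      stop(sprintf("region end %.0f exceeds length of chromosome %s (%.0f)",
                   end, chrom, len))
  }
  structure(list(chrom = chrom, start = start, end = end), class = "region")
}

#' Parse a samtools-style region string
#'
#' Accepts `chrom:start-end` with 1-based inclusive bounds, the convention
#' used by `samtools depth -r` (e.g. `"29:17990000-18000000"`).
#'
#' @param text region string.
#' @inheritParams region
#' @return a [region()].
#' @examples
#' r <- parse_region("29:17990000-18000000")
#' region_length(r)  # 10000001
#' @export
parse_region <- function(text, layout = NULL) {
  if (length(text) != 1L || !is.character(text)) stop("expected one region string")
  m <- regmatches(text, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", text))[[1]]
  if (length(m) != 4L)
    stop("malformed region string (expected chrom:start-end): ", text)
  region(m[2], as.numeric(m[3]), as.numeric(m[4]), layout = layout)
}

#' @rdname parse_region
#' @param x a `region`.
#' @export
region_length <- function(x) {
  stopifnot(inherits(x, "region"))
  x$end - x$start + 1
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s:%.0f-%.0f (%.0f bp)\n",
              x$chrom, x$start, x$end, region_length(x)))
  invisible(x)
}

#' @export
format.region <- function(x, ...) sprintf("%s:%.0f-%.0f", x$chrom, x$start, x$end)

.region_contains <- function(outer, inner) {
  outer$chrom == inner$chrom && outer$start <= inner$start && inner$end <= outer$end
}

#' Tile a genome layout with fixed-size windows
#'
#' Windows tumble (step = size) from position 1 on each chromosome. A
#' trailing window shorter than `size` is kept and flagged `partial` by
#' default; with `keep_partial = FALSE` it is dropped.
#'
#' @param layout a [genome_layout()].
#' @param size window size in bp.
#' @param autosomes_only restrict to flagged autosomes.
#' @param keep_partial keep (and flag) the trailing sub-`size` window.
#' @return `data.table` with `chrom`, `start`, `end`, `partial`.
#' @export
tile_windows <- function(layout, size, autosomes_only = FALSE, keep_partial = TRUE) {
  .layout_check(layout)
  size <- as.numeric(size)
  if (!is.finite(size) || size < 1) stop("window size must be a positive integer")
  lay <- if (autosomes_only) layout[layout$autosome, ] else layout
  out <- lapply(seq_len(nrow(lay)), function(i) {
    len <- lay$length[i]
    starts <- seq(1, len, by = size)
    ends <- pmin(starts + size - 1, len)
    data.table::data.table(chrom = lay$chrom[i], start = starts, end = ends,
                           partial = ends - starts + 1 < size)
  })
  out <- data.table::rbindlist(out)
  if (!keep_partial) out <- out[!out$partial]
  out[]
}
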