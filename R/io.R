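# On-disk formats: samtools-depth-style TSV, tagged-read TSV, BED.
# Readers reject malformed input rather than repairing it silently.

#' Per-base depth track
#'
#' A dense vector of per-base depths over a [region()], one value per
#' position (the output shape of `samtools depth -aa` restricted to one
#' chromosome or region).
#'
#' @param region a [region()].
#' @param depth numeric vector of non-negative depths, one per base.
#' @return a `depth_track` object.
#' @export
depth_track <- function(region, depth) {
  stopifnot(inherits(region, "region"))
  depth <- as.numeric(depth)
  if (length(depth) != region_length(region))
    stop(sprintf("depth length (%d) != region length (%.0f)",
                 length(depth), region_length(region)))
  if (anyNA(depth) || any(depth < 0)) stop("depths must be non-negative")
  structure(list(region = region, depth = depth), class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %s, mean depth %.2f\n",
              format(x$region), mean(x$depth)))
  invisible(x)
}

#' Read a samtools-depth-style table into dense depth tracks
#'
#' Expects the three-column output of `samtools depth -aa` (chromosome,
#' 1-based position, depth), sorted, with every position present. Gaps,
#' duplicated positions or negative depths are errors: the normalization
#' and callable-mask arithmetic assume complete per-base output.
#'
#' @param path TSV file (no header): chrom, pos, depth.
#' @param region optional [region()]; when given, exactly that region must
#'   be covered and a single `depth_track` is returned.
#' @return a named list of `depth_track` (one per chromosome), or a single
#'   `depth_track` when `region` is supplied.
#' @export
read_depth_table <- function(path, region = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "depth"),
                          colClasses = list(character = 1, numeric = 2:3))
  if (nrow(dt) == 0L) stop("empty depth table: ", path)
  if (anyNA(dt)) stop("malformed depth table (NA values): ", path)
  if (any(dt$depth < 0)) stop("negative depth in ", path)
  tracks <- lapply(split(dt, by = "chrom", sorted = FALSE), function(d) {
    if (is.unsorted(d$pos)) stop("depth table not position-sorted: ", path)
    if (anyDuplicated(d$pos)) stop("duplicate positions in depth table: ", path)
    if (nrow(d) != d$pos[nrow(d)] - d$pos[1] + 1)
      stop("depth table has gaps (need samtools depth -aa style output): ", path)
    depth_track(region(d$chrom[1], d$pos[1], d$pos[nrow(d)]), d$depth)
  })
  if (is.null(region)) return(tracks)
  tr <- tracks[[region$chrom]]
  if (is.null(tr)) stop("region chromosome absent from depth table: ", region$chrom)
  if (tr$region$start > region$start || tr$region$end < region$end)
    stop("depth table does not cover region ", format(region))
  idx <- (region$start - tr$region$start + 1):(region$end - tr$region$start + 1)
  depth_track(region, tr$depth[idx])
}

#' @rdname read_depth_table
#' @param tracks a `depth_track` or list of them.
#' @export
write_depth_table <- function(tracks, path) {
  if (inherits(tracks, "depth_track")) tracks <- list(tracks)
  dt <- data.table::rbindlist(lapply(tracks, function(tr) {
    data.table::data.table(chrom = tr$region$chrom,
                           pos = seq(tr$region$start, tr$region$end),
                           depth = tr$depth)
  }))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read haplotype-tagged read starts
#'
#' Three-column TSV (chrom, 1-based alignment start, tag) where tag is one
#' of `paternal`, `maternal`, `unassigned`. Extracting these from alignment
#' files (e.g. from trio-binning haplotagged BAMs) is a documented pre-step
#' outside this package.
#'
#' @param path TSV file, no header.
#' @param layout optional [genome_layout()] used to validate coordinates.
#' @return `data.table` with `chrom`, `start`, `tag` (factor).
#' @export
read_tagged_reads <- function(path, layout = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "tag"),
                          colClasses = list(character = c(1, 3), numeric = 2))
  .validate_tagged_reads(dt, layout)
}

.tag_levels <- c("paternal", "maternal", "unassigned")

.validate_tagged_reads <- function(dt, layout = NULL) {
  dt <- data.table::as.data.table(dt)
  if (!all(c("chrom", "start", "tag") %in% names(dt)))
    stop("tagged reads need columns chrom, start, tag")
  if (anyNA(dt$start) || any(dt$start < 1)) stop("read starts must be >= 1")
  bad <- setdiff(unique(as.character(dt$tag)), .tag_levels)
  if (length(bad)) stop("unknown read tag(s): ", paste(bad, collapse = ", "))
  dt[, "tag" := factor(as.character(dt$tag), levels = .tag_levels)]
  if (!is.null(layout)) {
    lens <- .chrom_length(layout, dt$chrom)
    if (any(dt$start > lens)) stop("read start beyond chromosome end")
  }
  dt[]
}

#' @rdname read_tagged_reads
#' @param reads the `data.table` to write.
#' @export
write_tagged_reads <- function(reads, path) {
  data.table::fwrite(reads[, c("chrom", "start", "tag")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write 1-based inclusive segments as BED
#'
#' Converts 1-based inclusive segments `[s, e]` to BED's 0-based half-open
#' `(s - 1, e]`. Segments must be sorted and non-overlapping within each
#' chromosome; anything else is an error, not repaired.
#'
#' @param segments `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive); extra columns are appended as additional BED fields.
#' @param path output file.
#' @export
write_bed <- function(segments, path) {
  seg <- data.table::as.data.table(segments)
  if (nrow(seg)) {
    if (any(seg$start < 1) || any(seg$end < seg$start))
      stop("segments must satisfy 1 <= start <= end")
    .check_disjoint_sorted(seg)
  }
  out <- data.table::copy(seg)
  out[, "start" := out$start - 1]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

.check_disjoint_sorted <- function(seg) {
  for (d in split(seg, by = "chrom", sorted = FALSE)) {
    if (is.unsorted(d$start, strictly = FALSE))
      stop("segments not sorted by start within chromosome ", d$chrom[1])
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping segments on chromosome ", d$chrom[1])
  }
  invisible(seg)
}

#' @rdname write_bed
#' @return `read_bed()` returns a `data.table` with 1-based inclusive
#'   `chrom`, `start`, `end` (plus any extra columns).
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric()))
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
  dt[, "chrom" := as.character(dt$chrom)]
  dt[, "start" := as.numeric(dt$start) + 1]
  dt[, "end" := as.numeric(dt$end)]
  dt[]
}
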