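# Small-variant post-filtering, reproducing the study's chain:
# depth-based genotype masking -> InDel proximity filter -> site quality and
# allele-count filters -> bi-allelic autosomal SNP selection.
# Each record is removed at most once, attributed to the first failing rule.

#' Mask genotypes outside the normal coverage range
#'
#' Sets a sample's genotype to missing iff its depth is `< mean/3` or
#' `> 2.5 x mean` genome coverage (both strict; the factors are
#' `depth_low_factor` / `depth_high_factor`). A missing depth field also
#' masks the genotype. Records are never removed here. The cohort allele
#' count is recomputed from the surviving genotypes, since masking precedes
#' the allele-count filter.
#'
#' @param vt a [variant_table()].
#' @param mean_coverage average genome coverage (> 0).
#' @param params a [pipeline_params()].
#' @return list with `records` (masked table) and `n_genotypes_masked`.
#' @export
mask_genotypes_by_depth <- function(vt, mean_coverage, params = pipeline_params()) {
  if (!is.numeric(mean_coverage) || mean_coverage <= 0)
    stop("mean_coverage must be > 0")
  lo <- mean_coverage * params$depth_low_factor
  hi <- mean_coverage * params$depth_high_factor
  out <- data.table::copy(vt)
  masked <- 0L
  for (s in vcf_samples(vt)) {
    gcol <- paste0("gt.", s); dcol <- paste0("dp.", s)
    dp <- out[[dcol]]
    bad <- (is.na(dp) | dp < lo | dp > hi) & !is.na(out[[gcol]])
    masked <- masked + sum(bad)
    if (any(bad)) out[bad, (gcol) := NA_character_]
  }
  out[, "ac" := recompute_ac(out)]
  list(records = out[], n_genotypes_masked = masked)
}

#' Remove variants too close to InDels
#'
#' Discards SNPs whose VCF POS lies strictly closer than `proximity_bp`
#' (default 5 bp) to the POS of any InDel, and InDels strictly closer than
#' `proximity_bp` to another InDel. Distances are anchor-POS distances and
#' every removal is judged against the original (pre-filter) record set, so
#' an InDel that itself gets removed still masks its neighbours.
#'
#' @param vt a coordinate-sorted [variant_table()].
#' @param params a [pipeline_params()].
#' @return list with `records` and `n_removed_proximity`.
#' @export
proximity_filter <- function(vt, params = pipeline_params()) {
  keep <- rep(TRUE, nrow(vt))
  for (d in split(seq_len(nrow(vt)), vt$chrom)) {
    pos <- vt$pos[d]
    if (is.unsorted(pos)) stop("records must be coordinate-sorted per chromosome")
    is_indel <- vt$class[d] == "InDel"
    ipos <- pos[is_indel]
    if (!length(ipos)) next
    near_snp <- .min_dist(pos[!is_indel], ipos) < params$proximity_bp
    # for an InDel, distance to *another* InDel: exclude self
    near_ind <- .min_dist_excl_self(ipos) < params$proximity_bp
    drop <- logical(length(pos))
    drop[!is_indel] <- near_snp
    drop[is_indel] <- near_ind
    keep[d[drop]] <- FALSE
  }
  list(records = vt[keep], n_removed_proximity = sum(!keep))
}

# Minimum |a - b| from each element of `a` to the sorted vector `b`.
.min_dist <- function(a, b) {
  if (!length(a)) return(numeric(0))
  if (!length(b)) return(rep(Inf, length(a)))
  i <- findInterval(a, b)
  left <- ifelse(i >= 1, a - b[pmax(i, 1)], Inf)
  right <- ifelse(i < length(b), b[pmin(i + 1, length(b))] - a, Inf)
  pmin(left, right)
}

# Minimum distance from each element of sorted `p` to any *other* element,
# honouring duplicates (distance 0 if another record shares the POS).
.min_dist_excl_self <- function(p) {
  n <- length(p)
  if (n <= 1L) return(rep(Inf, n))
  gap_prev <- c(Inf, diff(p))
  gap_next <- c(diff(p), Inf)
  pmin(gap_prev, gap_next)
}

#' Site quality and allele-count filter
#'
#' Removes records with PHRED site quality `< min_site_qual` (30) or cohort
#' allele count `< min_allele_count` (2), both strict. Quality is judged
#' first; a record failing both is attributed to the quality rule.
#'
#' @inheritParams proximity_filter
#' @return list with `records`, `n_removed_qual`, `n_removed_ac`.
#' @export
quality_ac_filter <- function(vt, params = pipeline_params()) {
  ac <- vt$ac
  if (anyNA(ac)) ac[is.na(ac)] <- recompute_ac(vt[is.na(ac)])
  bad_qual <- is.na(vt$qual) | vt$qual < params$min_site_qual
  bad_ac <- !bad_qual & ac < params$min_allele_count
  list(records = vt[!(bad_qual | bad_ac)],
       n_removed_qual = sum(bad_qual),
       n_removed_ac = sum(bad_ac))
}

#' Keep bi-allelic autosomal SNPs
#'
#' Retains records with exactly one alternate allele, SNP class, and a
#' chromosome flagged autosomal in the layout — the set used for all
#' downstream heterozygosity statistics.
#'
#' @inheritParams proximity_filter
#' @param layout a [genome_layout()] with autosome flags.
#' @return list with `records` and `n_removed_nonsnp`.
#' @export
select_biallelic_autosomal_snps <- function(vt, layout) {
  .layout_check(layout)
  autosomes <- layout$chrom[layout$autosome]
  n_alt <- lengths(strsplit(vt$alt, ",", fixed = TRUE))
  keep <- n_alt == 1L & vt$class == "SNP" & vt$chrom %in% autosomes
  list(records = vt[keep], n_removed_nonsnp = sum(!keep))
}

#' Run the full post-filter chain
#'
#' Order: depth masking, InDel proximity, quality/allele-count, bi-allelic
#' autosomal SNP selection. The report partitions the input exactly.
#'
#' @inheritParams mask_genotypes_by_depth
#' @param layout a [genome_layout()].
#' @return list with `records` (final set) and `report` (a `filter_report`:
#'   `n_input`, `n_genotypes_masked`, `n_removed_proximity`,
#'   `n_removed_qual`, `n_removed_ac`, `n_removed_nonsnp`,
#'   `n_retained_final`).
#' @export
filter_variants <- function(vt, layout, mean_coverage,
                            params = pipeline_params()) {
  n_input <- nrow(vt)
  m <- mask_genotypes_by_depth(vt, mean_coverage, params)
  p <- proximity_filter(m$records, params)
  q <- quality_ac_filter(p$records, params)
  b <- select_biallelic_autosomal_snps(q$records, layout)
  report <- structure(list(
    n_input = n_input,
    n_genotypes_masked = m$n_genotypes_masked,
    n_removed_proximity = p$n_removed_proximity,
    n_removed_qual = q$n_removed_qual,
    n_removed_ac = q$n_removed_ac,
    n_removed_nonsnp = b$n_removed_nonsnp,
    n_retained_final = nrow(b$records)), class = "filter_report")
  stopifnot(report$n_retained_final ==
              n_input - report$n_removed_proximity - report$n_removed_qual -
              report$n_removed_ac - report$n_removed_nonsnp)
  list(records = b$records, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %d\n", nm, x[[nm]]))
  invisible(x)
}
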