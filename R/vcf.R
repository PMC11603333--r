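# Small-variant VCF input/output. Reading is backed by
# VariantAnnotation::readVcf; records are held in a flat data.table (one row
# per VCF record, multi-allelic sites preserved) with one genotype and one
# depth column per sample. Only the fields consumed downstream are modelled.

#' Construct a variant table
#'
#' The in-memory form of a small-variant call set: a `data.table` with one
#' row per VCF record and columns `chrom`, `pos`, `ref`, `alt`
#' (comma-joined), `qual`, `ac`, `class` (`"SNP"` or `"InDel"`), plus
#' `gt.<sample>` (genotype string, `NA` = missing) and `dp.<sample>`
#' (read depth) for every sample. Sample names are kept in the `"samples"`
#' attribute.
#'
#' @param dt a `data.frame` with the columns above.
#' @param samples character vector of sample names.
#' @return a `variant_table`.
#' @export
variant_table <- function(dt, samples) {
  dt <- data.table::as.data.table(dt)
  need <- c("chrom", "pos", "ref", "alt", "qual", "ac")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(dt) && (anyNA(dt$pos) || any(dt$pos < 1))) stop("POS must be >= 1")
  for (s in samples) {
    for (col in paste0(c("gt.", "dp."), s))
      if (!col %in% names(dt)) stop("missing per-sample column: ", col)
  }
  if (!"class" %in% names(dt))
    dt[, "class" := variant_class(dt$ref, dt$alt)]
  data.table::setattr(dt, "samples", as.character(samples))
  data.table::setattr(dt, "class", unique(c("variant_table", class(dt))))
  dt[]
}

#' @rdname variant_table
#' @param x a `variant_table`.
#' @export
vcf_samples <- function(x) attr(x, "samples", exact = TRUE)

#' Classify variants as SNP or InDel from allele lengths
#'
#' A record is a SNP iff the reference allele and every alternate allele
#' are single bases; anything else (including mixed multi-allelic records)
#' is an InDel.
#'
#' @param ref reference alleles.
#' @param alt alternate alleles, comma-joined when multi-allelic.
#' @return character vector, `"SNP"` or `"InDel"`.
#' @export
variant_class <- function(ref, alt) {
  alts <- strsplit(as.character(alt), ",", fixed = TRUE)
  snp <- nchar(ref) == 1L &
    vapply(alts, function(a) length(a) > 0L && all(nchar(a) == 1L), logical(1))
  ifelse(snp, "SNP", "InDel")
}

# Split a diploid/haploid genotype string into integer allele indexes.
# Any "." allele (or NA) makes the whole genotype missing (NULL).
.gt_alleles <- function(gt) {
  lapply(gt, function(g) {
    if (is.na(g)) return(NULL)
    a <- strsplit(g, "[/|]")[[1]]
    if (length(a) == 0L || any(a == ".")) return(NULL)
    suppressWarnings(ai <- as.integer(a))
    if (anyNA(ai)) stop("malformed genotype: ", g)
    ai
  })
}

#' Is a genotype heterozygous?
#'
#' @param gt genotype strings (`NA` = missing).
#' @return logical; `FALSE` for missing genotypes.
#' @export
is_het <- function(gt) {
  vapply(.gt_alleles(gt), function(a) !is.null(a) && length(unique(a)) > 1L,
         logical(1))
}

#' Recompute the cohort allele count from genotypes
#'
#' Counts non-reference alleles over all non-missing genotypes of all
#' samples, the AC a caller would emit after genotype masking.
#'
#' @param vt a [variant_table()].
#' @return integer vector of allele counts.
#' @export
recompute_ac <- function(vt) {
  samples <- vcf_samples(vt)
  ac <- integer(nrow(vt))
  for (s in samples) {
    al <- .gt_alleles(vt[[paste0("gt.", s)]])
    ac <- ac + vapply(al, function(a) if (is.null(a)) 0L else sum(a > 0L),
                      integer(1))
  }
  ac
}

#' Read a VCF into a variant table
#'
#' Backed by `VariantAnnotation::readVcf()`. Records come back in file
#' order with multi-allelic sites preserved as single rows. The cohort
#' allele count is taken from `INFO/AC` when present (summed over alternate
#' alleles) and recomputed from the genotypes otherwise. A missing `GT`
#' field is an error; per-sample depth is read from `FORMAT/DP` and `NA`
#' when absent.
#'
#' @param path a VCF file (plain text or bgzipped).
#' @return a [variant_table()].
#' @export
read_variants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gr <- SummarizedExperiment::rowRanges(vcf)
  g <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(g)) stop("VCF lacks a GT FORMAT field: ", path)
  n <- length(gr)
  alt <- VariantAnnotation::alt(vcf)
  alt_chr <- vapply(as(alt, "CharacterList"), paste, character(1), collapse = ",")
  info <- VariantAnnotation::info(vcf)
  samples <- colnames(g$GT)
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    pos   = BiocGenerics::start(gr),
    ref   = as.character(VariantAnnotation::ref(vcf)),
    alt   = alt_chr,
    qual  = as.numeric(VariantAnnotation::qual(vcf)))
  gt <- g$GT
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  dp <- if ("DP" %in% names(g)) g$DP else
    matrix(NA_real_, n, length(samples), dimnames = list(NULL, samples))
  for (s in samples) {
    dt[, (paste0("gt.", s)) := as.character(gt[, s])]
    dt[, (paste0("dp.", s)) := as.numeric(dp[, s])]
  }
  if ("AC" %in% names(info)) {
    dt[, "ac" := vapply(info$AC, function(a) sum(as.numeric(a)), numeric(1))]
  } else {
    dt[, "ac" := NA_real_]
  }
  vt <- variant_table(dt, samples)
  if (anyNA(vt$ac)) vt[is.na(vt$ac), "ac" := recompute_ac(vt[is.na(vt$ac)])]
  vt[]
}

#' Write a variant table as a minimal VCF
#'
#' Emits only the fields this pipeline consumes: `QUAL`, `INFO/AC`,
#' `FORMAT GT:DP`. Not a spec-complete VCF writer.
#'
#' @param vt a [variant_table()].
#' @param path output file.
#' @param layout optional [genome_layout()] for `##contig` header lines.
#' @export
write_variants <- function(vt, path, layout = NULL) {
  samples <- vcf_samples(vt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rohpan",
    if (!is.null(layout))
      sprintf("##contig=<ID=%s,length=%.0f>", layout$chrom, layout$length),
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count in genotypes\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (nrow(vt)) {
    fields <- lapply(samples, function(s) {
      gt <- vt[[paste0("gt.", s)]]
      dp <- vt[[paste0("dp.", s)]]
      gt[is.na(gt)] <- "./."
      dps <- ifelse(is.na(dp), ".", format(dp, trim = TRUE, scientific = FALSE))
      paste0(gt, ":", dps)
    })
    lines <- do.call(paste, c(list(
      vt$chrom, format(vt$pos, trim = TRUE, scientific = FALSE), ".",
      vt$ref, vt$alt,
      ifelse(is.na(vt$qual), ".", format(vt$qual, trim = TRUE, scientific = FALSE)),
      ".", sprintf("AC=%.0f", vt$ac), "GT:DP"), fields, list(sep = "\t")))
    writeLines(lines, con)
  }
  invisible(path)
}
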