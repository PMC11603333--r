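# Pipeline parameters: every threshold used downstream lives here, with the
# defaults of the wisent reference analysis.

.param_defaults <- list(
  phase_window           = 1e5,        # bp, trio-binning diagnostic windows
  het_window             = 1e6,        # bp, heterozygosity windows
  roh_window             = 1e4,        # bp, ROH windows
  depth_low_factor       = 1 / 3,      # callable iff depth > mean * low
  depth_high_factor      = 2.5,        #              and depth < mean * high
  min_callable_fraction  = 0.60,       # window exclusion rule
  roh_het_ceiling_factor = 0.25,       # ROH het ceiling, x genome mean het
  min_roh_length         = 1e5,        # bp, ROH entering F_ROH
  long_roh_length        = 2e6,        # bp, "long ROH" tally (strict >)
  bias_fold              = 5,          # parental read bias threshold (strict >)
  min_site_qual          = 30,         # PHRED site quality floor
  min_allele_count       = 2,          # cohort allele-count floor
  proximity_bp           = 5,          # SNP/InDel proximity exclusion (strict <)
  min_sample_coverage    = 5,          # fold; below -> low_confidence call
  min_sv_length          = 50,         # bp, SV length floor
  del_hom_max            = 0.25,       # normalized event coverage cutpoints
  del_het_max            = 0.75,
  autosome_length_L      = 2682350267  # bp, first 29 autosomes of the wisent reference
)

#' Pipeline parameters
#'
#' Assemble the full parameter set used across the pipeline, starting from
#' the defaults of the wisent reference analysis and overriding fields by
#' name. Unknown names are an error.
#'
#' Key fields: `phase_window` (100 kb trio-binning windows), `het_window`
#' (1 Mb heterozygosity windows), `roh_window` (10 kb ROH windows),
#' `depth_low_factor`/`depth_high_factor` (a genotype/base is within normal
#' coverage iff `mean/3 < depth < 2.5 * mean`, both strict),
#' `min_callable_fraction` (windows with < 60% callable bases are excluded),
#' `roh_het_ceiling_factor` (final ROH heterozygosity must stay below 0.25 of
#' the genome mean), `min_roh_length` (ROH >= 100 kb enter F_ROH),
#' `long_roh_length` (tally of ROH > 2 Mb), `bias_fold` (parental bias > 5x),
#' `min_site_qual`/`min_allele_count` (site filters, strict <30 / <2),
#' `proximity_bp` (variants closer than 5 bp to an InDel), `min_sv_length`
#' (50 bp SV floor), `min_sample_coverage` (5x floor for deletion calls),
#' `del_hom_max`/`del_het_max` (normalized-coverage genotype cutpoints) and
#' `autosome_length_L` (F_ROH denominator; 2,682,350,267 bp for the wisent
#' reference case).
#'
#' @param ... named overrides of individual fields.
#' @param config optional path to a YAML file whose top-level keys mirror
#'   the parameter names; explicit `...` overrides win over the file.
#' @return a validated `pipeline_params` list.
#' @examples
#' p <- pipeline_params(bias_fold = 10)
#' p$roh_window
#' @export
pipeline_params <- function(..., config = NULL) {
  p <- .param_defaults
  if (!is.null(config)) {
    y <- yaml::read_yaml(config)
    if (!is.list(y)) stop("config file must be a YAML mapping")
    p <- utils::modifyList(p, .check_param_names(y))
  }
  dots <- list(...)
  if (length(dots)) p <- utils::modifyList(p, .check_param_names(dots))
  .validate_params(p)
  structure(p, class = "pipeline_params")
}

.check_param_names <- function(x) {
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("parameter overrides must be named")
  bad <- setdiff(names(x), names(.param_defaults))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  lapply(x, as.numeric)
}

.validate_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all parameters must be numeric")
  if (any(vapply(p, function(v) !is.finite(v) || v <= 0, logical(1))))
    stop("all parameters must be positive and finite")
  if (p$depth_low_factor >= p$depth_high_factor)
    stop("depth_low_factor must be < depth_high_factor")
  if (p$roh_het_ceiling_factor >= 1)
    stop("roh_het_ceiling_factor must be in (0, 1)")
  if (p$min_callable_fraction > 1) stop("min_callable_fraction must be <= 1")
  if (p$del_hom_max >= p$del_het_max) stop("del_hom_max must be < del_het_max")
  invisible(p)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write parameters to a YAML config file
#'
#' @param params a [pipeline_params()] object.
#' @param path output file.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pipeline_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
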