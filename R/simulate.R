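# Seeded synthetic-data generator. Each generator emulates the statistical
# structure one pipeline stage assumes — not reads, alignments or LD — and
# returns machine-readable ground truth alongside the data so every stage
# has a recovery test. One global seed; each generator draws from its own
# sub-stream at a fixed offset so outputs do not couple.

.SEED_OFFSETS <- c(variants = 1L, depth = 2L, tags = 3L, sv = 4L)

.set_substream <- function(spec, what) {
  offset <- .SEED_OFFSETS[[what]]
  if (spec$seed + offset >= 2^31) stop("seed too large")
  set.seed(spec$seed + offset)
}

#' Simulation specification
#'
#' The stated world for all generators: a diploid genome with background
#' heterozygosity `mean_het` (per bp; default 1e-3, a typical bovine
#' genome-wide value), planted ROH retaining `residual_het_in_roh`
#' (default 5% of background, emulating the residual variant calls seen
#' inside true ROH), overdispersed short-read depth with mean `mean_depth`
#' and negative-binomial dispersion `depth_dispersion` (variance
#' `mu + dispersion * mu^2`; 0 means noise-free), per-window trio-binning
#' probabilities, optional embedded deletions and an SV-generating tree.
#'
#' @param layout a [genome_layout()].
#' @param seed integer master seed; fixes every output byte.
#' @param mean_het background heterozygosity per bp.
#' @param roh_segments `data.frame` (`chrom`, `start`, `end`) of truth ROH;
#'   must be non-overlapping and within the layout.
#' @param residual_het_in_roh heterozygosity per bp inside truth ROH.
#' @param mean_depth mean sequencing depth (fold).
#' @param depth_dispersion negative-binomial overdispersion coefficient.
#' @param binnability_profile probability a read is parental-assigned;
#'   scalar or one value per `phase_window` window.
#' @param parental_bias_profile probability an assigned read is paternal;
#'   scalar or one value per window.
#' @param phase_window window size for the trio-tag profiles (bp).
#' @param deletion_events list of `list(region =, genotype =)` with
#'   genotype one of `"hom"`, `"het"`, `"absent"`.
#' @param sv_tree list with `phylo` (a rooted [ape::phylo] tree) and
#'   `branch_counts` (integer vector, one SV count per edge of
#'   `phylo$edge`), optionally `root_count` for SVs on the root stem
#'   (present in every leaf).
#' @return a `sim_spec` object.
#' @export
sim_spec <- function(layout, seed = 1L, mean_het = 1e-3, roh_segments = NULL,
                     residual_het_in_roh = 0.05 * mean_het, mean_depth = 30,
                     depth_dispersion = 0.1, binnability_profile = 0.619,
                     parental_bias_profile = 0.5, phase_window = 1e5,
                     deletion_events = list(), sv_tree = NULL) {
  .layout_check(layout)
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed))
    stop("seed must be a single integer")
  if (mean_het < 0 || residual_het_in_roh < 0) stop("het rates must be >= 0")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  for (p in c(binnability_profile, parental_bias_profile))
    if (any(p < 0 | p > 1)) stop("profiles are probabilities in [0, 1]")
  if (!is.null(roh_segments)) {
    roh_segments <- data.table::as.data.table(roh_segments)
    roh_segments <- roh_segments[order(match(roh_segments$chrom, layout$chrom),
                                       roh_segments$start)]
    .check_disjoint_sorted(roh_segments)
    if (any(roh_segments$end > .chrom_length(layout, roh_segments$chrom)))
      stop("truth ROH outside layout")
  } else {
    roh_segments <- data.table::data.table(chrom = character(),
                                           start = numeric(), end = numeric())
  }
  for (ev in deletion_events) {
    stopifnot(inherits(ev$region, "region"))
    if (!ev$genotype %in% c("hom", "het", "absent"))
      stop("deletion genotype must be hom, het or absent")
  }
  structure(list(layout = layout, seed = as.integer(seed), mean_het = mean_het,
                 roh_segments = roh_segments[],
                 residual_het_in_roh = residual_het_in_roh,
                 mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 binnability_profile = binnability_profile,
                 parental_bias_profile = parental_bias_profile,
                 phase_window = phase_window,
                 deletion_events = deletion_events, sv_tree = sv_tree),
            class = "sim_spec")
}

#' Simulate heterozygous small variants with planted ROH
#'
#' Heterozygous SNP positions are a Poisson process at `mean_het` per bp
#' outside the truth ROH and `residual_het_in_roh` inside. Genotypes are
#' `0/1`; per-site depth is drawn around `mean_depth` so the depth-masking
#' filter has something to chew on. Deterministic under the spec seed.
#'
#' @param spec a [sim_spec()].
#' @return list: `variants` (a single-sample [variant_table()], sample
#'   `"sim"`), `truth_roh` (the planted segments).
#' @export
simulate_diploid_variants <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .set_substream(spec, "variants")
  rows <- list()
  for (i in seq_len(nrow(spec$layout))) {
    chrom_i <- spec$layout$chrom[i]; len <- spec$layout$length[i]
    keep <- which(spec$roh_segments$chrom == chrom_i)
    roh <- spec$roh_segments[keep, ]
    # partition [1, len] into (interval, rate) pieces
    bounds <- c(1, as.vector(rbind(roh$start, roh$end + 1)), len + 1)
    pos_all <- numeric(0)
    for (k in seq_len(length(bounds) - 1L)) {
      s <- bounds[k]; e <- bounds[k + 1L] - 1
      if (e < s) next
      in_roh <- k %% 2 == 0
      rate <- if (in_roh) spec$residual_het_in_roh else spec$mean_het
      piece <- e - s + 1
      n <- min(stats::rpois(1, piece * rate), piece)
      if (n > 0) pos_all <- c(pos_all, s - 1 + sort(sample.int(piece, n)))
    }
    if (!length(pos_all)) next
    n <- length(pos_all)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = chrom_i, pos = pos_all, ref = ref, alt = unname(alt),
      qual = 60, ac = 1,
      gt.sim = "0/1",
      dp.sim = .nb_draw(n, spec$mean_depth, spec$depth_dispersion))
  }
  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(chrom = character(), pos = numeric(),
                           ref = character(), alt = character(),
                           qual = numeric(), ac = numeric(),
                           gt.sim = character(), dp.sim = numeric())
  list(variants = variant_table(dt, "sim"), truth_roh = spec$roh_segments)
}

.nb_draw <- function(n, mu, dispersion) {
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (dispersion == 0) return(round(mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate overdispersed per-base depth tracks
#'
#' Per-base depth is negative-binomial with mean `mean_depth` — scaled by
#' 0 / 0.5 / 1 inside deletion events for `hom` / `het` / `absent`
#' genotypes — and variance `mu + dispersion * mu^2`. With
#' `depth_dispersion = 0` the track is the noise-free constant
#' `round(mean_depth)`.
#'
#' @param spec a [sim_spec()].
#' @param region optional [region()]: simulate only this region (one
#'   track); default simulates every layout chromosome in full.
#' @return a [depth_track()] when `region` is given, else a named list of
#'   them.
#' @export
simulate_depth <- function(spec, region = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  .set_substream(spec, "depth")
  make_track <- function(reg) {
    n <- region_length(reg)
    mu <- rep(spec$mean_depth, n)
    for (ev in spec$deletion_events) {
      if (ev$region$chrom != reg$chrom) next
      s <- max(ev$region$start, reg$start); e <- min(ev$region$end, reg$end)
      if (s > e) next
      f <- switch(ev$genotype, hom = 0, het = 0.5, absent = 1)
      mu[(s - reg$start + 1):(e - reg$start + 1)] <-
        mu[(s - reg$start + 1):(e - reg$start + 1)] * f
    }
    depth_track(reg, .nb_draw(n, mu, spec$depth_dispersion))
  }
  if (!is.null(region)) return(make_track(region))
  out <- lapply(seq_len(nrow(spec$layout)), function(i)
    make_track(region(spec$layout$chrom[i], 1, spec$layout$length[i])))
  stats::setNames(out, spec$layout$chrom)
}

#' Simulate haplotype-tagged read starts
#'
#' For each `phase_window` window, `reads_per_window` reads start uniformly
#' within the window; each is parental-assigned with the window's
#' binnability probability and, if assigned, paternal with the window's
#' bias probability.
#'
#' @param spec a [sim_spec()]; `binnability_profile` and
#'   `parental_bias_profile` are recycled or checked against the window
#'   count.
#' @param reads_per_window reads simulated per window.
#' @return list: `reads` (`chrom`, `start`, `tag`), `truth` (per-window
#'   `p_assign`, `p_paternal`).
#' @export
simulate_trio_tags <- function(spec, reads_per_window = 100) {
  stopifnot(inherits(spec, "sim_spec"))
  .set_substream(spec, "tags")
  win <- tile_windows(spec$layout, spec$phase_window)
  nw <- nrow(win)
  p_assign <- .expand_profile(spec$binnability_profile, nw, "binnability_profile")
  p_pat <- .expand_profile(spec$parental_bias_profile, nw, "parental_bias_profile")
  reads <- lapply(seq_len(nw), function(i) {
    n <- reads_per_window
    start <- win$start[i] + sample.int(win$end[i] - win$start[i] + 1, n,
                                       replace = TRUE) - 1L
    assigned <- stats::runif(n) < p_assign[i]
    pat <- stats::runif(n) < p_pat[i]
    tag <- ifelse(!assigned, "unassigned", ifelse(pat, "paternal", "maternal"))
    data.table::data.table(chrom = win$chrom[i], start = sort(start), tag = tag)
  })
  truth <- data.table::copy(win)
  truth[, "p_assign" := p_assign]
  truth[, "p_paternal" := p_pat]
  list(reads = .validate_tagged_reads(data.table::rbindlist(reads), spec$layout),
       truth = truth[])
}

.expand_profile <- function(p, n, what) {
  if (length(p) == 1L) return(rep(p, n))
  if (length(p) != n)
    stop(sprintf("%s has %d values but the layout has %d windows",
                 what, length(p), n))
  p
}

#' Simulate an SV presence matrix on a known tree
#'
#' Every edge of the truth tree contributes `branch_counts[edge]` SVs that
#' are present in exactly the leaves below that edge (plus `root_count`
#' SVs present in all leaves, which are phylogenetically uninformative).
#' SV positions are uniform on the layout; lengths are uniform in
#' [50, 5000] bp.
#'
#' @param spec a [sim_spec()] whose `sv_tree` is set.
#' @return list: `matrix` (an [sv_matrix()]), `truth_tree` (the
#'   [ape::phylo] tree).
#' @export
simulate_sv_matrix <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  tr <- spec$sv_tree
  if (is.null(tr)) stop("sim_spec has no sv_tree")
  phy <- tr$phylo
  if (!inherits(phy, "phylo") || length(phy$tip.label) < 2L)
    stop("sv_tree$phylo must be a rooted tree with >= 2 leaves")
  counts <- tr$branch_counts
  if (length(counts) != nrow(phy$edge))
    stop("branch_counts must have one entry per tree edge")
  if (any(counts < 0)) stop("branch SV counts must be >= 0")
  root_count <- if (is.null(tr$root_count)) 0L else tr$root_count
  .set_substream(spec, "sv")
  leaves <- phy$tip.label
  below <- .tips_below(phy)
  pres_rows <- list()
  for (e in seq_len(nrow(phy$edge))) {
    k <- counts[e]
    if (k == 0) next
    v <- leaves %in% below[[phy$edge[e, 2]]]
    pres_rows <- c(pres_rows, rep(list(v), k))
  }
  if (root_count > 0)
    pres_rows <- c(pres_rows, rep(list(rep(TRUE, length(leaves))), root_count))
  n <- length(pres_rows)
  if (n == 0) stop("no SVs to simulate (all branch counts zero)")
  ci <- sample.int(nrow(spec$layout), n, replace = TRUE,
                   prob = spec$layout$length / sum(spec$layout$length))
  len <- sample(50:5000, n, replace = TRUE)
  # keep pos + length within the chromosome so a deletion's REF allele fits
  pos <- vapply(seq_len(n), function(k)
    sample.int(spec$layout$length[ci[k]] - len[k], 1), integer(1))
  sv <- data.table::data.table(
    chrom = spec$layout$chrom[ci], pos = as.numeric(pos),
    sv_class = sample(c("insertion", "deletion"), n, replace = TRUE),
    length = len)
  m <- sv_matrix(leaves, sv, do.call(rbind, pres_rows))
  list(matrix = m, truth_tree = phy)
}

# tip labels below each node (index = node id in ape numbering)
.tips_below <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  # edges in ape are not guaranteed child-first; iterate until stable
  done <- FALSE
  while (!done) {
    done <- TRUE
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      add <- below[[child]]
      if (is.null(add)) { done <- FALSE; next }
      merged <- unique(c(below[[par]], add))
      if (!identical(below[[par]], merged)) below[[par]] <- merged
    }
  }
  below
}

#' Write a full simulated data set to a directory
#'
#' Emits everything the pipeline consumes, plus ground truth: `sim.vcf`,
#' `depth.tsv`, `tagged_reads.tsv`, `layout.tsv`, `truth_roh.bed`, and
#' `truth.json` (profiles, deletion events, Newick truth tree when an
#' `sv_tree` is set, in which case `sv_genotypes.vcf` is written too).
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @param reads_per_window passed to [simulate_trio_tags()].
#' @return `dir`, invisibly.
#' @export
simulate_to_dir <- function(spec, dir, reads_per_window = 100) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(dir, f)
  sim_v <- simulate_diploid_variants(spec)
  write_variants(sim_v$variants, pth("sim.vcf"), layout = spec$layout)
  write_bed(sim_v$truth_roh, pth("truth_roh.bed"))
  write_depth_table(simulate_depth(spec), pth("depth.tsv"))
  tags <- simulate_trio_tags(spec, reads_per_window)
  write_tagged_reads(tags$reads, pth("tagged_reads.tsv"))
  data.table::fwrite(spec$layout, pth("layout.tsv"), sep = "\t")
  truth <- list(seed = spec$seed, mean_het = spec$mean_het,
                residual_het_in_roh = spec$residual_het_in_roh,
                mean_depth = spec$mean_depth,
                depth_dispersion = spec$depth_dispersion,
                binnability_profile = spec$binnability_profile,
                parental_bias_profile = spec$parental_bias_profile,
                deletion_events = lapply(spec$deletion_events, function(ev)
                  list(region = format(ev$region), genotype = ev$genotype)))
  if (!is.null(spec$sv_tree)) {
    sv <- simulate_sv_matrix(spec)
    .write_sv_vcf(sv$matrix, pth("sv_genotypes.vcf"), spec$layout)
    truth$sv_tree_newick <- ape::write.tree(sv$truth_tree)
  }
  jsonlite::write_json(truth, pth("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

# Minimal deconstruction-style VCF for a simulated SV matrix: one haploid
# genotype column per assembly, REF/ALT sized to carry the SV length.
.write_sv_vcf <- function(m, path, layout) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rohpan-sv-sim",
    sprintf("##contig=<ID=%s,length=%.0f>", layout$chrom, layout$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$assemblies), collapse = "\t")), con)
  if (nrow(m$sv)) {
    ord <- order(match(m$sv$chrom, layout$chrom), m$sv$pos)
    base <- strrep("A", 1)
    for (i in ord) {
      len <- m$sv$length[i]
      if (m$sv$sv_class[i] == "insertion") {
        ref <- "A"; alt <- paste0("A", strrep("T", len))
      } else {
        ref <- paste0("A", strrep("T", len)); alt <- "A"
      }
      gts <- ifelse(m$presence[i, ], "1", "0")
      writeLines(paste(c(m$sv$chrom[i],
                         format(m$sv$pos[i], trim = TRUE, scientific = FALSE),
                         ".", ref, alt, "60", ".", ".", "GT", gts),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
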