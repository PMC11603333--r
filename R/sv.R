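# Structural-variant presence/absence analytics from a super-pangenome
# deconstruction: per-assembly totals, UpSet-style exact intersections,
# private-SV hotspot scans, pairwise shared-SV distances and a UPGMA tree.

#' SV presence/absence matrix
#'
#' @param assemblies ordered character vector of assembly labels.
#' @param sv `data.frame` with `chrom`, `pos`, `sv_class`
#'   (`"insertion"`/`"deletion"`), `length` (bp).
#' @param presence logical matrix, one row per SV, one column per assembly.
#' @return an `sv_matrix` object.
#' @export
sv_matrix <- function(assemblies, sv, presence) {
  sv <- data.table::as.data.table(sv)
  presence <- as.matrix(presence)
  mode(presence) <- "logical"
  if (nrow(sv) != nrow(presence)) stop("sv table and presence matrix disagree")
  if (ncol(presence) != length(assemblies))
    stop("presence matrix must have one column per assembly")
  if (anyDuplicated(assemblies)) stop("assembly labels must be unique")
  colnames(presence) <- assemblies
  if (nrow(presence) && any(rowSums(presence) == 0))
    stop("SV records with no carrier assembly are not allowed")
  structure(list(assemblies = as.character(assemblies), sv = sv[],
                 presence = presence),
            class = "sv_matrix")
}

#' @export
print.sv_matrix <- function(x, ...) {
  cat(sprintf("<sv_matrix> %d SVs x %d assemblies\n",
              nrow(x$presence), length(x$assemblies)))
  invisible(x)
}

#' Build an SV presence matrix from a deconstructed pangenome VCF
#'
#' Consumes the VCF produced by deconstructing pangenome graph paths (one
#' genotype column per assembly, e.g. `vg deconstruct` output against the
#' cattle backbone). Multi-allelic records are split per alternate allele;
#' an assembly is *present* for an allele iff it carries that allele
#' (missing genotypes count as absent and are tallied in
#' `attr(, "n_missing_genotypes")`). SV length is `|nchar(alt) - nchar(ref)|`
#' with insertions/deletions by sign; alleles shorter than `min_sv_length`
#' (50 bp) are dropped, as are alleles no assembly carries. Symbolic
#' alleles carry no length and are an error.
#'
#' @param path VCF file.
#' @param params a [pipeline_params()] (`min_sv_length`).
#' @return an [sv_matrix()].
#' @export
presence_from_deconstructed_vcf <- function(path, params = pipeline_params()) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("deconstructed VCF lacks GT: ", path)
  assemblies <- colnames(gt)
  if (!length(assemblies)) stop("deconstructed VCF has no genotype columns")
  gr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as(VariantAnnotation::alt(vcf), "CharacterList")
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  pos <- BiocGenerics::start(gr)
  rows <- list(); pres <- list(); n_missing <- 0L
  for (i in seq_along(ref)) {
    alts <- alt[[i]]
    if (any(grepl("^<", alts)))
      stop("symbolic ALT allele without length information at ",
           chrom[i], ":", pos[i])
    al <- .gt_alleles(ifelse(gt[i, ] %in% c(".", "./."), NA_character_, gt[i, ]))
    n_missing <- n_missing + sum(vapply(al, is.null, logical(1)))
    for (k in seq_along(alts)) {
      delta <- nchar(alts[k]) - nchar(ref[i])
      if (abs(delta) < params$min_sv_length) next
      carrier <- vapply(al, function(a) !is.null(a) && any(a == k), logical(1))
      if (!any(carrier)) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = chrom[i], pos = pos[i],
        sv_class = if (delta > 0) "insertion" else "deletion",
        length = abs(delta))
      pres[[length(pres) + 1L]] <- carrier
    }
  }
  if (!length(rows)) {
    m <- sv_matrix(assemblies,
                   data.table::data.table(chrom = character(), pos = numeric(),
                                          sv_class = character(), length = numeric()),
                   matrix(logical(0), 0, length(assemblies)))
  } else {
    m <- sv_matrix(assemblies, data.table::rbindlist(rows),
                   do.call(rbind, pres))
  }
  attr(m, "n_missing_genotypes") <- n_missing
  m
}

#' Exact intersection counts (UpSet semantics)
#'
#' Each SV is counted once, under its full presence pattern. Per-assembly
#' totals are the row sums of presence (the left bars of an UpSet plot);
#' pattern counts are the intersection bars.
#'
#' @param m an [sv_matrix()].
#' @return list with `patterns` (`data.table`: `pattern` label using `+` as
#'   separator, `n`) and `totals` (named integer vector per assembly).
#' @export
subset_intersections <- function(m) {
  stopifnot(inherits(m, "sv_matrix"))
  totals <- colSums(m$presence)
  storage.mode(totals) <- "integer"
  if (!nrow(m$presence)) {
    return(list(patterns = data.table::data.table(pattern = character(),
                                                  n = integer()),
                totals = totals))
  }
  pat <- apply(m$presence, 1L, function(p) paste(m$assemblies[p], collapse = "+"))
  tab <- data.table::data.table(pattern = pat)[, list(n = .N), by = "pattern"]
  tab <- tab[order(-tab$n, tab$pattern)]
  list(patterns = tab[], totals = totals)
}

#' Scan for hotspots of assembly-private SVs
#'
#' A private SV is present in the focal assembly only. Each window's fold
#' enrichment is its private-SV density relative to the genome-wide private
#' density: `(n_window / window_bp) / (n_genome / genome_bp)`.
#'
#' @param m an [sv_matrix()].
#' @param focal_assembly label of the focal assembly.
#' @param window window size in bp.
#' @param layout a [genome_layout()] covering the SV positions.
#' @param min_fold report only windows at or above this enrichment.
#' @return `data.table` of windows with `n_private` and `fold`, filtered to
#'   `fold >= min_fold`; the full per-window scan is in
#'   `attr(, "all_windows")` and the genome-wide private count in
#'   `attr(, "n_private_genome")`.
#' @export
private_sv_hotspots <- function(m, focal_assembly, window, layout,
                                min_fold = 10) {
  stopifnot(inherits(m, "sv_matrix"))
  j <- match(focal_assembly, m$assemblies)
  if (is.na(j)) stop("unknown focal assembly: ", focal_assembly)
  priv <- m$presence[, j] & rowSums(m$presence) == 1L
  win <- tile_windows(layout, window)
  n_genome <- sum(priv)
  genome_bp <- sum(layout$length)
  if (n_genome) {
    sv <- m$sv[priv, ]
    if (!all(sv$chrom %in% layout$chrom)) stop("SV positions outside layout")
    sv <- data.table::copy(sv)
    sv[, "start" := (sv$pos - 1) %/% window * window + 1]
    cnt <- sv[, list(n_private = .N), by = c("chrom", "start")]
    win <- merge(win, cnt, by = c("chrom", "start"), all.x = TRUE, sort = FALSE)
    win[is.na(win$n_private), "n_private" := 0L]
  } else {
    win[, "n_private" := 0L]
  }
  win[, "fold" := if (n_genome == 0) NA_real_ else
    (win$n_private / (win$end - win$start + 1)) / (n_genome / genome_bp)]
  win <- win[order(match(win$chrom, layout$chrom), win$start)]
  hot <- win[!is.na(win$fold) & win$fold >= min_fold, ]
  data.table::setattr(hot, "all_windows", win[])
  data.table::setattr(hot, "n_private_genome", n_genome)
  hot[]
}

#' Pairwise assembly distances from SV sharing
#'
#' Default (`method = "shared"`): `d(i, j) = 1 / |SVs present in both i and
#' j|` — the reciprocal of the pairwise SV overlap, so more sharing means
#' closer. Pairs sharing no SV get the sentinel `2 x max finite distance`.
#' The alternative `method = "discordant"` uses the fraction of SV records
#' on which the pair disagrees.
#'
#' @param m an [sv_matrix()].
#' @param method `"shared"` (reciprocal of shared count, default) or
#'   `"discordant"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_sv_distance <- function(m, method = c("shared", "discordant")) {
  stopifnot(inherits(m, "sv_matrix"))
  method <- match.arg(method)
  k <- length(m$assemblies)
  if (k < 2) stop("need at least 2 assemblies")
  shared <- crossprod(m$presence * 1)
  if (method == "shared") {
    d <- 1 / shared
    diag(d) <- 0
    if (any(is.infinite(d))) {
      finite_max <- max(d[is.finite(d)], 0)
      d[is.infinite(d)] <- 2 * finite_max
    }
  } else {
    n <- nrow(m$presence)
    if (n == 0) stop("empty SV matrix")
    pres <- m$presence * 1
    disc <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k))
      disc[i, j] <- sum(pres[, i] != pres[, j])
    d <- disc / n
  }
  dimnames(d) <- list(m$assemblies, m$assemblies)
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair-group average clustering: repeatedly join the
#' closest pair of clusters; the new cluster's distance to any other is the
#' cluster-size-weighted average of its members' distances; the merge
#' height is half the joining distance, so the result is ultrametric. Ties
#' are broken deterministically by the lexicographically smallest pair of
#' cluster labels (a cluster's label is the sorted concatenation of its
#' leaves).
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   leaf labels as dimnames.
#' @return an `upgma_tree`: `merges` (`data.table` with the two joined
#'   cluster labels, the joining distance and the merge `height`),
#'   `hclust` (a base-R `hclust` object), and `phylo` (an [ape::as.phylo]
#'   tree carrying branch lengths).
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$merges
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs leaf labels")
  if (!isTRUE(all.equal(d, t(d))) || any(d < 0) || any(diag(d) != 0))
    stop("need a symmetric non-negative distance matrix with zero diagonal")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2) stop("need at least 2 leaves")
  # active clusters: id (hclust convention: -leaf or +merge index), label,
  # size; dm holds current between-cluster distances
  act <- data.table::data.table(id = -seq_len(n), label = labels, size = 1L)
  dm <- d
  merges <- vector("list", n - 1L)
  hmerge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- nrow(dm)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      lab <- sort(c(act$label[i], act$label[j]))
      cand <- list(i = i, j = j, dij = dm[i, j], lab = lab)
      if (is.null(best) || cand$dij < best$dij ||
          (cand$dij == best$dij &&
           (cand$lab[1] < best$lab[1] ||
            (cand$lab[1] == best$lab[1] && cand$lab[2] < best$lab[2]))))
        best <- cand
    }
    i <- best$i; j <- best$j
    new_label <- paste(sort(unlist(strsplit(
      c(act$label[i], act$label[j]), "\\+"))), collapse = "+")
    merges[[step]] <- data.table::data.table(
      left = best$lab[1], right = best$lab[2],
      distance = best$dij, height = best$dij / 2)
    hmerge[step, ] <- sort(c(act$id[i], act$id[j]))
    # hclust stores the full joining distance; as.phylo halves it to get
    # the ultrametric node height
    heights[step] <- best$dij
    ni <- act$size[i]; nj <- act$size[j]
    newd <- (ni * dm[i, ] + nj * dm[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    act <- rbind(act[keep],
                 data.table::data.table(id = step, label = new_label,
                                        size = ni + nj))
  }
  hc <- .as_hclust(hmerge, heights, labels)
  phy <- ape::as.phylo(hc)
  structure(list(merges = data.table::rbindlist(merges),
                 hclust = hc, phylo = phy, labels = labels),
            class = "upgma_tree")
}

.as_hclust <- function(merge, height, labels) {
  # leaf order for plotting: left-to-right traversal of the merge tree
  order_of <- function(i) {
    if (i < 0) return(-i)
    c(order_of(merge[i, 1]), order_of(merge[i, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = order_of(nrow(merge)),
                 labels = labels, method = "average",
                 call = match.call(), dist.method = "sv"),
            class = "hclust")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves; root height %.4g\n",
              length(x$labels), max(x$merges$height)))
  print(x$merges)
  invisible(x)
}

#' Write a UPGMA tree as Newick
#'
#' @param tree an [upgma()] result.
#' @param path output file; when `NULL` the Newick string is returned.
#' @export
upgma_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "upgma_tree"))
  s <- ape::write.tree(tree$phylo)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Leaf-to-root heights of a tree (ultrametricity check)
#'
#' @param tree an [upgma()] result.
#' @return named numeric vector of root-to-leaf path lengths.
#' @export
leaf_depths <- function(tree) {
  phy <- tree$phylo
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  stats::setNames(depths, phy$tip.label)
}
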