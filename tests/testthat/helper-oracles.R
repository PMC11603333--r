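# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain loops, all-pairs scans, naive text parsing.

# --- phasing ---------------------------------------------------------------

oracle_bin_reads <- function(reads, layout, window) {
  out <- list()
  for (ci in seq_len(nrow(layout))) {
    chrom <- layout$chrom[ci]
    len <- layout$length[ci]
    s <- 1
    while (s <= len) {
      e <- min(s + window - 1, len)
      np <- nm <- nu <- 0L
      for (ri in seq_len(nrow(reads))) {
        if (reads$chrom[ri] == chrom && reads$start[ri] >= s && reads$start[ri] <= e) {
          tg <- as.character(reads$tag[ri])
          if (tg == "paternal") np <- np + 1L
          else if (tg == "maternal") nm <- nm + 1L
          else nu <- nu + 1L
        }
      }
      out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = s, end = e,
                                            n_paternal = np, n_maternal = nm,
                                            n_unassigned = nu)
      s <- s + window
    }
  }
  do.call(rbind, out)
}

oracle_count_biased <- function(n_pat, n_mat, fold) {
  cnt <- 0L
  for (i in seq_along(n_pat)) {
    p <- n_pat[i]; m <- n_mat[i]
    if (p == 0 && m == 0) next
    if (p == 0 || m == 0) { cnt <- cnt + 1L; next }  # one class absent: maximal bias
    if (max(p, m) / min(p, m) > fold) cnt <- cnt + 1L
  }
  cnt
}

# --- variant filters -------------------------------------------------------

oracle_mask_decisions <- function(dp, mean_cov) {
  # TRUE = genotype must be masked
  is.na(dp) | dp < mean_cov / 3 | dp > 2.5 * mean_cov
}

oracle_proximity_removed <- function(chrom, pos, class, proximity = 5) {
  n <- length(pos)
  removed <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (chrom[i] != chrom[j]) next
      if (class[j] != "InDel") next
      d <- abs(pos[i] - pos[j])
      if (class[i] == "SNP" && d < proximity) removed[i] <- TRUE
      if (class[i] == "InDel" && d < proximity) removed[i] <- TRUE
    }
  }
  removed
}

oracle_qual_ac_removed <- function(qual, ac, min_qual = 30, min_ac = 2) {
  removed <- logical(length(qual))
  for (i in seq_along(qual)) {
    if (is.na(qual[i]) || qual[i] < min_qual || ac[i] < min_ac) removed[i] <- TRUE
  }
  removed
}

# --- callable mask ---------------------------------------------------------

oracle_callable <- function(depth, start_pos, window, mean_cov) {
  # returns per-window callable counts, windows anchored at 1 on the genome
  lo <- mean_cov / 3; hi <- 2.5 * mean_cov
  pos <- seq(start_pos, length.out = length(depth))
  wi <- floor((pos - 1) / window)
  counts <- integer(0)
  for (w in sort(unique(wi))) {
    d <- depth[wi == w]
    counts <- c(counts, sum(d > lo & d < hi))
  }
  counts
}

# --- SV analytics ----------------------------------------------------------

oracle_upset <- function(presence, assemblies) {
  # enumerate all 2^k - 1 patterns and count exact matches
  k <- length(assemblies)
  res <- list()
  for (code in 1:(2^k - 1)) {
    members <- assemblies[bitwAnd(code, 2^(seq_len(k) - 1)) > 0]
    n <- 0L
    for (r in seq_len(nrow(presence))) {
      if (identical(sort(assemblies[presence[r, ]]), sort(members))) n <- n + 1L
    }
    if (n > 0) res[[paste(members, collapse = "+")]] <- n
  }
  res
}

oracle_pairwise_shared <- function(presence) {
  k <- ncol(presence)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    shared <- 0L
    for (r in seq_len(nrow(presence)))
      if (presence[r, i] && presence[r, j]) shared <- shared + 1L
    d[i, j] <- if (shared > 0) 1 / shared else Inf
  }
  if (any(is.infinite(d))) d[is.infinite(d)] <- 2 * max(d[is.finite(d)], 0)
  dimnames(d) <- list(colnames(presence), colnames(presence))
  d
}

# UPGMA reference: stats::hclust average linkage. Returns the sequence of
# (leaf set, height) merges for comparison.
oracle_upgma_merges <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labs <- hc$labels
  sets <- vector("list", nrow(hc$merge))
  leaves_of <- function(i, step) {
    if (i < 0) return(labs[-i])
    sets[[i]]
  }
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    m <- hc$merge[s, ]
    sets[[s]] <- sort(c(leaves_of(m[1], s), leaves_of(m[2], s)))
    out[[s]] <- list(leaves = sets[[s]], height = hc$height[s] / 2)
  }
  out
}

upgma_merge_sets <- function(tree) {
  # leaf sets + heights from the package tree, via the compound labels
  lapply(seq_len(nrow(tree$merges)), function(s) {
    m <- tree$merges[s, ]
    leaves <- sort(unlist(strsplit(c(m$left, m$right), "+", fixed = TRUE)))
    list(leaves = leaves, height = m$height)
  })
}

# --- naive VCF line parser -------------------------------------------------

oracle_parse_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  recs <- lapply(body, function(l) {
    f <- strsplit(l, "\t")[[1]]
    fmt <- strsplit(f[9], ":")[[1]]
    smp <- lapply(f[-(1:9)], function(s) {
      v <- strsplit(s, ":")[[1]]
      gt <- v[match("GT", fmt)]
      dp <- v[match("DP", fmt)]
      list(gt = if (gt %in% c(".", "./.", ".|.")) NA_character_ else gt,
           dp = if (is.na(dp) || dp == ".") NA_real_ else as.numeric(dp))
    })
    ac <- NA_real_
    for (kv in strsplit(f[8], ";")[[1]]) {
      p <- strsplit(kv, "=")[[1]]
      if (p[1] == "AC") ac <- sum(as.numeric(strsplit(p[2], ",")[[1]]))
    }
    list(chrom = f[1], pos = as.numeric(f[2]), ref = f[4], alt = f[5],
         qual = if (f[6] == ".") NA_real_ else as.numeric(f[6]),
         ac = ac, samples = stats::setNames(smp, samples))
  })
  list(samples = samples, records = recs)
}
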