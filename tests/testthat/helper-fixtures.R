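# Programmatic fixtures shared across test files.

tiny_layout <- function(n = 2, len = 1e5, autosome = TRUE) {
  genome_layout(as.character(seq_len(n)), rep(len, n), autosome)
}

# random variant table: mixed SNP/InDel, n_samples samples, some missing
# genotypes; positions sorted within chromosomes
rand_variant_table <- function(n = 50, n_samples = 2, chroms = c("1", "2"),
                               span = 1e4) {
  chrom <- sort(sample(chroms, n, replace = TRUE))
  dt <- data.table::data.table(chrom = chrom)
  dt <- dt[order(chrom)]
  pos <- unlist(lapply(split(seq_len(n), dt$chrom), function(ix)
    sort(sample.int(span, length(ix)))), use.names = FALSE)
  dt[, pos := pos]
  is_indel <- runif(n) < 0.3
  dt[, ref := ifelse(is_indel, "AT", "A")]
  dt[, alt := ifelse(is_indel & runif(n) < 0.5, "A",
                     ifelse(is_indel, "ATTT", "G"))]
  # occasionally multi-allelic SNP
  multi <- !is_indel & runif(n) < 0.15
  dt[multi, alt := "G,T"]
  dt[, qual := round(runif(n, 10, 80), 1)]
  samples <- paste0("s", seq_len(n_samples))
  for (s in samples) {
    gt <- sample(c("0/0", "0/1", "1/1", NA), n, replace = TRUE,
                 prob = c(0.3, 0.4, 0.2, 0.1))
    dt[, (paste0("gt.", s)) := gt]
    dt[, (paste0("dp.", s)) := rpois(n, 30)]
  }
  dt[, ac := NA_real_]
  vt <- variant_table(dt, samples)
  vt[, ac := recompute_ac(vt)]
  vt
}

# hand-built het-window table for ROH tests
make_hw <- function(n_het, callable = rep(1e4, length(n_het)), chrom = "1",
                    window = 1e4, excluded = NULL, genome_mean = NULL) {
  nw <- length(n_het)
  w <- data.table::data.table(
    chrom = chrom,
    start = seq(1, by = window, length.out = nw),
    end = seq(window, by = window, length.out = nw),
    window_bp = window, callable = callable, n_het = n_het)
  w[, het := ifelse(callable > 0, n_het / callable, NA_real_)]
  w[, excluded := if (is.null(excluded)) rep(FALSE, nw) else excluded]
  gm <- if (is.null(genome_mean))
    with(w[!w$excluded & w$callable > 0], sum(n_het) / sum(callable))
  else genome_mean
  data.table::setattr(w, "genome_mean_het", gm)
  data.table::setattr(w, "class", unique(c("het_windows", class(w))))
  w[]
}

rand_sv_presence <- function(n_sv = 100, assemblies = LETTERS[1:5]) {
  k <- length(assemblies)
  repeat {
    pres <- matrix(runif(n_sv * k) < runif(1, 0.2, 0.8), n_sv, k)
    pres <- pres[rowSums(pres) > 0, , drop = FALSE]
    if (nrow(pres) > 0) break
  }
  colnames(pres) <- assemblies
  sv <- data.table::data.table(
    chrom = "1", pos = sort(sample.int(1e6, nrow(pres))),
    sv_class = sample(c("insertion", "deletion"), nrow(pres), replace = TRUE),
    length = sample(50:2000, nrow(pres), replace = TRUE))
  sv_matrix(assemblies, sv, pres)
}

# random distance matrix with distinct entries (no UPGMA ties)
rand_dist <- function(k = 6) {
  labs <- LETTERS[seq_len(k)]
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  vals <- sample(seq(0.01, 1, by = 0.01), k * (k - 1) / 2)
  t <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d[i, j] <- d[j, i] <- vals[t]; t <- t + 1
  }
  d
}
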