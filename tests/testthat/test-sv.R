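test_that("deconstructed-VCF presence rules: carriers, class, length floor", {
  lay <- genome_layout("1", 1e5)
  f <- withr::local_tempfile(fileext = ".vcf")
  # record 1: 1,630 bp deletion carried by wisent+bison; record 2: 30 bp
  # indel (below the 50 bp floor); record 3: multi-allelic with one long
  # insertion carried by yak only; record 4: carried by nobody (dropped)
  del_ref <- paste0("A", strrep("T", 1630))
  ins_alt <- paste0("A", strrep("G", 200))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "wisent", "bison", "yak"), collapse = "\t"),
    paste(c("1", "1000", ".", del_ref, "A", "60", ".", ".", "GT",
            "1", "1", "0"), collapse = "\t"),
    paste(c("1", "5000", ".", "A", paste0("A", strrep("T", 30)), "60", ".",
            ".", "GT", "1", "1", "1"), collapse = "\t"),
    paste(c("1", "9000", ".", "A", paste0("C,", ins_alt), "60", ".", ".",
            "GT", "0", ".", "2"), collapse = "\t"),
    paste(c("1", "9500", ".", del_ref, "A", "60", ".", ".", "GT",
            "0", "0", "0"), collapse = "\t")), f)
  m <- presence_from_deconstructed_vcf(f)
  expect_identical(m$assemblies, c("wisent", "bison", "yak"))
  expect_equal(nrow(m$presence), 2)
  expect_equal(m$sv$sv_class, c("deletion", "insertion"))
  expect_equal(m$sv$length, c(1630, 200))
  expect_identical(m$presence[1, ], c(wisent = TRUE, bison = TRUE, yak = FALSE))
  expect_identical(m$presence[2, ], c(wisent = FALSE, bison = FALSE, yak = TRUE))
  expect_equal(attr(m, "n_missing_genotypes"), 1)
})

test_that("simulated deconstruction VCF round trips to the generator truth", {
  lay <- genome_layout(c("1", "2"), c(5e5, 5e5))
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  spec <- sim_spec(lay, seed = 6,
                   sv_tree = list(phylo = phy,
                                  branch_counts = rep(25L, nrow(phy$edge))))
  truth <- simulate_sv_matrix(spec)
  d <- withr::local_tempdir()
  simulate_to_dir(spec, d, reads_per_window = 5)
  m <- presence_from_deconstructed_vcf(file.path(d, "sv_genotypes.vcf"))
  expect_equal(nrow(m$presence), nrow(truth$matrix$presence))
  # same multiset of (pattern, class, length) triples
  key <- function(mm) sort(paste(
    apply(mm$presence, 1, function(p) paste(mm$assemblies[p], collapse = "+")),
    mm$sv$sv_class, mm$sv$length))
  expect_identical(key(m), key(truth$matrix))
})

test_that("UpSet intersections: exact patterns and per-assembly totals", {
  pres <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))
  m <- sv_matrix(c("A", "B"),
                 data.table::data.table(chrom = "1", pos = c(10, 20, 30),
                                        sv_class = "deletion", length = 100),
                 pres)
  si <- subset_intersections(m)
  expect_equal(si$totals, c(A = 2L, B = 2L))
  got <- stats::setNames(si$patterns$n, si$patterns$pattern)
  expect_equal(got[c("A+B", "A", "B")], c(`A+B` = 1L, A = 1L, B = 1L))

  # empty matrix
  m0 <- sv_matrix(c("A", "B"),
                  data.table::data.table(chrom = character(), pos = numeric(),
                                         sv_class = character(), length = numeric()),
                  matrix(logical(0), 0, 2))
  si0 <- subset_intersections(m0)
  expect_equal(nrow(si0$patterns), 0)
  expect_equal(si0$totals, c(A = 0L, B = 0L))
})

test_that("pattern counts equal brute-force enumeration on random 7x500", {
  set.seed(15)
  m <- rand_sv_presence(500, LETTERS[1:7])
  si <- subset_intersections(m)
  ref <- oracle_upset(m$presence, m$assemblies)
  expect_equal(sum(si$patterns$n), nrow(m$presence))
  expect_equal(length(ref), nrow(si$patterns))
  for (p in names(ref))
    expect_equal(si$patterns$n[si$patterns$pattern == p], ref[[p]],
                 label = p)
  # per-assembly total = sum of patterns containing it
  for (a in m$assemblies) {
    in_pat <- vapply(strsplit(si$patterns$pattern, "+", fixed = TRUE),
                     function(x) a %in% x, logical(1))
    expect_equal(sum(si$patterns$n[in_pat]), unname(si$totals[a]))
  }
})

test_that("private-SV hotspot fold enrichment mirrors the 27x construction", {
  # 27 private SVs in one 600 kb span of a 16.2 Mb genome -> fold 27
  lay <- genome_layout("7", 16.2e6)
  pres <- cbind(rep(TRUE, 27), rep(FALSE, 27))
  sv <- data.table::data.table(chrom = "7",
                               pos = seq(10.21e6, 10.79e6, length.out = 27),
                               sv_class = "deletion", length = 100)
  m <- sv_matrix(c("wisent", "cattle"), sv, pres)
  hot <- private_sv_hotspots(m, "wisent", 6e5, lay, min_fold = 10)
  expect_equal(nrow(hot), 1)
  expect_equal(hot$fold, 27)
  expect_equal(hot$n_private, 27L)

  # no private SVs -> empty report
  m2 <- sv_matrix(c("A", "B"),
                  data.table::data.table(chrom = "7", pos = 100,
                                         sv_class = "deletion", length = 60),
                  cbind(TRUE, TRUE))
  expect_equal(nrow(private_sv_hotspots(m2, "A", 6e5, lay)), 0)

  # uniform placement stays near fold 1 (stochastic bound, fixed seed)
  set.seed(2)
  n <- 1000
  mu <- sv_matrix(c("A", "B"),
                  data.table::data.table(chrom = "7",
                                         pos = sort(sample.int(16.2e6, n)),
                                         sv_class = "insertion", length = 60),
                  cbind(rep(TRUE, n), rep(FALSE, n)))
  all_w <- attr(private_sv_hotspots(mu, "A", 6e5, lay), "all_windows")
  expect_lt(max(all_w$fold), 3)
  expect_error(private_sv_hotspots(mu, "Z", 6e5, lay), "unknown focal")
})

test_that("pairwise distances are reciprocal shared counts with sentinel", {
  pres <- rbind(c(TRUE, TRUE, FALSE),
                c(TRUE, TRUE, FALSE),
                c(TRUE, FALSE, FALSE))
  pres <- pres[rep(1:3, c(10, 5, 3)), ]
  m <- sv_matrix(c("A", "B", "C"),
                 data.table::data.table(chrom = "1", pos = seq_len(nrow(pres)),
                                        sv_class = "deletion", length = 60),
                 pres)
  d <- pairwise_sv_distance(m)
  expect_equal(d["A", "B"], 1 / 15)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  # C shares nothing with anyone -> sentinel 2 x max finite
  expect_equal(d["A", "C"], 2 * (1 / 15))

  set.seed(8)
  for (rep in 1:10) {
    mr <- rand_sv_presence(120, LETTERS[1:5])
    expect_equal(pairwise_sv_distance(mr), oracle_pairwise_shared(mr$presence))
  }

  # identical presence rows give the minimal distance in the matrix
  pres2 <- matrix(runif(40 * 3) < 0.5, 40, 3)
  pres2 <- cbind(pres2, pres2[, 3])
  pres2 <- pres2[rowSums(pres2) > 0, ]
  colnames(pres2) <- c("A", "B", "C", "C2")
  m2 <- sv_matrix(colnames(pres2),
                  data.table::data.table(chrom = "1", pos = seq_len(nrow(pres2)),
                                         sv_class = "deletion", length = 60),
                  pres2)
  d2 <- pairwise_sv_distance(m2)
  off <- d2[upper.tri(d2)]
  expect_equal(d2["C", "C2"], min(off))
})

test_that("UPGMA hand-worked examples", {
  # two leaves at distance 0.2 -> single join at height 0.1
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(nrow(t2$merges), 1)
  expect_equal(t2$merges$height, 0.1)

  # d(A,B)=2, d(A,C)=d(B,C)=8 -> ((A,B),C) with heights 1 then 4
  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(t3$merges$height, c(1, 4))
  expect_identical(t3$merges$left, c("A", "A+B"))
  expect_identical(t3$merges$right, c("B", "C"))
  expect_identical(unname(ape::is.ultrametric(t3$phylo)), TRUE)
  nw <- upgma_newick(t3)
  expect_match(nw, "^\\(")

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2,
                            dimnames = list(c("A", "B"), c("A", "B")))),
               "symmetric")
})

test_that("UPGMA matches the reference implementation on random matrices", {
  set.seed(19)
  for (rep in 1:25) {
    d <- rand_dist(sample(4:7, 1))
    got <- upgma_merge_sets(upgma(d))
    ref <- oracle_upgma_merges(d)
    expect_equal(length(got), length(ref))
    for (s in seq_along(ref)) {
      expect_identical(got[[s]]$leaves, ref[[s]]$leaves)
      expect_equal(got[[s]]$height, ref[[s]]$height)
    }
  }
})

test_that("UPGMA output is ultrametric and label-permutation-equivariant", {
  set.seed(27)
  for (rep in 1:10) {
    d <- rand_dist(6)
    tr <- upgma(d)
    depths <- leaf_depths(tr)
    expect_lt(diff(range(depths)), 1e-9)
    expect_equal(unname(depths[1]), max(tr$merges$height))

    perm <- sample(6)
    dp <- d[perm, perm]
    trp <- upgma(dp)
    rf <- phangorn::RF.dist(ape::unroot(tr$phylo), ape::unroot(trp$phylo))
    expect_equal(rf, 0)
  }
})
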