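test_that("window tiling partitions each chromosome", {
  tw <- tile_windows(c(chrA = 120L, chrB = 75L), 50L)
  expect_equal(width(tw), c(50L, 50L, 20L, 50L, 25L))
  expect_equal(start(tw[seqnames(tw) == "chrA"]), c(1L, 51L, 101L))
  # disjoint cover of every base exactly once
  expect_true(isDisjoint(tw))
  expect_equal(sum(width(tw)), 120L + 75L)
  expect_equal(length(tw), sum(ceiling(c(120, 75) / 50)))
  expect_error(tile_windows(c(chrA = 100L), 0L), "width")
})

test_that("window RPKM follows count * 1e9 / (width * library)", {
  expect_equal(rpkm(10, 50, 1e6), 200)
  expect_equal(rpkm(10, 50, 2e6), 100)   # doubling the library halves RPKM
  # a read counts in every window its blocks overlap
  # reads: 40..59 (windows 1+2), 60..79 (window 2), 120..129 (window 3)
  aln <- make_aln("chrT", c(40, 60, 120), c("20M", "20M", "10M"),
                  seqlen = c(chrT = 200L))
  wr <- window_rpkm(aln, tile_windows(c(chrT = 200L), 50L))
  expect_equal(wr$counts, c(1L, 2L, 1L, 0L))
  expect_equal(wr$rpkm, rpkm(c(1, 2, 1, 0), 50, 3))
})

test_that("window counts equal the brute-force block-overlap oracle", {
  st <- small_study()
  aln <- st$sim$clip[[2]]
  cs <- st$ref$ann$chrom_sizes
  wr <- window_rpkm(aln, tile_windows(cs, 50L))
  expect_identical(as.integer(wr$counts), oracle_window_counts(aln, cs, 50L))
})

test_that("cluster thresholds encode the published filter wordings", {
  win <- tile_windows(c(chrT = 200L), 50L)
  mk_scores <- function(counts_mat, counts_in, lib_clip, lib_in) {
    structure(list(windows = win, counts_clip = counts_mat,
                   rpkm_clip = sapply(seq_len(ncol(counts_mat)), function(r)
                     rpkm(counts_mat[, r], width(win), lib_clip[r])),
                   counts_input = counts_in,
                   rpkm_input = rpkm(counts_in, width(win), lib_in),
                   lib_clip = lib_clip, lib_input = lib_in, width = 50L,
                   clip = NULL, input = NULL), class = "window_scores")
  }
  lib3 <- rep(1e6, 3)
  # summed 12 reads, pooled RPKM 80 vs input 24: fold 3.33 > 2, 12 >= 10 -> pass
  s1 <- mk_scores(matrix(c(4, 4, 4, rep(0, 9)), nrow = 4, byrow = TRUE),
                  c(3, 0, 0, 0), lib3, 2.5e6)
  expect_equal(length(call_clusters(s1, mode = "methods", pseudocount = 0)), 1L)
  # summed 9 reads: below the "minimum of 10 reads" -> fail
  s2 <- mk_scores(matrix(c(3, 3, 3, rep(0, 9)), nrow = 4, byrow = TRUE),
                  c(3, 0, 0, 0), lib3, 2.5e6)
  expect_equal(length(call_clusters(s2, mode = "methods", pseudocount = 0)), 0L)
  # fold exactly 2.0 is rejected (">2-fold"): pooled RPKM 80 vs input 40
  s3 <- mk_scores(matrix(c(4, 4, 4, rep(0, 9)), nrow = 4, byrow = TRUE),
                  c(5, 0, 0, 0), lib3, 2.5e6)
  expect_equal(length(call_clusters(s3, mode = "methods", pseudocount = 0)), 0L)
  # summed exactly 10 is accepted in methods mode ("minimum of 10 reads")
  s4 <- mk_scores(matrix(c(4, 3, 3, rep(0, 9)), nrow = 4, byrow = TRUE),
                  c(3, 0, 0, 0), lib3, 2.5e6)
  expect_equal(length(call_clusters(s4, mode = "methods", pseudocount = 0)), 1L)
  # results mode: summed exactly 10 fails (">10 reads"), 11 passes
  s5 <- mk_scores(matrix(c(4, 3, 3, rep(0, 9)), nrow = 4, byrow = TRUE),
                  c(1, 0, 0, 0), lib3, 1e6)
  expect_equal(length(call_clusters(s5, mode = "results", pseudocount = 0)), 0L)
  s6 <- mk_scores(matrix(c(4, 4, 3, rep(0, 9)), nrow = 4, byrow = TRUE),
                  c(1, 0, 0, 0), lib3, 1e6)
  expect_equal(length(call_clusters(s6, mode = "results", pseudocount = 0)), 1L)
  # results mode needs min_replicates individually passing folds
  s7 <- mk_scores(matrix(c(12, 1, 1, rep(0, 9)), nrow = 4, byrow = TRUE),
                  c(2, 0, 0, 0), lib3, 1e6)
  expect_equal(length(call_clusters(s7, mode = "results", pseudocount = 0)), 0L)
  # adjacent passing windows merge into one cluster spanning both
  s8 <- mk_scores(matrix(c(6, 6, 6, 6, 6, 6, rep(0, 6)), nrow = 4,
                         byrow = TRUE),
                  c(1, 1, 0, 0), lib3, 1e6)
  cl8 <- call_clusters(s8, mode = "methods", pseudocount = 0)
  expect_equal(length(cl8), 1L)
  expect_equal(width(cl8), 100L)
  expect_equal(cl8$n_windows, 2L)
})

test_that("raising thresholds never increases the number of clusters", {
  st <- small_study()
  sc <- window_scores(st$sim$clip, st$sim$input,
                      chrom_sizes = st$ref$ann$chrom_sizes)
  base <- length(call_clusters(sc, min_fold = 2, min_reads = 10))
  for (mf in c(3, 4, 8)) {
    expect_lte(length(call_clusters(sc, min_fold = mf, min_reads = 10)), base)
  }
  for (mr in c(20, 40, 80)) {
    expect_lte(length(call_clusters(sc, min_fold = 2, min_reads = mr)), base)
  }
})

test_that("merged cluster counts deduplicate reads against a brute-force count", {
  st <- small_study()
  sc <- window_scores(st$sim$clip, st$sim$input,
                      chrom_sizes = st$ref$ann$chrom_sizes)
  cl <- call_clusters(sc)
  expect_gt(length(cl), 0)
  manual <- Reduce(`+`, lapply(st$sim$clip, oracle_region_counts,
                               regions = cl))
  expect_equal(cl$total_reads, as.integer(manual))
})

test_that("replicate overlap is 1 for identical and 0 for disjoint cluster sets", {
  a <- GRanges("chrT", IRanges(c(1, 500), width = 100))
  b <- GRanges("chrT", IRanges(c(2000, 3000), width = 100))
  expect_equal(replicate_overlap(list(a, a, a)), 1)
  expect_equal(replicate_overlap(list(a, b)), 0)
  expect_error(replicate_overlap(list(a)), ">= 2 replicates")
})

test_that("strong planting yields high replicate overlap of per-replicate clusters", {
  st <- std_study()
  win <- tile_windows(st$ref$ann$chrom_sizes, 50L)
  per_rep <- lapply(st$sim$clip, replicate_clusters, windows = win,
                    min_reads = 20L)
  expect_gte(replicate_overlap(per_rep), 0.9)
})
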