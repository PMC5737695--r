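test_that("site caller enforces the coverage and frequency boundaries", {
  # 40 reads cover position 120; 2 carry a deletion there: freq exactly 5%
  aln <- make_aln("chrT", rep(101, 40),
                  c(rep("19M1D30M", 2), rep("50M", 38)))
  sites <- call_crosslink_sites(aln)
  expect_equal(length(sites), 1L)
  expect_equal(start(sites), 120L)
  expect_equal(sites$coverage, 40L)
  expect_equal(sites$deletions, 2L)
  expect_equal(sites$del_freq, 0.05)
  # coverage exactly 5 is rejected even with 100% deletion frequency
  aln2 <- make_aln("chrT", rep(101, 5), "19M1D30M")
  expect_equal(length(call_crosslink_sites(aln2)), 0L)
  # coverage 6 with one deletion (freq 1/6 > 5%) is called
  aln3 <- make_aln("chrT", rep(101, 6),
                   c("19M1D30M", rep("50M", 5)))
  expect_equal(length(call_crosslink_sites(aln3)), 1L)
  # multi-base deletions assign a site to every deleted position
  aln4 <- make_aln("chrT", rep(101, 10), c(rep("19M3D28M", 2), rep("52M", 8)))
  s4 <- call_crosslink_sites(aln4)
  expect_equal(start(s4), c(120L, 121L, 122L))
  # pileups are per strand
  aln5 <- c(make_aln("chrT", rep(101, 6), c("19M1D30M", rep("50M", 5)), "+"),
            make_aln("chrT", rep(101, 6), c("19M1D30M", rep("50M", 5)), "-"))
  expect_equal(length(call_crosslink_sites(aln5)), 2L)
})

test_that("site calls on simulated reads match the CIGAR-walk pileup oracle", {
  st <- small_study()
  aln <- st$sim$clip[[1]]
  got <- call_crosslink_sites(aln)
  exp <- oracle_crosslink_sites(aln, st$ref$ann$chrom_sizes)
  expect_equal(length(got), nrow(exp))
  got_df <- data.frame(chrom = as.character(seqnames(got)),
                       pos = start(got),
                       strand = as.character(strand(got)),
                       coverage = got$coverage, deletions = got$deletions)
  ord <- order(got_df$chrom, got_df$pos, got_df$strand)
  expect_equal(got_df[ord, ], exp, ignore_attr = TRUE)
})

test_that("site sequence extraction centers, clamps and respects strand", {
  genome <- Biostrings::DNAStringSet(c(chrZ = paste(rep("ACGT", 30),
                                                    collapse = "")))
  site <- GRanges("chrZ", IRanges(60, width = 1), strand = "+")
  s <- extract_site_sequences(site, genome, flank = 10)
  expect_equal(unname(nchar(as.character(s))), 21L)
  expect_equal(as.character(Biostrings::subseq(s[[1]], 11, 11)),
               as.character(genome[[1]][60]))
  # minus strand returns the reverse complement of the plus extraction
  site_m <- site; strand(site_m) <- "-"
  sm <- extract_site_sequences(site_m, genome, flank = 10)
  expect_equal(as.character(sm[[1]]),
               as.character(Biostrings::reverseComplement(s[[1]])))
  # clamping near the chromosome edge
  edge <- GRanges("chrZ", IRanges(4, width = 1), strand = "+")
  expect_equal(unname(nchar(as.character(
    extract_site_sequences(edge, genome, 10)))), 14L)
})

test_that("background construction is seeded, excludes sites, preserves composition", {
  st <- small_study()
  aln <- st$sim$clip[[1]]
  sites <- call_crosslink_sites(aln)
  expect_gt(length(sites), 0)
  bg1 <- make_background(sites, st$ref$genome, aln = aln, seed = 3)
  bg2 <- make_background(sites, st$ref$genome, aln = aln, seed = 3)
  expect_identical(as.character(bg1), as.character(bg2))
  expect_equal(length(bg1), 5L * length(sites))
  # shuffle mode preserves per-sequence length and base multiset
  fg <- extract_site_sequences(sites, st$ref$genome)
  sh <- make_background(sites, st$ref$genome, mode = "shuffle",
                        n_ratio = 1L, seed = 5)
  for (i in seq_along(sh)) {
    expect_equal(sort(strsplit(as.character(sh[[i]]), "")[[1]]),
                 sort(strsplit(as.character(fg[[i]]), "")[[1]]))
  }
})

test_that("ZOOPS counts once per sequence and matches the substring-set oracle", {
  expect_equal(kmer_zoops(c("ACGACG"), 3)[["ACG"]], 1L)
  expect_equal(kmer_zoops(c("ACG", "ACG"), 3)[["ACG"]], 2L)
  expect_false("CGN" %in% names(kmer_zoops(c("ACGNT"), 3)))
  expect_warning(kmer_zoops(c("AC"), 5), "empty")
  set.seed(11)
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 21, replace = TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = ""),
    character(1))
  for (k in c(3L, 5L)) {
    got <- kmer_zoops(seqs, k)
    exp <- oracle_zoops(seqs, k)
    expect_equal(got[order(names(got))], exp[order(names(exp))])
    expect_true(all(got <= length(seqs)))
  }
})

test_that("k-mer Fisher p-values agree with hypergeometric enumeration", {
  # [[2,0],[0,2]]: the fully-enriched 2+2 table has one-sided p = 1/6
  r <- kmer_enrichment(c(AA = 2L), c(AA = 0L), n_fg = 2, n_bg = 2)
  expect_equal(r$p, 1 / 6, tolerance = 1e-12)
  # identical proportions are never "enriched": p >= 0.5
  r2 <- kmer_enrichment(c(AA = 3L), c(AA = 3L), n_fg = 6, n_bg = 6)
  expect_gte(r2$p, 0.5)
  # grid agreement with the enumeration oracle for all tables, total <= 20
  for (n_fg in c(3L, 6L)) for (n_bg in c(4L, 9L)) {
    for (a in 0:n_fg) for (b in 0:n_bg) {
      got <- kmer_enrichment(stats::setNames(a, "K"),
                             stats::setNames(b, "K"), n_fg, n_bg)$p
      expect_equal(got, fisher_oracle_p(a, n_fg - a, b, n_bg - b,
                                        alternative = "greater"),
                   tolerance = 1e-9,
                   info = sprintf("a=%d b=%d nfg=%d nbg=%d", a, b, n_fg, n_bg))
    }
  }
})

test_that("Fisher's method has the right identities and chi-square tail", {
  r <- combine_fisher(c(1, 1, 1))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  # m = 1 is the identity
  for (p in c(0.9, 0.31, 1e-5)) {
    expect_equal(combine_fisher(p)$p, p, tolerance = 1e-12)
  }
  # numerical integration of the chi-square(6) density as oracle
  r3 <- combine_fisher(c(0.5, 0.5, 0.5))
  chi2 <- -6 * log(0.5)
  oracle <- stats::integrate(function(x) stats::dchisq(x, df = 6), chi2, Inf,
                             rel.tol = 1e-12)$value
  expect_equal(r3$chi2, chi2)
  expect_equal(r3$df, 6L)
  expect_equal(r3$p, oracle, tolerance = 1e-9)
  expect_warning(combine_fisher(c(0.5, 0)), "clamped")
})

test_that("motif ranking is invariant under replicate order permutation", {
  st <- small_study()
  sites <- lapply(st$sim$clip, call_crosslink_sites)
  t1 <- rank_motifs(sites, st$ref$genome, k_range = 5L,
                    aln_sets = st$sim$clip, seed = 9)
  perm <- c(3, 1, 2)
  t2 <- rank_motifs(sites[perm], st$ref$genome, k_range = 5L,
                    aln_sets = st$sim$clip[perm], seed = 9)
  expect_equal(t1$kmer, t2$kmer)
  expect_equal(t1$p_combined, t2$p_combined, tolerance = 1e-12)
  expect_equal(t1$fg_with, t2$fg_with)
  # reported foreground fraction is consistent
  expect_equal(t1$fg_fraction, t1$fg_with / t1$n_fg)
})
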