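test_that("anchor profiles are flat for uniform coverage and oriented by strand", {
  # one long read gives coverage 1 across the whole window
  aln <- make_aln("chrT", 1, "600M")
  anch <- GRanges("chrT", IRanges(300, width = 1), strand = "+")
  prof <- anchor_profile(aln, anch, half_window = 100, normalize = "none")
  expect_equal(length(prof$values), 201L)
  expect_true(all(prof$values == 1))
  # a coverage step downstream of a minus-strand anchor appears at
  # positive offsets after orientation flip
  aln2 <- make_aln("chrT", c(1, 1), c("600M", "300M"))  # higher cov left
  anch_m <- GRanges("chrT", IRanges(350, width = 1), strand = "-")
  pm <- anchor_profile(aln2, anch_m, half_window = 100, normalize = "none")
  # genomic left (<=300) is downstream for the minus anchor
  expect_true(all(pm$values[pm$offsets > 50] == 2))
  expect_true(all(pm$values[pm$offsets < 49] == 1))
  # mirrored plus-strand anchor reproduces the mirrored profile exactly
  anch_p <- anch_m; strand(anch_p) <- "+"
  pp <- anchor_profile(aln2, anch_p, half_window = 100, normalize = "none")
  expect_equal(pm$values, rev(pp$values))
})

test_that("cpm scaling makes profiles invariant to read duplication", {
  st <- small_study()
  aln <- st$sim$input
  anch <- anchors_from_annotation(st$ref$ann, "tss")
  p1 <- anchor_profile(aln, anch, half_window = 200, normalize = "cpm")
  p2 <- anchor_profile(c(aln, aln), anch, half_window = 200,
                       normalize = "cpm")
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

test_that("anchors truncated by chromosome edges contribute defined offsets only", {
  aln <- make_aln("chrT", 1, "200M")
  anch <- GRanges("chrT", IRanges(30, width = 1), strand = "+")
  prof <- anchor_profile(aln, anch, half_window = 100, normalize = "none")
  expect_true(all(is.na(prof$values[prof$offsets < -29])))
  expect_true(all(prof$values[prof$offsets >= -29 & prof$offsets <= 100] == 1))
})

test_that("region RPKM is consistent with window RPKM and scales with length", {
  st <- small_study()
  aln <- st$sim$input
  win <- tile_windows(st$ref$ann$chrom_sizes, 50L)[200:210]
  expect_equal(region_rpkm(aln, win), window_rpkm(aln, win)$rpkm)
  # doubling region length with the same reads halves RPKM when counts equal
  r1 <- GRanges("simchr1", IRanges(1, width = 500))
  r2 <- GRanges("simchr1", IRanges(1, width = 1000))
  c1 <- countOverlaps(r1, grglist(read_alignments(aln)))
  c2 <- countOverlaps(r2, grglist(read_alignments(aln)))
  if (c1 == c2) {
    expect_equal(region_rpkm(aln, r2), region_rpkm(aln, r1) / 2)
  }
  expect_error(region_rpkm(aln, GRanges("simchr1", IRanges(5, 4))),
               "zero-length")
  # brute-force overlap-count oracle over planted cluster regions
  got <- region_rpkm(aln, st$ref$truth$clusters)
  exp_counts <- oracle_region_counts(read_alignments(aln),
                                     st$ref$truth$clusters)
  expect_equal(got, rpkm(exp_counts, width(st$ref$truth$clusters),
                         length(aln)))
})

test_that("Mann-Whitney U handles exact, approximate and degenerate cases", {
  expect_equal(mannwhitney_u(c(3, 3, 3), c(3, 3, 3))$p, 1)
  r <- mannwhitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # exact p equals full permutation enumeration for n <= 12
  set.seed(31)
  for (i in 1:6) {
    x <- round(stats::rnorm(sample(3:6, 1)), 3)
    y <- round(stats::rnorm(sample(3:6, 1), mean = 0.8), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(mannwhitney_u(x, y)$p, mwu_oracle_p(x, y),
                 tolerance = 1e-9)
  }
  # the normal approximation tracks the permutation p for n = 8 vs 8
  set.seed(17)
  for (i in 1:5) {
    x <- stats::rnorm(8)
    y <- stats::rnorm(8, mean = 0.6)
    expect_lt(abs(mannwhitney_u(x, y)$p - mwu_oracle_p(x, y)), 0.01)
  }
})

test_that("exon-context comparison degenerates to p = 1 when focus equals background", {
  toy <- toy_annotation()
  aln <- make_aln("chrT", seq(90, 1800, by = 37), "50M",
                  strand = rep(c("+", "-"), length.out = 47))
  ex <- GRanges("chrT", IRanges(c(301, 1301), width = 100))
  res <- compare_exon_context(aln, ex, ex, toy$ann)
  expect_equal(res$flanking_exons$p, 1)
  expect_equal(res$gene_body$p, 1)
})

test_that("exon-context comparison equals the region-RPKM + U-test composition", {
  st <- small_study()
  ann <- st$ref$ann
  aln <- st$sim$clip[[1]]
  mparts <- lapply(unique(ann$tx$gene_id[ann$tx$biotype == "mRNA"]),
                   function(g) flatten_exonic_parts(ann, g))
  focus <- do.call(c, lapply(mparts[1:3], function(p) granges(p[2])))
  backg <- do.call(c, lapply(mparts[4:8], function(p) granges(p[2])))
  res <- compare_exon_context(aln, focus, backg, ann)
  # manual composition for the gene-body kind
  gene_of <- function(ex) ann$genes[overlapsAny(ann$genes, ex,
                                                ignore.strand = TRUE)]
  rf <- region_rpkm(aln, do.call(c, lapply(seq_along(focus),
                                           function(i) gene_of(focus[i]))))
  rb <- region_rpkm(aln, do.call(c, lapply(seq_along(backg),
                                           function(i) gene_of(backg[i]))))
  mw <- mannwhitney_u(rf, rb)
  expect_equal(res$gene_body$p, mw$p)
  expect_equal(sort(res$gene_body$rpkm_focus), sort(unname(rf)))
})

test_that("planted intron-flank binding separates focus exons from background", {
  cfg <- sim_config(seed = 77L, library_size_clip = 30000L,
                    library_size_input = 10000L,
                    planted_clusters = data.frame(
                      gene = sprintf("G%02d", 5:8),
                      region = "intron", fold = 12))
  ref <- simulate_reference(cfg)
  sim <- simulate_clip_experiment(cfg, ref)
  ann <- ref$ann
  cl <- ref$truth$clusters
  # focus: both exonic parts flanking each planted intron; background: the
  # first two parts of the unplanted mRNA genes
  focus <- do.call(c, lapply(seq_along(cl), function(i) {
    parts <- flatten_exonic_parts(ann, cl$gene_id[i])
    c(granges(tail(parts[end(parts) < start(cl)[i]], 1)),
      granges(head(parts[start(parts) > end(cl)[i]], 1)))
  }))
  backg_genes <- setdiff(ann$genes$gene_id[ann$genes$biotype == "mRNA"],
                         cl$gene_id)
  backg <- do.call(c, lapply(backg_genes, function(g)
    granges(flatten_exonic_parts(ann, g)[1:2])))
  pooled <- do.call(c, sim$clip)
  res <- compare_exon_context(pooled, focus, backg, ann)
  expect_lt(res$flanking_introns$p, 0.01)
  expect_gt(res$gene_body$p, res$flanking_introns$p)
})

test_that("coverage-ratio profiles are 1 for identical libraries and track planted change", {
  st <- small_study()
  anch <- anchors_from_annotation(st$ref$ann, "polya")
  cr <- coverage_ratio_profile(st$sim$input, st$sim$input, anch, 150)
  expect_true(all(abs(cr$values - 1) < 1e-12))
  expect_true(all(abs(cr$log2_ratio) < 1e-12))
  # doubled coverage downstream of anchors only
  aln_b <- make_aln("chrT", c(101, 101, 301, 301, 301), "200M")
  aln_a <- make_aln("chrT", c(101, 101, 301, 301, 301, 301, 301, 301,
                              301, 301), "200M")
  anch2 <- GRanges("chrT", IRanges(300, width = 1), strand = "+")
  cr2 <- coverage_ratio_profile(aln_a, aln_b, anch2, 100)
  up <- cr2$values[cr2$offsets > 5]
  dn <- cr2$values[cr2$offsets < -5]
  expect_gt(stats::median(up), stats::median(dn))
})
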