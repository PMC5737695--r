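mk_records <- function(n_last, n_internal, de_last, de_internal,
                       lfc_last = 2, lfc_internal = 1, seed = 1) {
  set.seed(seed)
  n <- n_last + n_internal
  is_last <- c(rep(TRUE, n_last), rep(FALSE, n_internal))
  de <- c(seq_len(n_last) <= de_last, seq_len(n_internal) <= de_internal)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             part_id = sprintf("g%03d:E001", seq_len(n)),
             pos_from_3p = ifelse(is_last, 1L, 2L),
             is_last = is_last,
             log2fc = ifelse(de, ifelse(is_last, lfc_last, lfc_internal),
                             stats::rnorm(n, 0, 0.05)),
             padj = ifelse(de, 1e-8, stats::runif(n, 0.5, 1)))
}

test_that("last-exon enrichment builds the 2x2 table and odds ratio from the filters", {
  rec <- mk_records(10, 90, de_last = 8, de_internal = 10)
  res <- last_exon_enrichment(rec)
  expect_equal(unname(res$table), matrix(c(8, 2, 10, 80), nrow = 2,
                                         byrow = TRUE))
  expect_equal(res$odds_ratio, 32)
  # p equals the fixed-margin hypergeometric enumeration oracle
  expect_equal(res$p, fisher_oracle_p(8, 2, 10, 80), tolerance = 1e-9)
  expect_error(last_exon_enrichment(rec[!rec$is_last, ]), "no last exons")
})

test_that("enrichment is invariant under record shuffling", {
  rec <- mk_records(12, 80, de_last = 7, de_internal = 9)
  res1 <- last_exon_enrichment(rec)
  set.seed(4)
  res2 <- last_exon_enrichment(rec[sample(nrow(rec)), ])
  expect_equal(res1$table, res2$table)
  expect_equal(res1$p, res2$p)
})

test_that("direction counts partition DE records and flip under sign reversal", {
  rec <- mk_records(10, 50, de_last = 6, de_internal = 8)
  rec$log2fc[rec$is_last & rec$padj < 0.05][1:2] <- -2  # two down last exons
  ds <- direction_summary(rec)
  expect_equal(ds$up + ds$down + ds$zero, ds$de_total)
  expect_equal(ds$up[ds$stratum == "last"], 4)
  expect_equal(ds$down[ds$stratum == "last"], 2)
  flipped <- rec; flipped$log2fc <- -flipped$log2fc
  dsf <- direction_summary(flipped)
  expect_equal(dsf$up, ds$down)
  expect_equal(dsf$down, ds$up)
  # all-up last exons: zero downs
  rec2 <- mk_records(10, 50, de_last = 6, de_internal = 0)
  expect_equal(direction_summary(rec2)$down[1], 0)
})

test_that("CDF comparison returns p = 1 for identical samples and shifts cleanly", {
  a <- c(0.1, 0.4, 0.9, 1.4)
  res <- cdf_compare(a, a)
  expect_equal(res$p, 1)
  expect_equal(res$cdf_a, res$cdf_b)
  res2 <- cdf_compare(a, a + 1)
  expect_equal(res2$cdf_b$value, res2$cdf_a$value + 1)
  expect_equal(res2$cdf_b$cdf, res2$cdf_a$cdf)
})

test_that("position profiles summarize by 3'-end rank and test against pooled internals", {
  # degenerate: all zero log2FC
  rec0 <- data.frame(gene_id = "g", part_id = letters[1:20],
                     pos_from_3p = rep(1:4, 5), is_last = rep(1:4, 5) == 1,
                     log2fc = 0, padj = 0.5)
  pp0 <- position_profile(rec0, max_pos = 4)
  expect_true(all(pp0$median == 0))
  expect_equal(pp0$p[1], 1)
  expect_equal(pp0$flag[1], "degenerate")
  # shifted last-exon values separate at n = 50 per group
  set.seed(9)
  rec1 <- data.frame(gene_id = "g", part_id = as.character(1:150),
                     pos_from_3p = rep(1:3, each = 50),
                     is_last = rep(1:3, each = 50) == 1,
                     log2fc = c(stats::rnorm(50, 1), stats::rnorm(100, 0)),
                     padj = 0.5)
  pp1 <- position_profile(rec1, max_pos = 3)
  expect_lt(pp1$p[1], 0.01)
  # t and p match the closed-form Welch oracle
  v <- rec1$log2fc[rec1$pos_from_3p == 1]
  pool <- rec1$log2fc[rec1$pos_from_3p >= 2]
  se2 <- var(v) / length(v) + var(pool) / length(pool)
  t_exp <- (mean(v) - mean(pool)) / sqrt(se2)
  df_exp <- se2^2 / ((var(v) / length(v))^2 / (length(v) - 1) +
                       (var(pool) / length(pool))^2 / (length(pool) - 1))
  p_exp <- 2 * stats::pt(-abs(t_exp), df_exp)
  expect_equal(pp1$t[1], t_exp, tolerance = 1e-9)
  expect_equal(pp1$p[1], p_exp, tolerance = 1e-9)
  expect_error(position_profile(rec0[rec0$pos_from_3p == 1, ]),
               ">= 2 positions")
})

test_that("exon correlation joins on part identity and recovers planted correlations", {
  rec <- mk_records(10, 40, de_last = 5, de_internal = 5)
  expect_equal(exon_correlation(rec, rec)$r, 1)
  neg <- rec; neg$log2fc <- -neg$log2fc
  expect_equal(exon_correlation(rec, neg)$r, -1)
  expect_error(exon_correlation(rec[1:2, ], rec[1:2, ]), "fewer than 3")
  # planted bivariate correlation rho = -0.57 recovered within +-0.08
  rho <- -0.57; n <- 500
  hits <- 0L
  for (s in 1:20) {
    set.seed(300 + s)
    a <- stats::rnorm(n)
    b <- rho * a + sqrt(1 - rho^2) * stats::rnorm(n)
    ra <- data.frame(gene_id = "g", part_id = as.character(seq_len(n)),
                     pos_from_3p = 1L, is_last = TRUE, log2fc = a,
                     padj = 0.01)
    rb <- ra; rb$log2fc <- b
    if (abs(exon_correlation(ra, rb)$r - rho) <= 0.08) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("annotation-derived tables have exactly one last part per gene", {
  st <- small_study()
  de <- simulate_exon_de_table(st$cfg, st$ref$ann)
  per_gene <- tapply(de$is_last, de$gene_id, sum)
  expect_true(all(per_gene == 1L))
})

test_that("mRNA region split reflects the precursor-read excess of CLIP over input", {
  st <- small_study()
  idx <- build_region_index(st$ref$ann)
  fr_clip <- mrna_region_fractions(st$sim$clip[[1]], idx)
  fr_input <- mrna_region_fractions(st$sim$input, idx)
  expect_equal(sum(fr_clip), 1, tolerance = 1e-9)
  expect_equal(sum(fr_input), 1, tolerance = 1e-9)
  # CLIP draws half its reads from precursors, input only 15%
  expect_gt(fr_clip[["intron"]], 2 * fr_input[["intron"]])
})
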