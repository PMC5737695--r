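# Last-exon differential-expression statistics over exonic-part tables:
# enrichment, direction summaries, CDF comparisons, per-position profiles
# and cross-condition correlation.

#' Read an exon-level differential-expression table
#'
#' TSV contract: header row with columns `gene_id`, `part_id`,
#' `pos_from_3p`, `log2fc`, `padj` (`is_last` derived as `pos_from_3p == 1`
#' when absent).
#'
#' @param path TSV file.
#' @return Validated `data.frame`.
#' @export
read_exon_de <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "part_id", "pos_from_3p", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$is_last)) df$is_last <- df$pos_from_3p == 1L
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
    stop("padj values must lie in [0, 1]")
  df
}

#' Last-exon enrichment among differentially expressed exonic parts
#'
#' DE status is `padj < alpha` and `|log2fc| >= min_abs_lfc`; the 2x2 table
#' last-vs-internal x DE-vs-not is tested by Fisher's exact test (two-sided
#' by default, point-probability method). The reported odds ratio is the
#' unconditional `(a d)/(b c)`, Haldane-corrected (+0.5 per cell) when any
#' cell is zero.
#'
#' @param records DE `data.frame` (see [read_exon_de()]).
#' @param alpha adjusted p-value threshold (exclusive).
#' @param min_abs_lfc absolute log2 fold-change threshold (inclusive;
#'   default 0, matching an FDR-only DE criterion).
#' @param alternative passed to [stats::fisher.test()].
#' @return An `enrichment_result`: `table`, `odds_ratio`, `p`,
#'   `direction_counts`.
#' @export
last_exon_enrichment <- function(records, alpha = 0.05, min_abs_lfc = 0,
                                 alternative = "two.sided") {
  if (!any(records$is_last)) stop("no last exons present in the table")
  de <- records$padj < alpha & abs(records$log2fc) >= min_abs_lfc
  a <- sum(records$is_last & de);  b <- sum(records$is_last & !de)
  cc <- sum(!records$is_last & de); d <- sum(!records$is_last & !de)
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("last", "internal"), c("DE", "not_DE")))
  ft <- stats::fisher.test(tab, alternative = alternative)
  or <- if (any(tab == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else (a * d) / (b * cc)
  dirs <- direction_summary(records, alpha = alpha,
                            min_abs_lfc = min_abs_lfc)
  structure(list(table = tab, odds_ratio = or, p = ft$p.value,
                 direction_counts = dirs, alpha = alpha,
                 min_abs_lfc = min_abs_lfc),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Last-exon DE enrichment (padj <", x$alpha, ", |log2FC| >=",
      x$min_abs_lfc, ")\n")
  print(x$table)
  cat("odds ratio =", signif(x$odds_ratio, 4),
      "; Fisher exact p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Up/down counts of DE exonic parts, stratified by last vs internal
#'
#' Among DE records (`padj < alpha`, `|log2fc| >= min_abs_lfc`), counts of
#' upregulated (`log2fc > 0`) and downregulated (`log2fc < 0`) parts per
#' stratum; DE records with exactly zero log2FC are counted in neither and
#' reported separately.
#'
#' @inheritParams last_exon_enrichment
#' @param min_abs_lfc default 0.5 log2, the fold filter used for direction
#'   counts.
#' @return `data.frame(stratum, up, down, zero, de_total)`.
#' @export
direction_summary <- function(records, alpha = 0.05, min_abs_lfc = 0.5) {
  de <- records$padj < alpha & abs(records$log2fc) >= min_abs_lfc
  strat <- function(sel) {
    data.frame(up = sum(sel & de & records$log2fc > 0),
               down = sum(sel & de & records$log2fc < 0),
               zero = sum(sel & de & records$log2fc == 0),
               de_total = sum(sel & de))
  }
  cbind(data.frame(stratum = c("last", "internal")),
        rbind(strat(records$is_last), strat(!records$is_last)))
}

#' Compare two value distributions by Mann-Whitney U and empirical CDFs
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @return List `U`, `p`, `cdf_a`, `cdf_b` (step-function tables with
#'   columns `value`, `cdf`).
#' @export
cdf_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1L, length(values_b) >= 1L)
  mw <- mannwhitney_u(values_a, values_b)
  step_tab <- function(v) {
    knots <- sort(unique(v))
    data.frame(value = knots, cdf = stats::ecdf(v)(knots))
  }
  list(U = mw$U, p = mw$p,
       cdf_a = step_tab(values_a), cdf_b = step_tab(values_b))
}

#' Per-position log2FC profile from the 3' end
#'
#' For exonic-part positions 1..`max_pos` counted from the 3' end (1 = last
#' exon), reports n, median and quartiles of log2FC plus a two-tailed
#' t-test of each position's values against the pooled internal parts
#' (positions >= 2, excluding the tested position). Positions with n < 2
#' keep their summary but skip the test (`flag = "too_few"`); an all-equal
#' degenerate comparison returns p = 1 with `flag = "degenerate"`.
#'
#' @param records DE `data.frame`.
#' @param max_pos largest 3'-end position reported.
#' @return `data.frame(pos_from_3p, n, median, q25, q75, t, p, flag)`.
#' @export
position_profile <- function(records, max_pos = 10L) {
  if (length(unique(records$pos_from_3p)) < 2L)
    stop("records must span >= 2 positions")
  internal <- records$log2fc[records$pos_from_3p >= 2L]
  rows <- lapply(seq_len(max_pos), function(p) {
    v <- records$log2fc[records$pos_from_3p == p]
    pool <- if (p == 1L) internal
            else records$log2fc[records$pos_from_3p >= 2L &
                                  records$pos_from_3p != p]
    base <- data.frame(pos_from_3p = p, n = length(v),
                       median = if (length(v)) stats::median(v) else NA_real_,
                       q25 = if (length(v))
                         unname(stats::quantile(v, 0.25)) else NA_real_,
                       q75 = if (length(v))
                         unname(stats::quantile(v, 0.75)) else NA_real_)
    if (length(v) < 2L || length(pool) < 2L)
      return(cbind(base, t = NA_real_, p = NA_real_, flag = "too_few"))
    if (length(unique(c(v, pool))) == 1L)
      return(cbind(base, t = 0, p = 1, flag = "degenerate"))
    tt <- stats::t.test(v, pool)
    cbind(base, t = unname(tt$statistic), p = tt$p.value, flag = "ok")
  })
  do.call(rbind, rows)
}

#' Pearson correlation of exon-level log2FC between two conditions
#'
#' Joins two DE tables on `(gene_id, part_id)`, optionally keeping only
#' parts DE in both conditions, and reports the Pearson correlation of
#' their log2 fold changes.
#'
#' @param records_a,records_b DE `data.frame`s.
#' @param require_de_in_both keep only parts with `padj < alpha` in both.
#' @param alpha DE threshold used by the filter.
#' @return List `r`, `n`.
#' @export
exon_correlation <- function(records_a, records_b,
                             require_de_in_both = FALSE, alpha = 0.05) {
  m <- merge(records_a, records_b, by = c("gene_id", "part_id"),
             suffixes = c("_a", "_b"))
  if (require_de_in_both)
    m <- m[m$padj_a < alpha & m$padj_b < alpha, ]
  if (nrow(m) < 3L)
    stop("fewer than 3 shared exonic parts after filtering")
  list(r = stats::cor(m$log2fc_a, m$log2fc_b), n = nrow(m))
}

#' Fraction of mRNA reads per pre-mRNA region
#'
#' Among reads assigned to mRNA loci, the split between introns, 3'UTRs,
#' coding regions and 5'UTRs (exonic reads without CDS annotation stay
#' "exon"), echoing the canonical pre-mRNA region piechart of a nuclear
#' CLIP library.
#'
#' @param aln BAM path or `GAlignments`.
#' @param index `RegionIndex` (with CDS-derived subregions).
#' @return Named fractions over mRNA-assigned reads.
#' @export
mrna_region_fractions <- function(aln, index) {
  aln <- read_alignments(aln)
  lab <- categorize_reads(aln, index)
  blocks <- aligned_blocks(aln)
  is_exon <- lab == "mRNA exon"
  is_intron <- lab == "mRNA intron"
  sub <- index$subregions
  u5 <- is_exon & overlapsAny(blocks, sub$utr5, ignore.strand = TRUE)
  u3 <- is_exon & overlapsAny(blocks, sub$utr3, ignore.strand = TRUE) & !u5
  cds <- is_exon & overlapsAny(blocks, sub$cds, ignore.strand = TRUE) &
    !u5 & !u3
  other_ex <- is_exon & !u5 & !u3 & !cds
  n <- sum(is_exon) + sum(is_intron)
  if (n == 0L) stop("no mRNA reads to split")
  c(intron = sum(is_intron) / n, utr3 = sum(u3) / n, cds = sum(cds) / n,
    utr5 = sum(u5) / n, exon_other = sum(other_ex) / n)
}
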