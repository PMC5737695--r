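# Priority-based read categorization and exon-exon vs exon-intron
# junction-spanning statistics.

#' Categorize aligned reads by the RNA-class priority table
#'
#' A read "overlaps" a class when any of its aligned blocks (M/=/X segments,
#' with deletions absorbed; N splice gaps confer no overlap) intersects a
#' class region on the matching strand ("antisense mRNA" regions carry the
#' inverted strand, so the match is uniform). Among all classes a read
#' overlaps, the one with the smallest priority number wins; reads touching
#' nothing are "unannotated".
#'
#' @param aln BAM path or `GAlignments` (primary alignments).
#' @param index `RegionIndex` from [build_region_index()].
#' @param ignore_strand drop the strand requirement (the antisense class is
#'   then never assigned).
#' @return Factor of class labels, levels = [CLIP_CLASSES], one per read.
#' @export
categorize_reads <- function(aln, index, ignore_strand = FALSE) {
  aln <- read_alignments(aln)
  blocks <- aligned_blocks(aln)
  label <- factor(rep("unannotated", length(aln)), levels = CLIP_CLASSES)
  remaining <- seq_along(aln)
  for (cl in names(index$classes)) {
    if (!length(remaining)) break
    reg <- index$classes[[cl]]
    if (cl == "antisense mRNA" && ignore_strand) next
    if (!length(reg)) next
    hit <- overlapsAny(blocks[remaining], reg, ignore.strand = ignore_strand)
    label[remaining[hit]] <- cl
    remaining <- remaining[!hit]
  }
  label
}

#' Distribution of reads among RNA classes
#'
#' Per-class counts and fractions (fractions sum to 1 over categorized
#' primary alignments).
#'
#' @inheritParams categorize_reads
#' @return List with `counts`, `fractions` (both named by class) and `n`.
#' @export
category_distribution <- function(aln, index, ignore_strand = FALSE) {
  aln <- read_alignments(aln)
  if (length(aln) == 0L)
    stop("zero categorizable reads: alignment set is empty")
  lab <- categorize_reads(aln, index, ignore_strand = ignore_strand)
  counts <- table(lab)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 fractions = stats::setNames(as.numeric(counts / sum(counts)),
                                             names(counts)),
                 n = length(aln)),
            class = "category_distribution")
}

#' @export
print.category_distribution <- function(x, ...) {
  cat("Read class distribution over", x$n, "primary alignments:\n")
  print(round(x$fractions[x$counts > 0], 4))
  invisible(x)
}

# Annotated introns (unique, stranded) and the exon/intron boundary points
# flanking them, as the last exonic base before each boundary.
annotated_introns <- function(ann) {
  unique(unlist(ann$introns_by_tx, use.names = FALSE))
}

#' Count exon-exon and exon-intron junction-spanning reads
#'
#' EE reads carry an N splice gap that matches an annotated intron exactly
#' (both splice sites) with at least `min_overhang` aligned bases on each
#' side. EI reads are contiguous (no N) and cross an annotated exon/intron
#' boundary with at least `min_overhang` bases on each side. A read counts
#' at most once per class.
#'
#' @param aln BAM path or `GAlignments`.
#' @param ann `GenomeAnnotation`.
#' @param min_overhang minimum aligned bases on each side of the junction or
#'   boundary (>= 1).
#' @param sample_id label carried into the result.
#' @param ignore_strand drop the read-vs-transcript strand match.
#' @return A `junction_counts` list: `ee`, `ei`, `ratio_ei_ee`,
#'   `ratio_ee_ei`, `frac_ei` (= EI / (EE + EI)).
#' @export
junction_counts <- function(aln, ann, min_overhang = 5L, sample_id = "sample",
                            ignore_strand = FALSE) {
  stopifnot(min_overhang >= 1L)
  aln <- read_alignments(aln)
  introns <- annotated_introns(ann)

  # EE: exact intron match with sufficient flanking block widths
  ee <- 0L
  spliced <- which(njunc(aln) > 0L)
  if (length(spliced) && length(introns)) {
    ga <- aln[spliced]
    gaps <- junctions(ga)                  # per-read N gaps, ref-ascending
    blocks <- aligned_blocks(ga)
    gap_gr <- unlist(gaps, use.names = FALSE)
    read_of <- rep(seq_along(ga), lengths(gaps))
    gap_rank <- unlist(lapply(lengths(gaps), seq_len), use.names = FALSE)
    m <- if (ignore_strand) match(unstrand(gap_gr), unstrand(introns))
         else match(gap_gr, introns)
    ok <- !is.na(m)
    if (any(ok)) {
      flat_w <- unlist(width(blocks), use.names = FALSE)
      off <- cumsum(lengths(blocks)) - lengths(blocks)
      left_w <- flat_w[off[read_of[ok]] + gap_rank[ok]]
      right_w <- flat_w[off[read_of[ok]] + gap_rank[ok] + 1L]
      pass <- left_w >= min_overhang & right_w >= min_overhang
      ee <- length(unique(read_of[ok][pass]))
    }
  }

  # EI: contiguous reads fully covering [b - o + 1, b + o] for a boundary at
  # last-exonic-base b (intron start - 1 or intron end)
  ei <- 0L
  contig <- which(njunc(aln) == 0L)
  if (length(contig) && length(introns)) {
    b <- c(start(introns) - 1L, end(introns))
    bstr <- rep(strand(introns), 2L)
    bchr <- rep(seqnames(introns), 2L)
    bwin <- GRanges(bchr, IRanges(b - min_overhang + 1L, b + min_overhang),
                    strand = bstr)
    bwin <- unique(bwin)
    spans <- granges(aln[contig])          # includes D, no N by construction
    hits <- findOverlaps(bwin, spans, type = "within",
                         ignore.strand = ignore_strand)
    ei <- length(unique(subjectHits(hits)))
  }

  structure(list(sample_id = sample_id, ee = ee, ei = ei,
                 ratio_ei_ee = if (ee > 0) ei / ee else NA_real_,
                 ratio_ee_ei = if (ei > 0) ee / ei else NA_real_,
                 frac_ei = if (ee + ei > 0) ei / (ee + ei) else NA_real_),
            class = "junction_counts")
}

#' Compare exon-intron junction fractions between CLIP and input
#'
#' Two-sample, two-tailed Student's t-test (equal variances) on the
#' per-sample EI / (EE + EI) fractions, the stable form of the EI:EE ratio.
#' With zero variance in both groups and equal means the comparison is
#' degenerate; p = 1 is returned with `flagged = TRUE`.
#'
#' @param clip,input lists of `junction_counts` (>= 2 each).
#' @return List: `statistic`, `df`, `p`, `clip_frac`, `input_frac`,
#'   `flagged`.
#' @export
compare_junction_ratios <- function(clip, input) {
  fx <- vapply(clip, `[[`, numeric(1), "frac_ei")
  fy <- vapply(input, `[[`, numeric(1), "frac_ei")
  if (length(fx) < 2L || length(fy) < 2L)
    stop("need >= 2 samples per group for a t-test")
  if (any(!is.finite(c(fx, fy)))) stop("non-finite junction fractions")
  if (stats::sd(fx) == 0 && stats::sd(fy) == 0) {
    # zero variance in both groups: p = 1 for equal means by convention,
    # p = 0 (infinite separation) otherwise; flagged either way
    equal <- mean(fx) == mean(fy)
    return(list(statistic = if (equal) 0 else Inf * sign(mean(fx) - mean(fy)),
                df = length(fx) + length(fy) - 2L,
                p = if (equal) 1 else 0,
                clip_frac = fx, input_frac = fy, flagged = TRUE))
  }
  tt <- stats::t.test(fx, fy, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, clip_frac = fx, input_frac = fy, flagged = FALSE)
}
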