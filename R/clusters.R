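# 50-bp window tiling, CLIP-vs-input RPKM scoring and binding-cluster
# calling, with both published filter variants, plus replicate-overlap and
# planted-truth evaluation helpers.

#' Tile chromosomes into fixed-width windows
#'
#' Non-overlapping adjacent tiles per chromosome; the final partial tile is
#' kept and its true width enters the RPKM denominator.
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param width window width in bases (default 50).
#' @return `GRanges` partition of the genome.
#' @export
tile_windows <- function(chrom_sizes, width = 50L) {
  if (width < 1L) stop("config error: window width must be >= 1")
  GenomicRanges::tileGenome(chrom_sizes, tilewidth = width,
                            cut.last.tile.in.chrom = TRUE)
}

#' Window read counts and RPKM for one library
#'
#' A read counts in every window any of its aligned blocks overlaps
#' (bedtools-coverage semantics); windows are unstranded genome tiles.
#'
#' @param aln BAM path or `GAlignments`.
#' @param windows window `GRanges` from [tile_windows()].
#' @return List with `counts`, `rpkm` and `lib_size`.
#' @export
window_rpkm <- function(aln, windows) {
  aln <- read_alignments(aln)
  if (length(aln) == 0L) {
    warning("empty alignment set: all-zero window counts")
    return(list(counts = integer(length(windows)),
                rpkm = numeric(length(windows)), lib_size = 0L))
  }
  counts <- countOverlaps(windows, aligned_blocks(aln),
                          ignore.strand = TRUE)
  list(counts = counts,
       rpkm = rpkm(counts, width(windows), length(aln)),
       lib_size = length(aln))
}

#' Score windows for CLIP replicates against an input library
#'
#' Computes per-replicate CLIP counts/RPKM and input counts/RPKM over a
#' shared window grid; the container consumed by [call_clusters()].
#'
#' @param clip list of BAM paths or `GAlignments`, one per replicate.
#' @param input BAM path or `GAlignments`.
#' @param chrom_sizes named chromosome lengths (required unless `windows`
#'   given).
#' @param windows optional precomputed window grid.
#' @param width window width when tiling.
#' @return A `window_scores` object.
#' @export
window_scores <- function(clip, input, chrom_sizes = NULL, windows = NULL,
                          width = 50L) {
  if (!is.list(clip)) clip <- list(clip)
  clip <- lapply(clip, read_alignments)
  input <- read_alignments(input)
  if (is.null(windows)) {
    if (is.null(chrom_sizes)) {
      sl <- seqlengths(clip[[1]])
      if (any(is.na(sl))) stop("chrom_sizes required (no seqlengths on BAM)")
      chrom_sizes <- sl
    }
    windows <- tile_windows(chrom_sizes, width)
  }
  wr <- lapply(clip, window_rpkm, windows = windows)
  wi <- window_rpkm(input, windows)
  structure(list(
    windows = windows,
    counts_clip = do.call(cbind, lapply(wr, `[[`, "counts")),
    rpkm_clip = do.call(cbind, lapply(wr, `[[`, "rpkm")),
    counts_input = wi$counts, rpkm_input = wi$rpkm,
    lib_clip = vapply(wr, `[[`, integer(1), "lib_size"),
    lib_input = wi$lib_size,
    width = width,
    clip = clip, input = input), class = "window_scores")
}

#' @export
print.window_scores <- function(x, ...) {
  cat("window_scores:", length(x$windows), "windows x",
      ncol(x$counts_clip), "CLIP replicates (libraries:",
      paste(x$lib_clip, collapse = "/"), "CLIP,", x$lib_input, "input)\n")
  invisible(x)
}

default_pseudocount <- function(scores) {
  1e9 / (scores$width * min(c(scores$lib_clip, scores$lib_input)))
}

#' Call binding clusters from scored windows
#'
#' Two published filter variants sit behind `mode`:
#' * `"results"` (default): a window passes when its per-replicate
#'   pseudocount-adjusted fold over input exceeds `min_fold` in at least
#'   `min_replicates` replicates AND the replicate-summed read count exceeds
#'   `min_reads` (strictly, ">10 reads").
#' * `"methods"`: a window passes when the pooled CLIP RPKM (replicate
#'   counts and library sizes summed) exceeds `min_fold` times input AND the
#'   summed count is at least `min_reads` ("minimum of 10 reads").
#'
#' Passing windows adjacent on a chromosome (gap <= `max_gap`) merge into
#' clusters; merged counts deduplicate reads by identity (each read counts
#' once per cluster) and the merged fold is recomputed on merged counts.
#'
#' @param scores `window_scores`.
#' @param mode `"results"` or `"methods"`.
#' @param min_fold fold-enrichment threshold (exclusive).
#' @param min_reads replicate-summed read threshold (inclusive in
#'   `"methods"` mode, exclusive in `"results"` mode, per the respective
#'   wording).
#' @param min_replicates replicates that must individually pass in
#'   `"results"` mode.
#' @param pseudocount RPKM pseudocount; default is the RPKM of one read in
#'   one window of the smallest library.
#' @param max_gap merge gap in bases (0 = only immediately adjacent).
#' @return `GRanges` of clusters with `cluster_id`, `n_windows`,
#'   `total_reads`, `fold`, `replicate_support`.
#' @export
call_clusters <- function(scores, mode = c("results", "methods"),
                          min_fold = 2, min_reads = 10L,
                          min_replicates = 2L, pseudocount = NULL,
                          max_gap = 0L) {
  mode <- match.arg(mode)
  stopifnot(methods::is(scores, "window_scores"))
  eps <- pseudocount %||% default_pseudocount(scores)
  sum_counts <- rowSums(scores$counts_clip)
  if (mode == "methods") {
    pooled_rpkm <- rpkm(sum_counts, width(scores$windows),
                        sum(scores$lib_clip))
    fold <- (pooled_rpkm + eps) / (scores$rpkm_input + eps)
    pass <- fold > min_fold & sum_counts >= min_reads
  } else {
    fold_rep <- (scores$rpkm_clip + eps) / (scores$rpkm_input + eps)
    n_pass <- rowSums(fold_rep > min_fold, na.rm = TRUE)
    pass <- n_pass >= min_replicates & sum_counts > min_reads
  }
  pass[is.na(pass)] <- FALSE   # 0/0 folds under a zero pseudocount
  merged <- reduce(scores$windows[pass], min.gapwidth = max_gap + 1L)
  if (length(merged) == 0L) {
    mcols(merged) <- DataFrame(cluster_id = character(0),
                               n_windows = integer(0),
                               total_reads = integer(0), fold = numeric(0),
                               replicate_support = integer(0))
    return(merged)
  }
  n_windows <- countOverlaps(merged, scores$windows[pass])
  if (!is.null(scores$clip)) {
    # merged counts deduplicate reads; fold recomputed on merged counts
    blocks <- lapply(scores$clip, aligned_blocks)
    cnt_rep <- vapply(blocks, function(b)
      countOverlaps(merged, b, ignore.strand = TRUE),
      integer(length(merged)))
    cnt_rep <- matrix(cnt_rep, nrow = length(merged))
    cnt_in <- countOverlaps(merged, aligned_blocks(scores$input),
                            ignore.strand = TRUE)
  } else {
    # no alignments attached: merged counts are member-window sums
    ov <- findOverlaps(scores$windows[pass], merged)
    grp <- factor(subjectHits(ov), levels = seq_along(merged))
    cnt_rep <- apply(scores$counts_clip[pass, , drop = FALSE], 2,
                     function(v) as.integer(rowsum(v[queryHits(ov)], grp)))
    cnt_rep <- matrix(cnt_rep, nrow = length(merged))
    cnt_in <- as.integer(rowsum(scores$counts_input[pass][queryHits(ov)],
                                grp))
  }
  total_reads <- rowSums(cnt_rep)
  pooled_rpkm <- rpkm(total_reads, width(merged), sum(scores$lib_clip))
  in_rpkm <- rpkm(cnt_in, width(merged), scores$lib_input)
  fold_merged <- (pooled_rpkm + eps) / (in_rpkm + eps)
  rep_rpkm <- sweep(cnt_rep, 2, scores$lib_clip, function(c, l)
    c * 1e9 / (width(merged) * l))
  support <- rowSums((rep_rpkm + eps) / (in_rpkm + eps) > min_fold)
  mcols(merged) <- DataFrame(
    cluster_id = sprintf("cluster_%05d", seq_along(merged)),
    n_windows = n_windows, total_reads = as.integer(total_reads),
    fold = fold_merged, replicate_support = as.integer(support))
  merged
}

#' Per-replicate clusters for reproducibility analysis
#'
#' Unfiltered clusters of one library: covered windows (count > 0) merged,
#' then kept when the deduplicated read count exceeds `min_reads` (">20
#' reads" at the default).
#'
#' @param aln BAM path or `GAlignments`.
#' @param windows window grid.
#' @param min_reads cluster read-count threshold (exclusive).
#' @return `GRanges` with `total_reads`.
#' @export
replicate_clusters <- function(aln, windows, min_reads = 20L) {
  aln <- read_alignments(aln)
  blocks <- aligned_blocks(aln)
  counts <- countOverlaps(windows, blocks, ignore.strand = TRUE)
  merged <- reduce(windows[counts > 0L])
  total <- countOverlaps(merged, blocks, ignore.strand = TRUE)
  merged <- merged[total > min_reads]
  mcols(merged)$total_reads <- total[total > min_reads]
  merged
}

#' Replicate overlap fraction of cluster sets
#'
#' Fraction of clusters (per replicate, then averaged) that overlap by at
#' least 1 bp a cluster from at least `min_support - 1` other replicates.
#'
#' @param cluster_list list of per-replicate cluster `GRanges`.
#' @param min_support replicates (including the cluster's own) required.
#' @return Overlap fraction in [0, 1].
#' @export
replicate_overlap <- function(cluster_list, min_support = 2L) {
  if (length(cluster_list) < 2L)
    stop("need >= 2 replicates for an overlap analysis")
  fracs <- vapply(seq_along(cluster_list), function(i) {
    cl <- cluster_list[[i]]
    if (length(cl) == 0L) return(NA_real_)
    others <- cluster_list[-i]
    n_sup <- rowSums(vapply(others, function(o)
      overlapsAny(cl, o, ignore.strand = TRUE), logical(length(cl))))
    mean(n_sup >= (min_support - 1L))
  }, numeric(1))
  mean(fracs, na.rm = TRUE)
}

#' Recall and precision of called clusters against planted truth
#'
#' 1-bp-overlap matching: recall is the fraction of truth intervals touched
#' by a call, precision the fraction of calls touching a truth interval.
#'
#' @param called cluster `GRanges`.
#' @param truth planted cluster `GRanges`.
#' @return List `recall`, `precision`, `n_called`, `n_truth`.
#' @export
cluster_recovery <- function(called, truth) {
  list(recall = if (length(truth))
         mean(overlapsAny(truth, called, ignore.strand = TRUE)) else NA_real_,
       precision = if (length(called))
         mean(overlapsAny(called, truth, ignore.strand = TRUE)) else NA_real_,
       n_called = length(called), n_truth = length(truth))
}

#' Fraction of transcribed bases covered by clusters
#'
#' @param called cluster `GRanges`.
#' @param ann `GenomeAnnotation`; transcribed bases are the union of gene
#'   spans.
#' @return Fraction in [0, 1].
#' @export
transcribed_cluster_coverage <- function(called, ann) {
  genes <- reduce(granges(ann$genes), ignore.strand = TRUE)
  if (length(called) == 0L) return(0)
  hit <- GenomicRanges::intersect(reduce(granges(called),
                                         ignore.strand = TRUE),
                                  genes, ignore.strand = TRUE)
  sum(width(hit)) / sum(width(genes))
}
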