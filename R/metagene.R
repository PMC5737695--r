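# Strand-oriented metagene profiles around anchor sets, region RPKM
# comparisons around focus exons, coverage-ratio profiles, and the
# Mann-Whitney U wrapper shared by the statistics.

# Base-level coverage from aligned blocks (N gaps excluded), optionally
# scaled to counts-per-million.
scaled_coverage <- function(aln, cpm = TRUE) {
  aln <- read_alignments(aln)
  cov <- coverage(aligned_blocks(aln))
  if (cpm && length(aln) > 0L) cov <- cov * (1e6 / length(aln))
  list(cov = cov, lib = length(aln))
}

# Matrix of per-anchor coverage windows, oriented in transcription
# direction; offsets outside the chromosome are NA.
anchor_matrix <- function(cov, anchors, half_window) {
  W <- half_window
  n <- length(anchors)
  mat <- matrix(NA_real_, nrow = n, ncol = 2L * W + 1L)
  chr_all <- as.character(seqnames(anchors))
  lens <- stats::setNames(
    vapply(cov, length, integer(1)), names(cov))
  for (chr in unique(chr_all)) {
    v <- as.numeric(cov[[chr]])
    L <- lens[[chr]]
    for (i in which(chr_all == chr)) {
      p <- start(anchors)[i]
      lo <- max(1L, p - W); hi <- min(L, p + W)
      mat[i, (lo - (p - W) + 1L):(hi - (p - W) + 1L)] <- v[lo:hi]
    }
  }
  minus <- as.character(strand(anchors)) == "-"
  if (any(minus)) mat[minus, ] <- mat[minus, ncol(mat):1L, drop = FALSE]
  mat
}

#' Metagene coverage profile around anchors
#'
#' Per anchor, base-level coverage over `[pos - W, pos + W]` oriented so
#' positive offsets point downstream in transcription direction
#' (minus-strand windows are reversed); per-library scaling then averaging
#' across anchors. Anchors truncated by chromosome edges contribute only
#' their defined offsets. With several libraries the per-library profiles
#' are averaged.
#'
#' @param alns BAM path / `GAlignments`, or a list of them.
#' @param anchors width-1 `GRanges` with strand, or a BED6 path.
#' @param half_window window half-width W in bases.
#' @param normalize `"cpm"` (per million mapped reads), `"per_anchor_sum"`
#'   (each anchor window scaled to unit sum before averaging) or `"none"`.
#' @return A `metagene_profile`: `offsets` (-W..W), `values`, `n_anchors`,
#'   `n_defined` per offset.
#' @export
anchor_profile <- function(alns, anchors, half_window = 500L,
                           normalize = c("cpm", "per_anchor_sum", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(half_window >= 1L)
  if (is.character(anchors)) anchors <- rtracklayer::import(anchors, "BED")
  if (length(anchors) == 0L) stop("empty anchor set")
  if (!is.list(alns)) alns <- list(alns)
  mats <- lapply(alns, function(a) {
    sc <- scaled_coverage(a, cpm = (normalize == "cpm"))
    m <- anchor_matrix(sc$cov, anchors, half_window)
    if (normalize == "per_anchor_sum") {
      rs <- rowSums(m, na.rm = TRUE)
      m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
    }
    m
  })
  prof <- Reduce(`+`, lapply(mats, function(m) {
    v <- colMeans(m, na.rm = TRUE); v[is.nan(v)] <- NA_real_; v
  })) / length(mats)
  structure(list(offsets = seq(-half_window, half_window),
                 values = unname(prof),
                 n_anchors = length(anchors),
                 n_defined = colSums(!is.na(mats[[1]])),
                 normalize = normalize),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile over", x$n_anchors, "anchors, offsets",
      min(x$offsets), "..", max(x$offsets),
      sprintf("(normalize = %s)\n", x$normalize))
  peak <- x$offsets[which.max(x$values)]
  cat("  peak value", signif(max(x$values, na.rm = TRUE), 4),
      "at offset", peak, "\n")
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$offsets, x$values, type = "l",
                 xlab = "offset from anchor (nt, transcription direction)",
                 ylab = "mean coverage", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' RPKM of arbitrary regions
#'
#' Overlapping-read count (any aligned block, strand-agnostic by default)
#' scaled by region length and library size.
#'
#' @param aln BAM path or `GAlignments`.
#' @param regions `GRanges`.
#' @param ignore_strand count reads regardless of strand (default TRUE).
#' @return Numeric RPKM per region.
#' @export
region_rpkm <- function(aln, regions, ignore_strand = TRUE) {
  if (any(width(regions) == 0L)) stop("validation error: zero-length region")
  aln <- read_alignments(aln)
  counts <- countOverlaps(regions, aligned_blocks(aln),
                          ignore.strand = ignore_strand)
  rpkm(counts, width(regions), length(aln))
}

# RPKM over a *set* of regions per unit (e.g. both flanking exons of one
# focus exon): reads deduplicated across the set, length summed.
grouped_rpkm <- function(aln, region_list, lib) {
  blocks <- aligned_blocks(aln)
  vapply(region_list, function(gr) {
    if (length(gr) == 0L) return(NA_real_)
    hits <- findOverlaps(gr, blocks, ignore.strand = TRUE)
    rpkm(length(unique(subjectHits(hits))), sum(width(gr)), lib)
  }, numeric(1))
}

# Flanking exonic parts / introns / gene span for each query exon.
context_regions <- function(ann, exons) {
  if (is.character(exons)) exons <- rtracklayer::import(exons, "BED")
  genes <- ann$genes
  part_cache <- new.env(parent = emptyenv())
  fl_ex <- fl_in <- body <- vector("list", length(exons))
  skipped <- 0L
  for (i in seq_along(exons)) {
    gi <- which(overlapsAny(genes, exons[i], ignore.strand = TRUE))
    if (length(gi) == 0L) { skipped <- skipped + 1L; next }
    gid <- genes$gene_id[gi[1]]
    parts <- if (!is.null(part_cache[[gid]])) part_cache[[gid]]
             else (part_cache[[gid]] <- flatten_exonic_parts(ann, gid))
    hit <- which(overlapsAny(parts, exons[i], ignore.strand = TRUE))
    if (length(hit) == 0L) { skipped <- skipped + 1L; next }
    lo <- min(hit); hi <- max(hit)
    neigh <- parts[c(if (lo > 1L) lo - 1L, if (hi < length(parts)) hi + 1L)]
    fl_ex[[i]] <- granges(neigh)
    span <- granges(genes[gi[1]])
    gaps <- GenomicRanges::setdiff(span, granges(parts), ignore.strand = TRUE)
    ex_rng <- range(granges(parts)[hit])
    left_gap <- gaps[end(gaps) == start(ex_rng) - 1L]
    right_gap <- gaps[start(gaps) == end(ex_rng) + 1L]
    fl_in[[i]] <- c(left_gap, right_gap)
    body[[i]] <- span
  }
  if (skipped > 0L)
    warning(skipped, " exon(s) not resolvable in the annotation; skipped")
  keep <- !vapply(body, is.null, logical(1))
  list(flanking_exons = fl_ex[keep], flanking_introns = fl_in[keep],
       gene_body = body[keep], n_skipped = skipped)
}

#' Compare CLIP binding around focus vs background exons
#'
#' For each exon, binding (RPKM) is measured in its two adjacent exonic
#' parts, its two adjacent introns, and the whole gene body; focus and
#' background distributions are compared per region kind by a two-sided
#' Mann-Whitney U test. Exons missing a neighbor use the available one;
#' exons not resolvable in the annotation are skipped with a warning.
#'
#' @param aln BAM path or `GAlignments` (the CLIP signal).
#' @param focus_exons,background_exons `GRanges` or BED paths.
#' @param ann `GenomeAnnotation`.
#' @return Named list of three `region_comparison` objects
#'   (`flanking_exons`, `flanking_introns`, `gene_body`), each with
#'   `rpkm_focus`, `rpkm_background`, `u_stat`, `p`.
#' @export
compare_exon_context <- function(aln, focus_exons, background_exons, ann) {
  aln <- read_alignments(aln)
  lib <- length(aln)
  cf <- context_regions(ann, focus_exons)
  cb <- context_regions(ann, background_exons)
  out <- lapply(c("flanking_exons", "flanking_introns", "gene_body"),
                function(kind) {
    rf <- grouped_rpkm(aln, cf[[kind]], lib)
    rb <- grouped_rpkm(aln, cb[[kind]], lib)
    rf <- rf[!is.na(rf)]; rb <- rb[!is.na(rb)]
    mw <- mannwhitney_u(rf, rb)
    structure(list(region_kind = kind, rpkm_focus = rf,
                   rpkm_background = rb, u_stat = mw$U, p = mw$p),
              class = "region_comparison")
  })
  stats::setNames(out, c("flanking_exons", "flanking_introns", "gene_body"))
}

#' Coverage-ratio profile between two libraries
#'
#' Per-offset ratio of CPM-scaled mean coverage around anchors
#' (`a / b`, pseudocount = CPM of one read in the smaller library), plus the
#' log2 ratio; used e.g. to contrast knockout vs wild-type RNA-seq coverage
#' around proximal poly(A) sites.
#'
#' @param aln_a,aln_b BAM paths or `GAlignments`.
#' @param anchors width-1 `GRanges` with strand, or BED path.
#' @param half_window window half-width in bases.
#' @return A `metagene_profile` whose `values` are ratios, with an extra
#'   `log2_ratio` element.
#' @export
coverage_ratio_profile <- function(aln_a, aln_b, anchors,
                                   half_window = 500L) {
  aln_a <- read_alignments(aln_a); aln_b <- read_alignments(aln_b)
  if (length(aln_a) == 0L || length(aln_b) == 0L)
    stop("both libraries must be non-empty")
  if (is.character(anchors)) anchors <- rtracklayer::import(anchors, "BED")
  ca <- scaled_coverage(aln_a); cb <- scaled_coverage(aln_b)
  ma <- colMeans(anchor_matrix(ca$cov, anchors, half_window), na.rm = TRUE)
  mb <- colMeans(anchor_matrix(cb$cov, anchors, half_window), na.rm = TRUE)
  eps <- 1e6 / min(ca$lib, cb$lib)
  ratio <- (ma + eps) / (mb + eps)
  structure(list(offsets = seq(-half_window, half_window),
                 values = unname(ratio),
                 log2_ratio = unname(log2(ratio)),
                 n_anchors = length(anchors),
                 normalize = "cpm"),
            class = "metagene_profile")
}

#' Mann-Whitney U test
#'
#' Exact p by enumeration when the pooled sample size is at most 12 and no
#' ties are present; normal approximation with tie correction (and
#' continuity correction) otherwise. If every value is identical across
#' both samples the comparison is degenerate and p = 1 is returned.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return List `U`, `p`, `method`.
#' @export
mannwhitney_u <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1,
                method = "degenerate"))
  exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}
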