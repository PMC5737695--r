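# Crosslink-site calling from deletion pileups and ZOOPS k-mer motif
# enrichment with per-replicate Fisher exact tests combined by Fisher's
# method.

# Reference-space ranges per read: aligned span (M/=/X/D merged, N gaps
# excluded) and the deleted positions.
.cigar_ranges <- function(aln, ops, reduce = TRUE) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar(aln), pos = start(aln), ops = ops, reduce.ranges = reduce)
}

#' Call crosslink sites from deletion pileups
#'
#' Reverse transcription introduces deletion errors at the protein-RNA
#' crosslink; a position is called when more than 5 reads cover it
#' (`coverage >= min_cov`, default 6) and at least `min_freq` of them carry
#' a deletion there (inclusive, default 5%). Coverage counts reads whose
#' aligned span (M/=/X with deletions included, splice gaps excluded) covers
#' the position; deletions come from CIGAR D operations, with multi-base
#' deletions contributing every deleted position. Pileups are per strand.
#'
#' @param aln BAM path or `GAlignments`.
#' @param min_cov minimum coverage (inclusive; the default encodes the
#'   strict ">5 reads" rule).
#' @param min_freq minimum deletion frequency (inclusive).
#' @return `GRanges` of width-1 sites with `coverage`, `deletions`,
#'   `del_freq`, sorted.
#' @export
call_crosslink_sites <- function(aln, min_cov = 6L, min_freq = 0.05) {
  aln <- read_alignments(aln)
  out <- GRanges(seqlengths = seqlengths(aln))
  mcols(out) <- DataFrame(coverage = integer(0), deletions = integer(0),
                          del_freq = numeric(0))
  if (length(aln) == 0L) return(out)
  span_ir <- .cigar_ranges(aln, ops = c("M", "=", "X", "D"))
  del_ir <- .cigar_ranges(aln, ops = "D", reduce = FALSE)
  chrom <- as.character(seqnames(aln))
  str <- as.character(strand(aln))
  res <- list()
  for (s in intersect(c("+", "-"), unique(str))) {
    sel <- which(str == s)
    span_gr <- GRanges(rep(chrom[sel], lengths(span_ir[sel])),
                       unlist(span_ir[sel], use.names = FALSE),
                       seqlengths = seqlengths(aln))
    del_gr <- GRanges(rep(chrom[sel], lengths(del_ir[sel])),
                      unlist(del_ir[sel], use.names = FALSE),
                      seqlengths = seqlengths(aln))
    if (length(del_gr) == 0L) next
    cov <- coverage(span_gr)
    del <- coverage(del_gr)
    for (chr in names(del)) {
      d <- del[[chr]]
      if (sum(S4Vectors::runValue(d)) == 0) next
      cv <- cov[[chr]]
      called <- (d >= min_freq * cv) & (cv >= min_cov) & (d > 0L)
      pos <- which(as.logical(called))
      if (!length(pos)) next
      res[[paste(chr, s)]] <- GRanges(
        chr, IRanges(pos, width = 1L), strand = s,
        coverage = as.integer(cv[pos]),
        deletions = as.integer(d[pos]),
        del_freq = as.numeric(d[pos]) / as.numeric(cv[pos]),
        seqlengths = seqlengths(aln))
    }
  }
  if (length(res)) sort(do.call(c, unname(res))) else out
}

#' Extract flanking sequences around crosslink sites
#'
#' Returns the `[pos - flank, pos + flank]` sequence on the site strand
#' (reverse-complemented for minus-strand sites), truncated at chromosome
#' edges.
#'
#' @param sites width-1 `GRanges`.
#' @param genome FASTA path or `DNAStringSet`.
#' @param flank bases on each side (default 10).
#' @return `DNAStringSet`, one sequence per site.
#' @export
extract_site_sequences <- function(sites, genome, flank = 10L) {
  genome <- load_genome(genome)
  if (length(sites) == 0L) return(Biostrings::DNAStringSet())
  chr <- as.character(seqnames(sites))
  lens <- stats::setNames(width(genome), names(genome))
  lo <- pmax(1L, start(sites) - flank)
  hi <- pmin(lens[chr], start(sites) + flank)
  seqs <- vector("list", length(sites))
  for (c in unique(chr)) {
    sel <- which(chr == c)
    at <- IRanges(lo[sel], hi[sel])
    seqs[sel] <- as.list(Biostrings::extractAt(genome[[c]], at))
  }
  out <- Biostrings::DNAStringSet(seqs)
  minus <- as.character(strand(sites)) == "-"
  if (any(minus)) out[minus] <- Biostrings::reverseComplement(out[minus])
  names(out) <- sprintf("%s_%d_%s", chr, start(sites),
                        as.character(strand(sites)))
  out
}

#' Build a background sequence set for motif enrichment
#'
#' `"sampled_positions"` draws covered positions (coverage >= 1 in the same
#' library) that are not called sites and extracts matched flanks, so the
#' background controls transcript composition; `"shuffle"` mononucleotide-
#' shuffles each foreground sequence `n_ratio` times, preserving length and
#' base composition.
#'
#' @param sites called site `GRanges` (foreground positions to exclude).
#' @param genome FASTA path or `DNAStringSet`.
#' @param aln the library the sites were called from (required for
#'   `"sampled_positions"`).
#' @param mode background model.
#' @param n_ratio background-to-foreground size ratio.
#' @param flank flank bases (as in [extract_site_sequences()]).
#' @param seed RNG seed (background sampling is deterministic given it).
#' @return `DNAStringSet` of background sequences.
#' @export
make_background <- function(sites, genome,
                            mode = c("sampled_positions", "shuffle"),
                            aln = NULL, n_ratio = 5L, flank = 10L,
                            seed = 1L) {
  mode <- match.arg(mode)
  genome <- load_genome(genome)
  n_bg <- max(1L, n_ratio * length(sites))
  if (mode == "shuffle") {
    fg <- extract_site_sequences(sites, genome, flank)
    return(with_stream(seed, "bg_shuffle", {
      reps <- rep(seq_along(fg), length.out = n_bg)
      Biostrings::DNAStringSet(vapply(reps, function(i) {
        paste(sample(strsplit(as.character(fg[[i]]), "")[[1]]),
              collapse = "")
      }, character(1)))
    }))
  }
  if (is.null(aln))
    stop("sampled_positions background needs the alignment set")
  aln <- read_alignments(aln)
  span_ir <- .cigar_ranges(aln, ops = c("M", "=", "X", "D"))
  chrom <- as.character(seqnames(aln))
  str <- as.character(strand(aln))
  cand <- list()
  for (s in c("+", "-")) {
    sel <- which(str == s)
    if (!length(sel)) next
    cov <- coverage(GRanges(rep(chrom[sel], lengths(span_ir[sel])),
                            unlist(span_ir[sel], use.names = FALSE),
                            seqlengths = seqlengths(aln)))
    covered <- as(cov > 0L, "GRanges")
    covered <- covered[covered$score]
    mcols(covered) <- NULL
    strand(covered) <- s
    cand[[s]] <- covered
  }
  cand <- do.call(c, unname(cand))
  cand <- GenomicRanges::setdiff(cand, sites)   # strand-aware exclusion
  total <- sum(width(cand))
  if (total < n_bg)
    stop("insufficient eligible covered positions for the background")
  with_stream(seed, "bg_sample", {
    picks <- sort(sample(total, n_bg))
    cw <- cumsum(width(cand))
    idx <- findInterval(picks - 1L, c(0L, cw), rightmost.closed = FALSE)
    pos <- start(cand)[idx] + (picks - c(0L, cw)[idx]) - 1L
    bg_sites <- GRanges(seqnames(cand)[idx], IRanges(pos, width = 1L),
                        strand = strand(cand)[idx],
                        seqlengths = seqlengths(cand))
    extract_site_sequences(bg_sites, genome, flank)
  })
}

#' ZOOPS k-mer counting
#'
#' Zero-or-once-per-sequence: each sequence contributes at most 1 to every
#' k-mer it contains; k-mers containing N are skipped.
#'
#' @param seqs `DNAStringSet` or character vector.
#' @param k k-mer length (>= 1).
#' @return Named integer vector of counts.
#' @export
kmer_zoops <- function(seqs, k) {
  stopifnot(k >= 1L)
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) return(stats::setNames(integer(0), character(0)))
  if (all(nchar(seqs) < k)) {
    warning("k exceeds every sequence length; empty ZOOPS counts")
    return(stats::setNames(integer(0), character(0)))
  }
  per_seq <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- unique(substring(s, 1:(n - k + 1L), k:n))
    km[!grepl("N", km, fixed = TRUE)]
  })
  tab <- table(unlist(per_seq, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' One-sided Fisher exact enrichment p-values for k-mers
#'
#' For each k-mer, the 2x2 ZOOPS table `[[fg_with, fg_without], [bg_with,
#' bg_without]]` is tested for enrichment in the foreground by the
#' hypergeometric upper tail (one-sided Fisher exact test).
#'
#' @param fg_counts,bg_counts named ZOOPS counts.
#' @param n_fg,n_bg foreground / background set sizes.
#' @param kmers k-mers to test (default: those observed in the foreground).
#' @return `data.frame(kmer, fg_with, bg_with, p)`.
#' @export
kmer_enrichment <- function(fg_counts, bg_counts, n_fg, n_bg,
                            kmers = names(fg_counts)) {
  fg <- ifelse(is.na(fg_counts[kmers]), 0L, fg_counts[kmers])
  bg <- ifelse(is.na(bg_counts[kmers]), 0L, bg_counts[kmers])
  stopifnot(all(fg <= n_fg), all(bg <= n_bg))
  # P(X >= fg) with X ~ Hypergeom(white = fg+bg, black = rest, drawn = n_fg)
  p <- stats::phyper(fg - 1, fg + bg, n_fg + n_bg - fg - bg, n_fg,
                     lower.tail = FALSE)
  data.frame(kmer = kmers, fg_with = as.integer(fg), bg_with = as.integer(bg),
             p = as.numeric(p), row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine p-values by Fisher's method
#'
#' `chi2 = -2 * sum(log(p_i))` with `2 m` degrees of freedom; the combined
#' p-value is the upper chi-square tail. For a single p-value the method is
#' the identity. Zero p-values are clamped to the smallest positive double
#' with a warning.
#'
#' @param p_list numeric p-values in (0, 1].
#' @return List `chi2`, `df`, `p`.
#' @export
combine_fisher <- function(p_list) {
  p <- as.numeric(p_list)
  stopifnot(length(p) >= 1L, all(p <= 1))
  if (any(p <= 0)) {
    warning("p-value(s) of 0 clamped to smallest representable double")
    p[p <= 0] <- .Machine$double.xmin
  }
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Rank k-mers by combined motif enrichment across replicates
#'
#' The full per-replicate pipeline (called sites -> flanking sequences ->
#' ZOOPS counts -> one-sided Fisher exact test against the background) with
#' per-k-mer p-values combined across replicates by Fisher's method. Rows
#' are sorted by combined p ascending, ties broken by total foreground count
#' (descending) then k-mer; a Bonferroni column over the 4^k k-mers of each
#' k accompanies the raw combined p, and `fg_fraction` reports the fraction
#' of foreground sequences containing the k-mer.
#'
#' @param site_sets list of per-replicate site `GRanges`.
#' @param genome FASTA path or `DNAStringSet`.
#' @param k_range k-mer lengths to scan (default 4:6, DRACH-length motifs).
#' @param aln_sets per-replicate alignments for the sampled-positions
#'   background; `NULL` falls back to shuffle.
#' @param background background mode, see [make_background()].
#' @param n_ratio background size ratio.
#' @param flank flank bases.
#' @param seed RNG seed for background sampling.
#' @return `data.frame` with per-replicate p-values, `chi2`, `df`,
#'   `p_combined`, `p_bonferroni`, `fg_fraction`.
#' @export
rank_motifs <- function(site_sets, genome, k_range = 4:6,
                        aln_sets = NULL,
                        background = c("sampled_positions", "shuffle"),
                        n_ratio = 5L, flank = 10L, seed = 1L) {
  background <- match.arg(background)
  stopifnot(length(site_sets) >= 1L)
  genome <- load_genome(genome)
  m <- length(site_sets)
  fg_seqs <- lapply(site_sets, extract_site_sequences, genome = genome,
                    flank = flank)
  # background seed derives from the replicate's site content, so the table
  # is invariant under replicate order permutation
  site_hash <- function(gr) {
    if (length(gr) == 0L) return(0L)
    as.integer((sum(as.numeric(start(gr)) %% 99991 * seq_along(gr)) +
                  7 * length(gr)) %% 2147480009)
  }
  bg_seqs <- lapply(seq_len(m), function(r) {
    if (length(site_sets[[r]]) == 0L) return(Biostrings::DNAStringSet())
    make_background(site_sets[[r]], genome, mode = background,
                    aln = if (!is.null(aln_sets)) aln_sets[[r]] else NULL,
                    n_ratio = n_ratio, flank = flank,
                    seed = stream_seed(seed,
                      paste0("bg_sites_", site_hash(site_sets[[r]]))))
  })
  out <- list()
  for (k in k_range) {
    fg_tab <- lapply(fg_seqs, kmer_zoops, k = k)
    bg_tab <- lapply(bg_seqs, kmer_zoops, k = k)
    kmers <- sort(unique(unlist(lapply(fg_tab, names), use.names = FALSE)))
    if (length(kmers) == 0L) next
    pmat <- matrix(1, nrow = length(kmers), ncol = m,
                   dimnames = list(kmers, paste0("p_rep", seq_len(m))))
    fgw <- bgw <- matrix(0L, nrow = length(kmers), ncol = m)
    for (r in seq_len(m)) {
      n_fg <- length(fg_seqs[[r]]); n_bg <- length(bg_seqs[[r]])
      if (n_fg == 0L || n_bg == 0L) next
      enr <- kmer_enrichment(fg_tab[[r]], bg_tab[[r]], n_fg, n_bg,
                             kmers = kmers)
      pmat[, r] <- enr$p
      fgw[, r] <- enr$fg_with; bgw[, r] <- enr$bg_with
    }
    comb <- t(apply(pmat, 1, function(p) {
      cf <- combine_fisher(p)
      c(chi2 = cf$chi2, df = cf$df, p_combined = cf$p)
    }))
    n_fg_tot <- sum(lengths(fg_seqs))
    df_k <- data.frame(kmer = kmers, k = k,
                       fg_with = rowSums(fgw), bg_with = rowSums(bgw),
                       n_fg = n_fg_tot, n_bg = sum(lengths(bg_seqs)),
                       pmat, comb,
                       p_bonferroni = pmin(1, comb[, "p_combined"] * 4^k),
                       fg_fraction = if (n_fg_tot > 0)
                         rowSums(fgw) / n_fg_tot else NA_real_,
                       row.names = NULL, stringsAsFactors = FALSE)
    out[[as.character(k)]] <- df_k
  }
  if (length(out) == 0L) {
    warning("no foreground k-mers; empty motif table")
    return(data.frame())
  }
  tab <- do.call(rbind, out)
  ord <- order(tab$p_combined, -tab$fg_with, tab$kmer)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  class(tab) <- c("motif_table", "data.frame")
  tab
}

#' @export
print.motif_table <- function(x, n = 10L, ...) {
  cat("Motif enrichment table:", nrow(x), "k-mers; top", min(n, nrow(x)),
      "by combined p:\n")
  print.data.frame(utils::head(as.data.frame(x)[, c("kmer", "k", "fg_with",
    "bg_with", "p_combined", "p_bonferroni", "fg_fraction")], n),
    digits = 4)
  invisible(x)
}
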