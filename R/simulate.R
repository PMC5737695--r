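# Deterministic synthetic CLIP study: genome + annotation, aligned CLIP/input
# reads with planted binding clusters and crosslink-induced deletions carrying
# a planted motif, and exon-level DE tables with a last-exon directional bias.
# One global seed drives independent substreams (genome, structures, planting,
# each replicate, DE table) so adding a replicate never perturbs the genome.

#' Configuration for the synthetic CLIP study
#'
#' Defaults define the package's standard study conditions: a ~100 kb
#' two-chromosome genome carrying 12 non-overlapping genes (1 rRNA, 1 snRNA,
#' 1 snoRNA, 1 lincRNA, 8 multi-exon mRNAs, one of them with a second,
#' exon-skipping isoform), 3 CLIP replicates totalling 150,000 reads plus a
#' 50,000-read RNA-seq input, 6 planted binding clusters at 10-fold
#' enrichment, 3 crosslink sites per cluster with deletion probability 0.3
#' against a 2e-4 background deletion rate, a planted pyrimidine-rich 5-mer
#' at 60% of crosslink sites, and an exon-level DE table in which 80% of
#' last exonic parts are shifted up.
#'
#' @param seed global integer seed.
#' @param n_genes number of genes (>= 6).
#' @param genome_len total genome length in bases.
#' @param exon_len,intron_len,n_exons sampling ranges (min, max) for mRNA
#'   structure.
#' @param read_len read length in bases.
#' @param n_clip_replicates number of CLIP replicates.
#' @param library_size_clip total primary alignments summed over all CLIP
#'   replicates (split evenly across replicates).
#' @param library_size_input primary alignments in the input library.
#' @param precursor_frac_clip,precursor_frac_input fraction of reads drawn
#'   from unspliced precursor coordinates rather than the mature transcript.
#' @param planted_clusters optional `data.frame(gene, region, fold)` with
#'   `region` in `{"intron","exon","polya_upstream"}`; `NULL` plants
#'   `n_planted_clusters` default clusters in the first mRNA genes.
#' @param n_planted_clusters,fold_enrichment,cluster_len defaults used when
#'   `planted_clusters` is `NULL`.
#' @param n_xlinks_per_cluster crosslink sites planted per cluster.
#' @param deletion_prob per-read probability of a 1-nt deletion at a covered
#'   crosslink site.
#' @param background_del_prob per-read probability of a random background
#'   deletion (typical sequencing indel error scale).
#' @param motif sequence planted at crosslink sites (centered).
#' @param motif_fraction fraction of crosslink sites carrying the motif.
#' @param de_sigma null log2FC standard deviation in the DE table.
#' @param de_shift mean log2FC of upshifted last exons.
#' @param de_last_exon_bias fraction of last exonic parts set DE-up.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 12L,
                       genome_len = 100000L,
                       exon_len = c(80L, 250L),
                       intron_len = c(150L, 600L),
                       n_exons = c(3L, 6L),
                       read_len = 50L,
                       n_clip_replicates = 3L,
                       library_size_clip = 150000L,
                       library_size_input = 50000L,
                       precursor_frac_clip = 0.5,
                       precursor_frac_input = 0.15,
                       planted_clusters = NULL,
                       n_planted_clusters = 6L,
                       fold_enrichment = 10,
                       cluster_len = 150L,
                       n_xlinks_per_cluster = 3L,
                       deletion_prob = 0.3,
                       background_del_prob = 2e-4,
                       motif = "TCTCC",
                       motif_fraction = 0.6,
                       de_sigma = 0.3,
                       de_shift = 2,
                       de_last_exon_bias = 0.8) {
  cfg <- as.list(environment())
  probs <- c(cfg$precursor_frac_clip, cfg$precursor_frac_input,
             cfg$deletion_prob, cfg$background_del_prob,
             cfg$motif_fraction, cfg$de_last_exon_bias)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0, 1]")
  if (cfg$n_genes < 6L) stop("config error: n_genes must be >= 6")
  if (cfg$fold_enrichment <= 0)
    stop("config error: fold_enrichment must be > 0")
  if (!is.null(planted_clusters) && any(planted_clusters$fold <= 0))
    stop("config error: fold_enrichment must be > 0")
  if (cfg$read_len < 20L) stop("config error: read_len too short")
  structure(cfg, class = "sim_config")
}

# ---- reference ------------------------------------------------------------

runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

# Draw gene structures (exon/intron widths per transcript) for the biotype
# plan; pure function of the "structure" stream.
plan_genes <- function(cfg) {
  n <- cfg$n_genes
  biotypes <- c("rRNA", "snRNA", "snoRNA", "lincRNA",
                rep("mRNA", n - 4L))
  strands <- rep(c("+", "-"), length.out = n)
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    b <- biotypes[i]
    ex <- switch(b,
      rRNA = 800L, snRNA = 150L, snoRNA = 120L,
      lincRNA = runif_int(2L, cfg$exon_len[1], cfg$exon_len[2]),
      mRNA = {
        k <- runif_int(1L, cfg$n_exons[1], cfg$n_exons[2])
        w <- runif_int(k, cfg$exon_len[1], cfg$exon_len[2])
        w[k] <- max(w[k], 170L)   # room for a poly(A)-proximal planting
        w
      })
    ir <- if (length(ex) > 1L)
      runif_int(length(ex) - 1L, cfg$intron_len[1], cfg$intron_len[2])
    else integer(0)
    genes[[i]] <- list(gene_id = sprintf("G%02d", i), biotype = b,
                       strand = strands[i], exon_w = ex, intron_w = ir,
                       span = sum(ex) + sum(ir))
  }
  genes
}

# Lay genes onto chromosomes with random gaps; error if they do not fit.
place_genes <- function(cfg, genes) {
  chrom_len <- c(simchr1 = round(0.6 * cfg$genome_len),
                 simchr2 = cfg$genome_len - round(0.6 * cfg$genome_len))
  cur_chrom <- 1L; cursor <- 1L
  placed <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    gap <- runif_int(1L, 200L, 500L)
    start <- cursor + gap
    while (start + g$span - 1L > chrom_len[cur_chrom]) {
      cur_chrom <- cur_chrom + 1L
      if (cur_chrom > length(chrom_len))
        stop("config error: genes do not fit in genome_len")
      cursor <- 1L
      start <- cursor + runif_int(1L, 200L, 500L)
    }
    g$chrom <- names(chrom_len)[cur_chrom]
    g$start <- start
    cursor <- start + g$span - 1L
    placed[[i]] <- g
  }
  list(genes = placed, chrom_len = chrom_len)
}

# Exons of one gene in genomic order given its structure and placement.
gene_exons <- function(g) {
  widths <- g$exon_w
  starts <- g$start + cumsum(c(0L, utils::head(widths, -1L) + g$intron_w))
  GRanges(g$chrom, IRanges(starts, width = widths), strand = g$strand)
}

#' Simulate the reference genome, annotation and planted ground truth
#'
#' Generates an i.i.d.-uniform nucleotide genome, tiles non-overlapping genes
#' of mixed biotypes onto it, resolves planted binding clusters and crosslink
#' sites inside mRNA genes, plants the configured motif (centered) at a
#' fraction of crosslink sites, and writes FASTA (+ .fai), GTF and
#' ground-truth BED/JSON files. Deterministic: the same config yields
#' byte-identical outputs.
#'
#' @param cfg `sim_config`.
#' @param outdir output directory (created if needed).
#' @return List with `fasta`, `gtf`, `ann` (`GenomeAnnotation` re-loaded from
#'   the emitted files), `genome` (`DNAStringSet`) and `truth` (planted
#'   clusters/xlinks/motif and the manifest counts).
#' @export
simulate_reference <- function(cfg, outdir = tempfile("simref")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genes <- with_stream(cfg$seed, "structure", {
    placed <- place_genes(cfg, plan_genes(cfg))
    placed
  })
  chrom_len <- genes$chrom_len
  genes <- genes$genes

  genome <- with_stream(cfg$seed, "genome", {
    Biostrings::DNAStringSet(vapply(chrom_len, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)))
  })
  names(genome) <- names(chrom_len)

  # transcript models; one mRNA gene receives an exon-skipping isoform
  tx_rows <- list(); exon_feats <- list(); cds_feats <- list()
  skip_gene <- NULL
  for (g in genes) {
    ex <- gene_exons(g)
    tid <- paste0(g$gene_id, ".T1")
    exon_feats[[tid]] <- ex
    tx_rows[[tid]] <- c(g$gene_id, g$biotype, g$strand)
    if (g$biotype == "mRNA") {
      cds_feats[[tid]] <- mature_to_genomic_cds(ex, g$strand)
      if (is.null(skip_gene) && length(g$exon_w) >= 4L) {
        skip_gene <- g$gene_id
        tid2 <- paste0(g$gene_id, ".T2")
        ex2 <- ex[-2L]
        exon_feats[[tid2]] <- ex2
        tx_rows[[tid2]] <- c(g$gene_id, g$biotype, g$strand)
        cds_feats[[tid2]] <- mature_to_genomic_cds(ex2, g$strand)
      }
    }
  }

  truth_plant <- with_stream(cfg$seed, "plant",
    plant_clusters(cfg, genes, exon_feats))

  # overwrite genome with motif copies centered on flagged crosslink sites
  if (length(truth_plant$xlinks) && nzchar(cfg$motif)) {
    k <- nchar(cfg$motif)
    xl <- truth_plant$xlinks[truth_plant$xlinks$has_motif]
    motif_fwd <- Biostrings::DNAString(cfg$motif)
    motif_rev <- Biostrings::reverseComplement(motif_fwd)
    for (i in seq_along(xl)) {
      pos <- start(xl)[i]
      chr <- as.character(seqnames(xl)[i])
      s <- pos - (k %/% 2L)
      # minus-strand sites read the reverse complement as their sense
      # sequence, so plant accordingly
      Biostrings::subseq(genome[[chr]], s, s + k - 1L) <-
        if (as.character(strand(xl)[i]) == "-") motif_rev else motif_fwd
    }
  }

  fasta <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta, width = 70L)
  Rsamtools::indexFa(fasta)

  tx_df <- do.call(rbind, tx_rows)
  ann0 <- structure(list(
    exons_by_tx = GRangesList(exon_feats),
    cds_by_tx = GRangesList(cds_feats),
    tx = data.frame(transcript_id = names(exon_feats),
                    gene_id = tx_df[, 1], biotype = tx_df[, 2],
                    strand = tx_df[, 3], stringsAsFactors = FALSE)),
    class = "GenomeAnnotation")
  gtf <- file.path(outdir, "annotation.gtf")
  write_gtf(ann0, gtf)
  ann <- load_annotation(gtf, fasta)

  truth <- list(
    n_genes = length(genes),
    n_transcripts = length(exon_feats),
    n_exons = sum(lengths(exon_feats)),
    genes = data.frame(
      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
      biotype = vapply(genes, `[[`, character(1), "biotype"),
      stringsAsFactors = FALSE),
    skip_gene = skip_gene,
    clusters = truth_plant$clusters,
    xlinks = truth_plant$xlinks,
    motif = cfg$motif)

  if (length(truth$clusters))
    write_bed6(truth$clusters, file.path(outdir, "true_clusters.bed"),
               name = paste0("cluster_", seq_along(truth$clusters)),
               score = round(100 * truth$clusters$fold))
  if (length(truth$xlinks))
    write_bed6(truth$xlinks, file.path(outdir, "true_xlinks.bed"),
               name = paste0("xlink_", seq_along(truth$xlinks)),
               score = as.integer(truth$xlinks$has_motif))
  jsonlite::write_json(
    list(n_genes = truth$n_genes, n_transcripts = truth$n_transcripts,
         n_exons = truth$n_exons, motif = cfg$motif,
         n_clusters = length(truth$clusters),
         n_xlinks = length(truth$xlinks)),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE)

  list(fasta = fasta, gtf = gtf, outdir = outdir,
       ann = ann, genome = genome, truth = truth)
}

# CDS genomic projection: mature transcript partitioned 5'UTR / CDS / 3'UTR.
mature_to_genomic_cds <- function(ex, strand) {
  L <- sum(width(ex))
  u5 <- max(30L, round(0.10 * L)); u3 <- max(60L, round(0.25 * L))
  if (u5 + u3 + 30L > L) { u5 <- max(1L, L %/% 10L); u3 <- max(1L, L %/% 4L) }
  mature_slice_to_genomic(ex, strand, u5 + 1L, L - u3)
}

# Map a mature-coordinate interval [from, to] to genomic ranges over exons.
mature_slice_to_genomic <- function(ex, strand, from, to) {
  if (strand == "-") ex <- rev(ex)          # transcription order
  w <- width(ex); cum <- cumsum(w); prev <- c(0L, utils::head(cum, -1L))
  out <- GRanges()
  for (i in seq_along(ex)) {
    lo <- max(from, prev[i] + 1L); hi <- min(to, cum[i])
    if (lo > hi) next
    if (strand == "-") {
      gs <- end(ex)[i] - (hi - prev[i]) + 1L
      ge <- end(ex)[i] - (lo - prev[i]) + 1L
    } else {
      gs <- start(ex)[i] + (lo - prev[i]) - 1L
      ge <- start(ex)[i] + (hi - prev[i]) - 1L
    }
    out <- c(out, GRanges(seqnames(ex)[i], IRanges(gs, ge), strand = strand))
  }
  sort(out)
}

# Resolve planted cluster intervals and crosslink positions inside mRNA genes.
plant_clusters <- function(cfg, genes, exon_feats) {
  mrna <- Filter(function(g) g$biotype == "mRNA", genes)
  spec <- cfg$planted_clusters
  if (is.null(spec)) {
    nc <- cfg$n_planted_clusters
    if (nc == 0L)
      return(list(clusters = GRanges(), xlinks = GRanges()))
    regions <- rep(c("intron", "intron", "intron", "exon", "exon",
                     "polya_upstream"), length.out = nc)
    spec <- data.frame(gene = vapply(mrna, `[[`, character(1), "gene_id")[
                         rep_len(seq_along(mrna), nc)],
                       region = regions, fold = cfg$fold_enrichment,
                       stringsAsFactors = FALSE)
  }
  if (nrow(spec) == 0L)
    return(list(clusters = GRanges(), xlinks = GRanges()))
  if (any(spec$fold <= 0)) stop("config error: fold_enrichment must be > 0")
  cl <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    g <- genes[[which(vapply(genes, `[[`, character(1), "gene_id") ==
                        spec$gene[i])]]
    ex <- exon_feats[[paste0(g$gene_id, ".T1")]]
    itv <- switch(spec$region[i],
      intron = {
        gaps <- GenomicRanges::setdiff(range(ex), ex)
        if (length(gaps) == 0L) stop("no intron can host a planted cluster")
        wide <- gaps[width(gaps) >= cfg$cluster_len + 40L]
        pick <- if (length(wide)) wide[runif_int(1L, 1L, length(wide))]
                else gaps[which.max(width(gaps))]
        len <- min(cfg$cluster_len, width(pick) - 40L)
        mid <- start(pick) + (width(pick) - len) %/% 2L
        GRanges(seqnames(pick), IRanges(mid, width = len), strand = g$strand)
      },
      exon = {
        wide <- ex[width(ex) >= min(cfg$cluster_len, 100L) + 20L]
        pick <- if (length(wide)) wide[runif_int(1L, 1L, length(wide))]
                else ex[which.max(width(ex))]
        len <- min(cfg$cluster_len, width(pick) - 20L)
        GRanges(seqnames(pick),
                IRanges(start(pick) + 10L, width = len), strand = g$strand)
      },
      polya_upstream = {
        # 80 bp ending 60 nt upstream of the transcript 3' end, inside the
        # last exon: planted CLIP coverage then peaks ~60-110 nt upstream of
        # the poly(A) site.
        last <- if (g$strand == "-") ex[1L] else ex[length(ex)]
        if (g$strand == "-")
          GRanges(seqnames(last),
                  IRanges(start(last) + 60L, width = 80L), strand = "-")
        else
          GRanges(seqnames(last),
                  IRanges(end(last) - 139L, width = 80L), strand = "+")
      },
      stop("unknown planted region kind: ", spec$region[i]))
    mcols(itv)$gene_id <- g$gene_id
    mcols(itv)$region <- spec$region[i]
    mcols(itv)$fold <- spec$fold[i]
    cl[[i]] <- itv
  }
  clusters <- do.call(c, cl)
  # crosslink sites: interior positions, pairwise spacing >= 8
  xl <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    lo <- start(clusters)[i] + 10L; hi <- end(clusters)[i] - 10L
    cand <- seq(lo, hi)
    pos <- integer(0)
    while (length(pos) < cfg$n_xlinks_per_cluster && length(cand)) {
      p <- cand[runif_int(1L, 1L, length(cand))]
      pos <- c(pos, p)
      cand <- cand[abs(cand - p) >= 8L]
    }
    xl[[i]] <- GRanges(seqnames(clusters)[i], IRanges(sort(pos), width = 1L),
                       strand = strand(clusters)[i],
                       cluster = i, gene_id = clusters$gene_id[i])
  }
  xlinks <- do.call(c, xl)
  n_motif <- round(cfg$motif_fraction * length(xlinks))
  has_motif <- logical(length(xlinks))
  if (n_motif > 0)
    has_motif[sample(length(xlinks), n_motif)] <- TRUE
  mcols(xlinks)$has_motif <- has_motif
  list(clusters = clusters, xlinks = xlinks)
}
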