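# Aligned-read simulation: CLIP replicates oversampled in planted clusters,
# input RNA-seq, spliced (N) and deletion-carrying (D) CIGARs, BAM output.

# Per-transcript structure cache used by the mature-read mapper.
tx_structures <- function(ann) {
  ids <- ann$tx$transcript_id
  lapply(stats::setNames(ids, ids), function(id) {
    ex <- ann$exons_by_tx[[id]]
    minus <- as.character(strand(ex)[1]) == "-"
    exo <- if (minus) rev(ex) else ex      # transcription order
    w <- width(exo)
    list(chrom = as.character(seqnames(ex))[1],
         strand = if (minus) "-" else "+",
         gstart = start(exo), gend = end(exo),
         w = w, cum = cumsum(w), prev = c(0L, utils::head(cumsum(w), -1L)),
         L = sum(w))
  })
}

# Map reads at transcript coordinates tstart (transcription order) on one
# transcript to genomic (pos, cigar). Exons are never shorter than the read,
# so a read spans at most one junction.
map_mature_reads <- function(st, tstart, read_len) {
  ei <- findInterval(tstart - 1L, c(0L, st$cum), rightmost.closed = FALSE)
  tend <- tstart + read_len - 1L
  within <- tend <= st$cum[ei]
  pos <- integer(length(tstart)); cig <- character(length(tstart))
  if (st$strand == "+") {
    pos[within] <- st$gstart[ei[within]] +
      (tstart[within] - st$prev[ei[within]]) - 1L
    cig[within] <- paste0(read_len, "M")
    cr <- which(!within)
    if (length(cr)) {
      i <- ei[cr]
      m1 <- st$cum[i] - tstart[cr] + 1L
      m2 <- read_len - m1
      gap <- st$gstart[i + 1L] - st$gend[i] - 1L
      pos[cr] <- st$gstart[i] + (tstart[cr] - st$prev[i]) - 1L
      cig[cr] <- paste0(m1, "M", gap, "N", m2, "M")
    }
  } else {
    # transcription runs right-to-left; leftmost aligned base differs by case
    p1 <- st$gend[ei] - (tstart - st$prev[ei]) + 1L   # 5' aligned base
    pos[within] <- p1[within] - read_len + 1L
    cig[within] <- paste0(read_len, "M")
    cr <- which(!within)
    if (length(cr)) {
      i <- ei[cr]
      m1 <- st$cum[i] - tstart[cr] + 1L               # bases in exon i
      m2 <- read_len - m1                             # bases in exon i+1
      gap <- st$gstart[i] - st$gend[i + 1L] - 1L
      pos[cr] <- st$gend[i + 1L] - m2 + 1L
      cig[cr] <- paste0(m2, "M", gap, "N", m1, "M")
    }
  }
  list(pos = pos, cigar = cig)
}

# Draw n reads from the transcriptome: genes by expression weight, precursor
# (contiguous, unspliced) vs mature (junction-aware) coordinates.
sample_background_reads <- function(n, ann, st_list, weights, prec_frac,
                                    read_len) {
  gene_ids <- names(weights)
  gidx <- sample(length(gene_ids), n, replace = TRUE, prob = weights)
  is_prec <- stats::runif(n) < prec_frac
  chrom <- character(n); pos <- integer(n)
  cig <- character(n); str <- character(n)

  genes <- ann$genes[match(gene_ids, ann$genes$gene_id)]
  gs <- start(genes); ge <- end(genes)
  gchr <- as.character(seqnames(genes)); gstr <- as.character(strand(genes))

  pr <- which(is_prec)
  if (length(pr)) {
    gi <- gidx[pr]
    span_lo <- gs[gi]; span_hi <- ge[gi] - read_len + 1L
    pos[pr] <- span_lo + floor(stats::runif(length(pr)) *
                                 (span_hi - span_lo + 1L))
    chrom[pr] <- gchr[gi]; str[pr] <- gstr[gi]
    cig[pr] <- paste0(read_len, "M")
  }
  mt <- which(!is_prec)
  if (length(mt)) {
    # choose an isoform uniformly within the gene, then map per transcript
    tx_by_gene <- split(ann$tx$transcript_id, ann$tx$gene_id)
    first_tx <- vapply(tx_by_gene, `[`, character(1), 1L)
    mt_genes <- gene_ids[gidx[mt]]
    txs <- unname(first_tx[mt_genes])
    multi <- names(tx_by_gene)[lengths(tx_by_gene) > 1L]
    for (gid in multi) {
      sel <- which(mt_genes == gid)
      if (!length(sel)) next
      cand <- tx_by_gene[[gid]]
      txs[sel] <- cand[1L + floor(stats::runif(length(sel)) * length(cand))]
    }
    for (id in unique(txs)) {
      sel <- mt[txs == id]
      st <- st_list[[id]]
      tstart <- 1L + floor(stats::runif(length(sel)) * (st$L - read_len + 1L))
      mp <- map_mature_reads(st, tstart, read_len)
      pos[sel] <- mp$pos; cig[sel] <- mp$cigar
      chrom[sel] <- st$chrom; str[sel] <- st$strand
    }
  }
  data.frame(chrom = chrom, pos = pos, cigar = cig, strand = str,
             stringsAsFactors = FALSE)
}

# Extra-weight shares that make planted-cluster read starts ~fold-times the
# background rate inside each cluster.
planted_weights <- function(cfg, ref, weights, prec_frac) {
  cl <- ref$truth$clusters
  if (length(cl) == 0L) return(list(p = 0, share = numeric(0)))
  ann <- ref$ann
  extra <- numeric(length(cl))
  for (i in seq_along(cl)) {
    gid <- cl$gene_id[i]
    w_g <- weights[[gid]]
    gene <- ann$genes[ann$genes$gene_id == gid]
    tx_ids <- ann$tx$transcript_id[ann$tx$gene_id == gid]
    mature_share <- mean(vapply(tx_ids, function(id) {
      ex <- ann$exons_by_tx[[id]]
      ov <- sum(width(GenomicRanges::intersect(ex, cl[i],
                                               ignore.strand = TRUE)))
      ov / sum(width(ex))
    }, numeric(1)))
    base <- w_g * (prec_frac * width(cl)[i] / width(gene) +
                     (1 - prec_frac) * mature_share)
    extra[i] <- (cl$fold[i] - 1) * base
  }
  list(p = sum(extra) / (1 + sum(extra)),
       share = if (sum(extra) > 0) extra / sum(extra) else extra)
}

# Insert 1-nt deletions: at covered crosslink sites with deletion_prob, and
# at random interior positions with background_del_prob. Applied to
# contiguous (single-M) reads; a read carries at most one deletion.
apply_deletions <- function(reads, xlinks, deletion_prob, background_del_prob,
                            read_len) {
  plain <- reads$cigar == paste0(read_len, "M")
  deleted <- rep(FALSE, nrow(reads))
  if (length(xlinks) && deletion_prob > 0) {
    for (i in seq_along(xlinks)) {
      s <- start(xlinks)[i]
      chr <- as.character(seqnames(xlinks)[i])
      cand <- which(plain & !deleted & reads$chrom == chr &
                      reads$pos >= s - read_len + 2L & reads$pos <= s - 1L)
      if (!length(cand)) next
      hit <- cand[stats::runif(length(cand)) < deletion_prob]
      if (!length(hit)) next
      m1 <- s - reads$pos[hit]
      reads$cigar[hit] <- paste0(m1, "M1D", read_len - m1, "M")
      deleted[hit] <- TRUE
    }
  }
  if (background_del_prob > 0) {
    cand <- which(plain & !deleted &
                    stats::runif(nrow(reads)) < background_del_prob)
    if (length(cand)) {
      off <- 1L + floor(stats::runif(length(cand)) * (read_len - 1L))
      reads$cigar[cand] <- paste0(off, "M1D", read_len - off, "M")
    }
  }
  reads
}

reads_to_galignments <- function(reads, chrom_sizes, prefix) {
  GenomicAlignments::GAlignments(
    seqnames = factor(reads$chrom, levels = names(chrom_sizes)),
    pos = as.integer(reads$pos),
    cigar = reads$cigar,
    strand = factor(reads$strand, levels = c("+", "-", "*")),
    names = sprintf("%s_%07d", prefix, seq_len(nrow(reads))),
    seqlengths = chrom_sizes)
}

# Write a GAlignments as SAM text and convert to a sorted, indexed BAM.
write_bam_file <- function(galn, path, chrom_sizes) {
  sam <- sub("\\.bam$", ".sam", path)
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), chrom_sizes))
  flag <- ifelse(as.character(strand(galn)) == "-", 16L, 0L)
  body <- paste(names(galn) %||% sprintf("r_%07d", seq_along(galn)),
                flag, as.character(seqnames(galn)), start(galn), 255L,
                cigar(galn), "*", 0L, 0L, "*", "*", sep = "\t")
  writeLines(c(hdr, body), sam)
  Rsamtools::asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE,
                   indexDestination = TRUE)
  unlink(sam)
  invisible(path)
}

#' Simulate CLIP replicates and an RNA-seq input over a reference
#'
#' Input reads are drawn from mature and precursor transcript coordinates in
#' proportion to per-gene expression weights; CLIP reads are additionally
#' oversampled inside the planted clusters so their start-rate is about
#' `fold` times the background rate. CLIP reads overlapping a planted
#' crosslink site acquire a 1-nt deletion (CIGAR `D`) with
#' `deletion_prob`; a background deletion rate applies everywhere. Spliced
#' mature reads carry `N` CIGAR gaps at annotated introns.
#'
#' @param cfg `sim_config`.
#' @param ref result of [simulate_reference()].
#' @param outdir when non-`NULL`, sorted+indexed BAMs are written here.
#' @param write_bam write BAM files (default: only when `outdir` is given).
#' @return List with `clip` (list of `GAlignments`, one per replicate),
#'   `input` (`GAlignments`), `clip_bams`/`input_bam` (paths or `NULL`),
#'   `truth` and `expr_weights`.
#' @export
simulate_clip_experiment <- function(cfg, ref, outdir = NULL,
                                     write_bam = !is.null(outdir)) {
  ann <- ref$ann
  st_list <- tx_structures(ann)
  weights <- expression_weights(ann)
  chrom_sizes <- ann$chrom_sizes

  pw <- planted_weights(cfg, ref, weights, cfg$precursor_frac_clip)
  cl <- ref$truth$clusters

  n_rep <- cfg$n_clip_replicates
  base_n <- cfg$library_size_clip %/% n_rep
  n_by_rep <- rep(base_n, n_rep)
  extra <- cfg$library_size_clip - base_n * n_rep
  if (extra > 0) n_by_rep[seq_len(extra)] <- n_by_rep[seq_len(extra)] + 1L

  clip <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    clip[[r]] <- with_stream(cfg$seed, paste0("clip", r), {
      n <- n_by_rep[r]
      n_pl <- stats::rbinom(1L, n, pw$p)
      bg <- sample_background_reads(n - n_pl, ann, st_list, weights,
                                    cfg$precursor_frac_clip, cfg$read_len)
      reads <- if (n_pl > 0) {
        ci <- sample(length(cl), n_pl, replace = TRUE, prob = pw$share)
        lo <- start(cl)[ci]
        hi <- pmax(lo, end(cl)[ci] - cfg$read_len + 1L)
        pl <- data.frame(
          chrom = as.character(seqnames(cl))[ci],
          pos = lo + floor(stats::runif(n_pl) * (hi - lo + 1L)),
          cigar = paste0(cfg$read_len, "M"),
          strand = as.character(strand(cl))[ci],
          stringsAsFactors = FALSE)
        rbind(bg, pl)
      } else bg
      reads <- apply_deletions(reads, ref$truth$xlinks, cfg$deletion_prob,
                               cfg$background_del_prob, cfg$read_len)
      reads_to_galignments(reads, chrom_sizes, sprintf("clip%d", r))
    })
  }
  input <- with_stream(cfg$seed, "input", {
    reads <- sample_background_reads(cfg$library_size_input, ann, st_list,
                                     weights, cfg$precursor_frac_input,
                                     cfg$read_len)
    reads <- apply_deletions(reads, GRanges(), 0,
                             cfg$background_del_prob, cfg$read_len)
    reads_to_galignments(reads, chrom_sizes, "input")
  })

  clip_bams <- input_bam <- NULL
  if (write_bam) {
    stopifnot(!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    clip_bams <- vapply(seq_len(n_rep), function(r) {
      p <- file.path(outdir, sprintf("clip_rep%d.bam", r))
      write_bam_file(clip[[r]], p, chrom_sizes)
      p
    }, character(1))
    input_bam <- file.path(outdir, "input.bam")
    write_bam_file(input, input_bam, chrom_sizes)
  }
  list(clip = clip, input = input, clip_bams = clip_bams,
       input_bam = input_bam, truth = ref$truth, expr_weights = weights)
}

# Expression weights by biotype: rRNA-dominated ncRNA background plus an
# mRNA majority, echoing the class mixture of a nuclear CLIP library.
expression_weights <- function(ann) {
  genes <- ann$genes
  w <- numeric(length(genes))
  bt <- genes$biotype
  w[bt == "rRNA"] <- 0.26 / max(1, sum(bt == "rRNA"))
  w[bt == "snRNA"] <- 0.05 / max(1, sum(bt == "snRNA"))
  w[bt == "snoRNA"] <- 0.04 / max(1, sum(bt == "snoRNA"))
  w[bt == "lincRNA"] <- 0.05 / max(1, sum(bt == "lincRNA"))
  w[bt == "mRNA"] <- 0.60 / max(1, sum(bt == "mRNA"))
  other <- !(bt %in% c("rRNA", "snRNA", "snoRNA", "lincRNA", "mRNA"))
  w[other] <- 0.01
  stats::setNames(w / sum(w), genes$gene_id)
}

#' Simulate an exon-level differential-expression table
#'
#' Per exonic part (from [flatten_exonic_parts()] over all genes), null parts
#' receive `log2fc ~ Normal(0, de_sigma)` and a uniform adjusted p-value;
#' a `de_last_exon_bias` fraction of last parts is shifted up
#' (`log2fc >= 0.6`, tiny `padj`), emulating the near-exclusive upregulation
#' of last exons seen after demethylase loss. Null parts with `|log2fc| >=
#' 0.5` draw their `padj` above 0.05 so planted labels are exactly the
#' records passing the default DE filters.
#'
#' @param cfg `sim_config`.
#' @param ann `GenomeAnnotation`.
#' @param path optional TSV output path.
#' @return `data.frame` with columns `gene_id`, `part_id`, `pos_from_3p`,
#'   `is_last`, `log2fc`, `padj`, `true_label` (`"up"` or `"null"`).
#' @export
simulate_exon_de_table <- function(cfg, ann, path = NULL) {
  parts_list <- lapply(unique(ann$tx$gene_id),
                       function(g) flatten_exonic_parts(ann, g))
  parts <- do.call(c, parts_list)
  df <- data.frame(gene_id = parts$gene_id, part_id = parts$part_id,
                   pos_from_3p = parts$pos_from_3p, is_last = parts$is_last,
                   stringsAsFactors = FALSE)
  n <- nrow(df)
  with_stream(cfg$seed, "de_table", {
    lfc <- stats::rnorm(n, 0, cfg$de_sigma)
    padj <- stats::runif(n)
    padj[abs(lfc) >= 0.5] <- stats::runif(sum(abs(lfc) >= 0.5), 0.05, 1)
    label <- rep("null", n)
    last_idx <- which(df$is_last)
    n_up <- round(cfg$de_last_exon_bias * length(last_idx))
    if (n_up > 0) {
      up <- sample(last_idx, n_up)
      lfc[up] <- pmax(0.6, stats::rnorm(n_up, cfg$de_shift, 0.4))
      padj[up] <- stats::runif(n_up, 0, 1e-8)
      label[up] <- "up"
    }
    df$log2fc <- lfc; df$padj <- padj; df$true_label <- label
  })
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
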