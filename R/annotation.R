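# Genome annotation: GTF loading, exonic-part flattening, and the prioritized
# RNA-class region index that drives read categorization.

#' RNA class priority table
#'
#' The fixed 12-class vocabulary used to categorize CLIP reads, ordered by
#' priority (1 wins over 2, etc.): rRNA, tRNA, snoRNA, snRNA, miRNA, mRNA exon,
#' mRNA intron, mRNA unknown, lincRNA, repeat, antisense mRNA, unannotated.
#'
#' @export
CLIP_CLASSES <- c("rRNA", "tRNA", "snoRNA", "snRNA", "miRNA",
                  "mRNA exon", "mRNA intron", "mRNA unknown",
                  "lincRNA", "repeat", "antisense mRNA", "unannotated")

.BIOTYPES <- c("rRNA", "tRNA", "snoRNA", "snRNA", "miRNA", "mRNA",
               "lincRNA", "antisense", "repeat")

# Light sanity pass over a GTF so malformed lines are reported by number;
# parsing proper is delegated to rtracklayer.
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("GTF parse error at line ", i, ": expected 9 tab-separated fields")
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))))
      stop("GTF parse error at line ", i, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

#' Load a genome annotation
#'
#' Reads an Ensembl-dialect GTF (attributes `gene_id`, `transcript_id`,
#' `gene_biotype`; `exon` features required, `CDS` features optional) into a
#' `GenomeAnnotation` object holding per-transcript exons and introns, gene
#' spans, and chromosome sizes. Coordinates follow the GRanges convention;
#' GTF/BED conversion happens at the I/O boundary.
#'
#' @param gtf_path GTF file path.
#' @param fasta_path optional genome FASTA; supplies chromosome sizes and
#'   enables bounds validation. Without it sizes default to the maximum
#'   feature end per chromosome.
#' @param repeats_path optional BED of repeat intervals (e.g. RepeatMasker
#'   export); absent, the "repeat" class is never assigned.
#' @return A `GenomeAnnotation` object.
#' @export
load_annotation <- function(gtf_path, fasta_path = NULL, repeats_path = NULL) {
  validate_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  if (!all(c("type", "gene_id", "transcript_id") %in% names(mcols(gr))) &&
      !("type" %in% names(mcols(gr))))
    stop("GTF must carry type, gene_id and transcript_id")
  exons <- gr[gr$type == "exon"]
  if (length(exons) == 0L) stop("GTF contains no exon features")
  if (is.null(exons$gene_biotype)) exons$gene_biotype <- "mRNA"
  exons$gene_biotype[exons$gene_biotype %in%
                       c("protein_coding", "mRNA")] <- "mRNA"
  bad <- !(exons$gene_biotype %in% .BIOTYPES)
  if (any(bad)) exons$gene_biotype[bad] <- "mRNA"

  chrom_sizes <- if (!is.null(fasta_path)) {
    idx <- Rsamtools::scanFaIndex(fasta_path)
    stats::setNames(width(idx), as.character(seqnames(idx)))
  } else {
    tapply(end(gr), as.character(seqnames(gr)), max)
  }
  chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  out_of_bounds <- end(exons) > chrom_sizes[as.character(seqnames(exons))] |
    start(exons) < 1L
  if (any(out_of_bounds, na.rm = TRUE))
    stop("validation error: exon outside chromosome bounds (",
         paste(utils::head(exons$transcript_id[which(out_of_bounds)]), collapse = ", "),
         ")")

  seqlevels(exons) <- names(chrom_sizes)
  seqlengths(exons) <- chrom_sizes
  exons_by_tx <- split(granges(exons, use.mcols = FALSE),
                       exons$transcript_id)
  exons_by_tx <- endoapply(exons_by_tx, sort)

  ord <- match(names(exons_by_tx), exons$transcript_id)
  tx <- data.frame(transcript_id = names(exons_by_tx),
                   gene_id = exons$gene_id[ord],
                   biotype = exons$gene_biotype[ord],
                   chrom = as.character(seqnames(exons))[ord],
                   strand = as.character(strand(exons))[ord],
                   stringsAsFactors = FALSE)

  # introns are the gaps between consecutive exons of one transcript
  introns_by_tx <- psetdiff(unlist(range(exons_by_tx)), exons_by_tx)

  cds <- gr[gr$type == "CDS"]
  cds_by_tx <- if (length(cds)) {
    seqlevels(cds) <- names(chrom_sizes)
    seqlengths(cds) <- chrom_sizes
    endoapply(split(granges(cds, use.mcols = FALSE), cds$transcript_id), sort)
  } else NULL

  gene_rows <- !duplicated(tx$gene_id)
  genes <- unlist(range(split(unlist(exons_by_tx, use.names = FALSE),
                              rep(tx$gene_id, lengths(exons_by_tx)))))
  genes <- genes[tx$gene_id[gene_rows]]
  mcols(genes)$gene_id <- tx$gene_id[gene_rows]
  mcols(genes)$biotype <- tx$biotype[gene_rows]
  strand(genes) <- tx$strand[gene_rows][match(names(genes),
                                              tx$gene_id[gene_rows])]

  repeats <- if (!is.null(repeats_path))
    rtracklayer::import(repeats_path, format = "BED") else NULL

  ann <- structure(list(exons_by_tx = exons_by_tx,
                        introns_by_tx = introns_by_tx,
                        cds_by_tx = cds_by_tx,
                        tx = tx,
                        genes = genes,
                        chrom_sizes = chrom_sizes,
                        repeats = repeats,
                        n_exon_features = length(exons)),
                   class = "GenomeAnnotation")
  ann
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x$tx), "transcripts,",
      length(x$genes), "genes,", x$n_exon_features, "exon features on",
      length(x$chrom_sizes), "chromosome(s)\n")
  cat("  biotypes:", paste(names(table(x$genes$biotype)),
                           table(x$genes$biotype), collapse = ", "), "\n")
  invisible(x)
}

#' Write a GenomeAnnotation back to GTF
#'
#' Emits exon (and, when present, CDS) features with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes, deterministically ordered,
#' so `load_annotation(write_gtf(ann))` round-trips the feature set.
#'
#' @param ann `GenomeAnnotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  fmt <- function(grl, type) {
    gr <- unlist(grl, use.names = FALSE)
    txid <- rep(names(grl), lengths(grl))
    meta <- ann$tx[match(txid, ann$tx$transcript_id), ]
    data.frame(chrom = as.character(seqnames(gr)),
               source = "clipscape", type = type,
               start = start(gr), end = end(gr),
               score = ".", strand = as.character(strand(gr)),
               frame = ".",
               attr = sprintf(
                 'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                 meta$gene_id, txid, meta$biotype),
               stringsAsFactors = FALSE)
  }
  df <- fmt(ann$exons_by_tx, "exon")
  if (!is.null(ann$cds_by_tx)) df <- rbind(df, fmt(ann$cds_by_tx, "CDS"))
  df <- df[order(df$chrom, df$start, df$attr, df$type), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(df$chrom, df$source, df$type, df$start, df$end, df$score,
                   df$strand, df$frame, df$attr, sep = "\t"), con)
  invisible(path)
}

#' Flatten a gene into disjoint exonic parts
#'
#' Projects all isoform exon boundaries of a gene onto the genome and returns
#' the boundary-split union as disjoint parts (the flattened counting bins of
#' exon-level differential-usage analysis). Parts are numbered from the 5'
#' end (`part_number`) and from the 3' end (`pos_from_3p`, 1 = last part),
#' strand-aware: on the minus strand the leftmost part has `pos_from_3p = 1`.
#'
#' @param ann `GenomeAnnotation`.
#' @param gene_id gene identifier.
#' @return `GRanges` of parts with `gene_id`, `part_id`, `part_number`,
#'   `pos_from_3p`, `is_last` metadata columns.
#' @export
flatten_exonic_parts <- function(ann, gene_id) {
  tx_ids <- ann$tx$transcript_id[ann$tx$gene_id == gene_id]
  if (length(tx_ids) == 0L) stop("unknown gene_id: ", gene_id)
  ex <- unlist(ann$exons_by_tx[tx_ids], use.names = FALSE)
  parts <- disjoin(ex)   # boundary-split union, sorted by start
  n <- length(parts)
  minus <- as.character(strand(parts)[1]) == "-"
  part_number <- if (minus) rev(seq_len(n)) else seq_len(n)
  mcols(parts)$gene_id <- gene_id
  mcols(parts)$part_number <- part_number
  mcols(parts)$pos_from_3p <- n + 1L - part_number
  mcols(parts)$part_id <- sprintf("%s:E%03d", gene_id, part_number)
  mcols(parts)$is_last <- mcols(parts)$pos_from_3p == 1L
  parts
}

# Genomic 5'UTR / CDS / 3'UTR projections for coding transcripts.
utr_cds_regions <- function(ann) {
  empty <- GRanges(seqlengths = ann$chrom_sizes)
  if (is.null(ann$cds_by_tx))
    return(list(utr5 = empty, cds = empty, utr3 = empty))
  tx_ids <- intersect(names(ann$cds_by_tx), names(ann$exons_by_tx))
  u5 <- u3 <- cd <- vector("list", length(tx_ids))
  for (i in seq_along(tx_ids)) {
    id <- tx_ids[i]
    ex <- ann$exons_by_tx[[id]]
    cds <- range(ann$cds_by_tx[[id]])
    cd[[i]] <- GenomicRanges::intersect(ex, ann$cds_by_tx[[id]])
    utr <- GenomicRanges::setdiff(ex, cds)
    left <- utr[end(utr) < start(cds)]
    right <- utr[start(utr) > end(cds)]
    if (as.character(strand(ex)[1]) == "-") {
      u5[[i]] <- right; u3[[i]] <- left
    } else {
      u5[[i]] <- left; u3[[i]] <- right
    }
  }
  cat_gr <- function(lst) {
    if (length(lst) == 0) return(empty)
    reduce(do.call(c, lst))
  }
  list(utr5 = cat_gr(u5), cds = cat_gr(cd), utr3 = cat_gr(u3))
}

#' Build the prioritized RNA-class region index
#'
#' Maps every genomic position to the set of RNA classes overlapping it, with
#' mRNA positions sub-labeled exon vs intron and the opposite strand of mRNA
#' exons labeled "antisense mRNA" (unless an explicit antisense biotype is
#' annotated). "mRNA unknown" is the full mRNA gene span, so a read within an
#' mRNA locus that touches neither exon nor intron of any isoform still
#' resolves to its gene. The "repeat" class comes only from the optional
#' repeats BED.
#'
#' @param ann `GenomeAnnotation`.
#' @return A `RegionIndex` object: strand-aware class regions in priority
#'   order plus genomic 5'UTR/CDS/3'UTR subregions.
#' @export
build_region_index <- function(ann) {
  empty <- GRanges(seqlengths = ann$chrom_sizes)
  by_biotype <- function(b, what = c("exons", "span")) {
    what <- match.arg(what)
    ids <- ann$tx$transcript_id[ann$tx$biotype == b]
    if (length(ids) == 0L) return(empty)
    if (what == "exons") reduce(unlist(ann$exons_by_tx[ids], use.names = FALSE))
    else reduce(unlist(range(ann$exons_by_tx[ids]), use.names = FALSE))
  }
  m_ids <- ann$tx$transcript_id[ann$tx$biotype == "mRNA"]
  m_exon <- if (length(m_ids))
    reduce(unlist(ann$exons_by_tx[m_ids], use.names = FALSE)) else empty
  m_intron <- if (length(m_ids))
    reduce(unlist(ann$introns_by_tx[m_ids], use.names = FALSE)) else empty
  m_span <- if (length(m_ids))
    reduce(unlist(range(ann$exons_by_tx[m_ids]), use.names = FALSE)) else empty
  antisense <- c(by_biotype("antisense"), invertStrand(m_exon))
  rep_gr <- if (!is.null(ann$repeats)) {
    r <- granges(ann$repeats, use.mcols = FALSE)
    seqlevels(r) <- seqlevels(empty)
    r
  } else empty
  classes <- list(
    "rRNA" = by_biotype("rRNA"),
    "tRNA" = by_biotype("tRNA"),
    "snoRNA" = by_biotype("snoRNA"),
    "snRNA" = by_biotype("snRNA"),
    "miRNA" = by_biotype("miRNA"),
    "mRNA exon" = m_exon,
    "mRNA intron" = m_intron,
    "mRNA unknown" = m_span,
    "lincRNA" = by_biotype("lincRNA"),
    "repeat" = rep_gr,
    "antisense mRNA" = antisense)
  structure(list(classes = classes,
                 priorities = stats::setNames(seq_along(CLIP_CLASSES),
                                              CLIP_CLASSES),
                 subregions = utr_cds_regions(ann),
                 chrom_sizes = ann$chrom_sizes),
            class = "RegionIndex")
}

#' @export
print.RegionIndex <- function(x, ...) {
  n <- vapply(x$classes, length, integer(1))
  cat("RegionIndex with", length(x$classes), "classes:\n")
  print(n)
  invisible(x)
}

#' Classes overlapping query positions
#'
#' Returns, for each query range, the set of RNA classes whose regions
#' overlap it (strand is ignored for position queries; the antisense class is
#' omitted since an unstranded position has no antisense).
#'
#' @param index `RegionIndex`.
#' @param gr query `GRanges`.
#' @return `CharacterList`, one set per query.
#' @export
classes_at <- function(index, gr) {
  hits <- lapply(setdiff(names(index$classes), "antisense mRNA"), function(cl) {
    overlapsAny(gr, index$classes[[cl]], ignore.strand = TRUE)
  })
  names(hits) <- setdiff(names(index$classes), "antisense mRNA")
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    out[[i]] <- names(hits)[vapply(hits, `[`, logical(1), i)]
    # drop the catch-all span label when a finer mRNA label is present
    if (any(c("mRNA exon", "mRNA intron") %in% out[[i]]))
      out[[i]] <- setdiff(out[[i]], "mRNA unknown")
  }
  IRanges::CharacterList(out)
}

#' Anchor sets derived from an annotation
#'
#' Strand-oriented single-base anchors: transcription start sites (`tss`) or
#' transcript 3' ends / annotated poly(A) positions (`polya`), one per
#' transcript, deduplicated.
#'
#' @param ann `GenomeAnnotation`.
#' @param type `"tss"` or `"polya"`.
#' @param biotype optional biotype filter (e.g. `"mRNA"`).
#' @return `GRanges` of width-1 anchors.
#' @export
anchors_from_annotation <- function(ann, type = c("tss", "polya"),
                                    biotype = NULL) {
  type <- match.arg(type)
  keep <- if (is.null(biotype)) rep(TRUE, nrow(ann$tx))
          else ann$tx$biotype %in% biotype
  spans <- unlist(range(ann$exons_by_tx[ann$tx$transcript_id[keep]]))
  anchors <- if (type == "tss") resize(spans, 1L, fix = "start")
             else resize(spans, 1L, fix = "end")
  unique(anchors)
}
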