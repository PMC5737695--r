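# Shared fixtures: a cached standard simulated study, a hand-built toy
# annotation with known geometry, and constructors for synthetic alignments.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(GenomicAlignments)
  library(Biostrings)
})

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Standard study at the package's default conditions (12 genes, ~100 kb,
# 3 x ~50k CLIP reads + 50k input), fixed fixture seed.
std_study <- function() {
  cached("std", function() {
    cfg <- sim_config(seed = 101L)
    ref <- simulate_reference(cfg)
    sim <- simulate_clip_experiment(cfg, ref)
    list(cfg = cfg, ref = ref, sim = sim)
  })
}

# Small study for cheap module tests.
small_study <- function() {
  cached("small", function() {
    cfg <- sim_config(seed = 42L, library_size_clip = 9000L,
                      library_size_input = 3000L)
    ref <- simulate_reference(cfg)
    sim <- simulate_clip_experiment(cfg, ref)
    list(cfg = cfg, ref = ref, sim = sim)
  })
}

# Larger annotation (exonic-part substrate) for the DE statistics; the read
# modules never touch it, so no libraries are simulated.
de_study_ann <- function() {
  cached("de_ann", function() {
    cfg <- sim_config(seed = 7L, n_genes = 60L, genome_len = 400000L)
    simulate_reference(cfg)$ann
  })
}

# Hand-built toy annotation with known geometry:
#   geneA (+, mRNA): iso1 exons [101,200],[301,400]; iso2 [101,200],[301,450]
#     -> flattened parts [101,200],[301,400],[401,450]
#   geneB (-, mRNA): exons [1001,1100],[1301,1400],[1601,1800] with CDS
#   geneR (rRNA, +): [3001,3800], overlapping geneC mRNA exon [3501,3700]
#   geneC (+, mRNA): exons [3501,3700],[3901,4000]
#   geneS (snoRNA, +): [1451,1550] hosted inside geneB's intron
#   geneL (lincRNA, +): [5001,5200]
toy_annotation <- function() {
  cached("toy", function() {
    dir <- tempfile("toyann"); dir.create(dir)
    gtf <- file.path(dir, "toy.gtf")
    line <- function(chrom, type, s, e, str, gid, tid, bt)
      paste(chrom, "test", type, s, e, ".", str, ".",
            sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                    gid, tid, bt), sep = "\t")
    writeLines(c(
      line("chrT", "exon", 101, 200, "+", "geneA", "geneA.1", "protein_coding"),
      line("chrT", "exon", 301, 400, "+", "geneA", "geneA.1", "protein_coding"),
      line("chrT", "exon", 101, 200, "+", "geneA", "geneA.2", "protein_coding"),
      line("chrT", "exon", 301, 450, "+", "geneA", "geneA.2", "protein_coding"),
      line("chrT", "exon", 1001, 1100, "-", "geneB", "geneB.1", "protein_coding"),
      line("chrT", "exon", 1301, 1400, "-", "geneB", "geneB.1", "protein_coding"),
      line("chrT", "exon", 1601, 1800, "-", "geneB", "geneB.1", "protein_coding"),
      # CDS: mature length 400; 5'UTR = first 100 (genomic [1701,1800]),
      # CDS = next 250, 3'UTR = last 50 (genomic [1001,1050])
      line("chrT", "CDS", 1051, 1100, "-", "geneB", "geneB.1", "protein_coding"),
      line("chrT", "CDS", 1301, 1400, "-", "geneB", "geneB.1", "protein_coding"),
      line("chrT", "CDS", 1601, 1700, "-", "geneB", "geneB.1", "protein_coding"),
      line("chrT", "exon", 3001, 3800, "+", "geneR", "geneR.1", "rRNA"),
      line("chrT", "exon", 3501, 3700, "+", "geneC", "geneC.1", "protein_coding"),
      line("chrT", "exon", 3901, 4000, "+", "geneC", "geneC.1", "protein_coding"),
      line("chrT", "exon", 1451, 1550, "+", "geneS", "geneS.1", "snoRNA"),
      line("chrT", "exon", 5001, 5200, "+", "geneL", "geneL.1", "lincRNA")
    ), gtf)
    fasta <- file.path(dir, "toy.fa")
    set.seed(99)
    writeXStringSet(DNAStringSet(c(chrT = paste(
      sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
      collapse = ""))), fasta)
    Rsamtools::indexFa(fasta)
    ann <- load_annotation(gtf, fasta)
    list(gtf = gtf, fasta = fasta, ann = ann,
         index = build_region_index(ann))
  })
}

# Synthetic alignments with explicit CIGARs.
make_aln <- function(chrom, pos, cigar, strand = "+",
                     seqlen = c(chrT = 10000L)) {
  n <- max(length(chrom), length(pos), length(cigar), length(strand))
  GAlignments(seqnames = factor(rep_len(chrom, n), levels = names(seqlen)),
              pos = as.integer(rep_len(pos, n)),
              cigar = rep_len(cigar, n),
              strand = factor(rep_len(strand, n),
                              levels = c("+", "-", "*")),
              seqlengths = seqlen)
}

# ---- independent oracles --------------------------------------------------

# Hypergeometric enumeration over all tables with the observed margins.
# two-sided: point-probability method; greater: upper tail.
fisher_oracle_p <- function(a, b, c, d,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)), numeric(1))
  p_obs <- probs[xs == a]
  if (alternative == "greater") sum(probs[xs >= a])
  else sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Full-permutation Mann-Whitney: distribution of U over all group
# assignments; two-sided doubling rule on the exact tail.
mwu_oracle_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, u_of)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Manual CIGAR walk: reference intervals (M/=/X/D merged, N splits blocks)
# and deleted positions, with no GenomicAlignments machinery.
walk_cigar <- function(cig, pos) {
  ops <- regmatches(cig, gregexpr("\\d+[A-Z=]", cig))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  cur <- pos
  blocks <- list(); dels <- integer(0)
  bstart <- NA_integer_
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      if (is.na(bstart)) bstart <- cur
      if (op[i] == "D") dels <- c(dels, cur:(cur + len[i] - 1L))
      cur <- cur + len[i]
    } else if (op[i] == "N") {
      if (!is.na(bstart)) blocks[[length(blocks) + 1L]] <-
          c(bstart, cur - 1L)
      bstart <- NA_integer_
      cur <- cur + len[i]
    }
    # I/S/H/P consume no reference
  }
  if (!is.na(bstart)) blocks[[length(blocks) + 1L]] <- c(bstart, cur - 1L)
  list(blocks = blocks, dels = dels)
}

# Brute-force window counts: direct arithmetic on 50-bp tile indices.
oracle_window_counts <- function(aln, chrom_sizes, width = 50L) {
  chroms <- names(chrom_sizes)
  n_win <- ceiling(chrom_sizes / width)
  offset <- cumsum(c(0L, head(n_win, -1L)))
  names(offset) <- chroms
  counts <- integer(sum(n_win))
  cigs <- cigar(aln); poss <- start(aln)
  chrs <- as.character(seqnames(aln))
  for (i in seq_along(aln)) {
    w <- walk_cigar(cigs[i], poss[i])
    idx <- integer(0)
    for (b in w$blocks)
      idx <- c(idx, ((b[1] - 1L) %/% width):((b[2] - 1L) %/% width))
    idx <- unique(idx)
    j <- offset[[chrs[i]]] + idx + 1L
    counts[j] <- counts[j] + 1L
  }
  counts
}

# Brute-force per-strand deletion pileup via difference arrays.
oracle_crosslink_sites <- function(aln, chrom_sizes, min_cov = 6L,
                                   min_freq = 0.05) {
  out <- list()
  chrs <- as.character(seqnames(aln)); strs <- as.character(strand(aln))
  cigs <- cigar(aln); poss <- start(aln)
  for (s in c("+", "-")) for (chr in names(chrom_sizes)) {
    sel <- which(chrs == chr & strs == s)
    if (!length(sel)) next
    L <- chrom_sizes[[chr]]
    covd <- numeric(L + 1L); del <- numeric(L)
    for (i in sel) {
      w <- walk_cigar(cigs[i], poss[i])
      for (b in w$blocks) {
        covd[b[1]] <- covd[b[1]] + 1
        covd[b[2] + 1L] <- covd[b[2] + 1L] - 1
      }
      if (length(w$dels)) del[w$dels] <- del[w$dels] + 1
    }
    cov <- cumsum(covd)[seq_len(L)]
    hit <- which(del > 0 & cov >= min_cov & del >= min_freq * cov)
    if (length(hit))
      out[[paste(chr, s)]] <- data.frame(chrom = chr, pos = hit,
                                         strand = s, coverage = cov[hit],
                                         deletions = del[hit])
  }
  if (!length(out)) return(data.frame())
  df <- do.call(rbind, out)
  df[order(df$chrom, df$pos, df$strand), ]
}

# Brute-force read counts over arbitrary regions (any-block overlap).
oracle_region_counts <- function(aln, regions) {
  cigs <- cigar(aln); poss <- start(aln)
  chrs <- as.character(seqnames(aln))
  rchr <- as.character(seqnames(regions))
  rs <- start(regions); re <- end(regions)
  counts <- integer(length(regions))
  for (i in seq_along(aln)) {
    w <- walk_cigar(cigs[i], poss[i])
    for (j in seq_along(regions)) {
      if (rchr[j] != chrs[i]) next
      for (b in w$blocks) {
        if (b[1] <= re[j] && b[2] >= rs[j]) {
          counts[j] <- counts[j] + 1L
          break
        }
      }
    }
  }
  counts
}

# Set-of-substrings ZOOPS oracle built character by character.
oracle_zoops <- function(seqs, k) {
  tab <- new.env(parent = emptyenv())
  for (s in as.character(seqs)) {
    chars <- strsplit(s, "")[[1]]
    if (length(chars) < k) next
    seen <- character(0)
    for (i in seq_len(length(chars) - k + 1L)) {
      km <- paste(chars[i:(i + k - 1L)], collapse = "")
      if (grepl("N", km, fixed = TRUE)) next
      if (!(km %in% seen)) seen <- c(seen, km)
    }
    for (km in seen)
      tab[[km]] <- (if (is.null(tab[[km]])) 0L else tab[[km]]) + 1L
  }
  ks <- ls(tab)
  stats::setNames(vapply(ks, function(k2) tab[[k2]], integer(1)), ks)
}

# Brute-force priority categorization against an explicit feature list.
oracle_categorize <- function(aln, index) {
  labs <- character(length(aln))
  cigs <- cigar(aln); poss <- start(aln)
  chrs <- as.character(seqnames(aln)); strs <- as.character(strand(aln))
  cls_df <- lapply(index$classes, function(gr)
    data.frame(chrom = as.character(seqnames(gr)), s = start(gr),
               e = end(gr), str = as.character(strand(gr))))
  for (i in seq_along(aln)) {
    w <- walk_cigar(cigs[i], poss[i])
    labs[i] <- "unannotated"
    for (cl in names(cls_df)) {
      f <- cls_df[[cl]]
      found <- FALSE
      for (j in seq_len(nrow(f))) {
        if (f$chrom[j] != chrs[i]) next
        if (!(f$str[j] == "*" || f$str[j] == strs[i])) next
        for (b in w$blocks) {
          if (b[1] <= f$e[j] && b[2] >= f$s[j]) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) { labs[i] <- cl; break }
    }
  }
  labs
}
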