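# Shared internal helpers: alignment input, RPKM arithmetic, seeded substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read primary alignments from a BAM file
#'
#' Loads primary, mapped alignments (secondary and supplementary records are
#' excluded, matching the duplicate-collapsed primary-alignment convention used
#' throughout the package). A `GAlignments` object passes through unchanged, so
#' every analysis function accepts either a BAM path or an in-memory object.
#'
#' @param x BAM file path or a `GAlignments` object.
#' @return A `GAlignments` object.
#' @export
read_alignments <- function(x) {
  if (methods::is(x, "GAlignments")) return(x)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  GenomicAlignments::readGAlignments(x,
    param = Rsamtools::ScanBamParam(flag = flags))
}

#' Library size of an alignment set
#'
#' Number of primary mapped alignments; the denominator of every RPKM and CPM
#' in the package.
#'
#' @param x BAM path or `GAlignments`.
#' @return Integer count.
#' @export
library_size <- function(x) length(read_alignments(x))

#' Reads per kilobase per million mapped reads
#'
#' `count * 1e9 / (width * lib_size)`.
#'
#' @param count read counts.
#' @param width feature widths in bases.
#' @param lib_size library size (primary mapped alignments).
#' @return Numeric RPKM values.
#' @export
rpkm <- function(count, width, lib_size) {
  stopifnot(all(width > 0), lib_size > 0)
  count * 1e9 / (width * lib_size)
}

# Aligned blocks (M/=/X, with D absorbed, N gaps excluded) as a GRangesList;
# the overlap unit used by the counting and classification code.
aligned_blocks <- function(aln) {
  GenomicAlignments::grglist(aln, drop.D.ranges = FALSE)
}

# Deterministic per-stream seed derived from one global seed, so that e.g.
# adding a replicate never perturbs the genome stream.  Kept below 2^31 - 1.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 12345) %% 2147483629)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(stream_seed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Load a genome as a named DNAStringSet; names trimmed to the first word.
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  g <- Biostrings::readDNAStringSet(genome)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Write a GRanges as BED6 (name/score/strand), converting coordinates at the
# boundary via rtracklayer.
write_bed6 <- function(gr, path, name = NULL, score = NULL) {
  mcols(gr) <- NULL
  gr$name <- name %||% paste0("feature_", seq_along(gr))
  gr$score <- score %||% rep(0, length(gr))
  rtracklayer::export(sort(gr), path, format = "BED")
  invisible(path)
}
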