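# End-to-end pipeline wrapper over the synthetic study: simulate, call
# clusters and crosslink sites, rank motifs, emit the DE table, and write
# every result as plain-text/BAM artifacts.

#' Run the full CLIP analysis pipeline on a simulated study
#'
#' Simulates the reference and libraries for `cfg`, scores 50-bp windows,
#' calls binding clusters (both filter variants available via `mode`), calls
#' crosslink sites per replicate, ranks k-mer motifs, and generates the
#' exon-level DE table. When `outdir` is given, all artifacts are written:
#' FASTA/GTF/BAMs, clusters as BED6 (score = `min(1000, round(100 * fold))`)
#' and TSV, per-replicate crosslink sites as BED6 (score =
#' `round(1000 * del_freq)`), the motif table and DE table as TSV. Given the
#' same config (including seed) the outputs are byte-identical across runs.
#'
#' @param cfg `sim_config`.
#' @param outdir output directory, or `NULL` to keep results in memory.
#' @param mode cluster filter variant, see [call_clusters()].
#' @param k_range k-mer lengths for motif ranking.
#' @return List with `ref`, `sim`, `scores`, `clusters`, `sites`, `motifs`,
#'   `de_table` and (when written) `files`.
#' @export
run_clip_pipeline <- function(cfg, outdir = NULL,
                              mode = c("results", "methods"),
                              k_range = 5L) {
  mode <- match.arg(mode)
  write_out <- !is.null(outdir)
  if (write_out) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(cfg, outdir = if (write_out)
    file.path(outdir, "reference") else tempfile("simref"))
  sim <- simulate_clip_experiment(cfg, ref,
    outdir = if (write_out) file.path(outdir, "alignments") else NULL)
  scores <- window_scores(sim$clip, sim$input,
                          chrom_sizes = ref$ann$chrom_sizes)
  clusters <- call_clusters(scores, mode = mode)
  sites <- lapply(sim$clip, call_crosslink_sites)
  motifs <- rank_motifs(sites, ref$genome, k_range = k_range,
                        aln_sets = sim$clip, seed = cfg$seed)
  de_table <- simulate_exon_de_table(cfg, ref$ann)

  files <- NULL
  if (write_out) {
    cl_bed <- file.path(outdir, "clusters.bed")
    if (length(clusters))
      write_bed6(clusters, cl_bed, name = clusters$cluster_id,
                 score = pmin(1000, round(100 * clusters$fold)))
    else writeLines(character(0), cl_bed)
    cl_tsv <- file.path(outdir, "clusters.tsv")
    utils::write.table(as.data.frame(clusters), cl_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    site_beds <- vapply(seq_along(sites), function(r) {
      p <- file.path(outdir, sprintf("xlink_sites_rep%d.bed", r))
      if (length(sites[[r]]))
        write_bed6(sites[[r]], p,
                   name = sprintf("site_%05d", seq_along(sites[[r]])),
                   score = round(1000 * sites[[r]]$del_freq))
      else writeLines(character(0), p)
      p
    }, character(1))
    motif_tsv <- file.path(outdir, "motifs.tsv")
    utils::write.table(as.data.frame(motifs), motif_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    de_tsv <- file.path(outdir, "exon_de.tsv")
    utils::write.table(de_table, de_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(fasta = ref$fasta, gtf = ref$gtf,
               stats::setNames(sim$clip_bams,
                               paste0("clip_bam", seq_along(sim$clip_bams))),
               input_bam = sim$input_bam, clusters_bed = cl_bed,
               clusters_tsv = cl_tsv,
               stats::setNames(site_beds,
                               paste0("sites_bed", seq_along(site_beds))),
               motifs_tsv = motif_tsv, de_tsv = de_tsv)
  }
  list(ref = ref, sim = sim, scores = scores, clusters = clusters,
       sites = sites, motifs = motifs, de_table = de_table, files = files)
}
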