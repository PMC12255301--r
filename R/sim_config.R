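#' Simulation configuration
#'
#' Parameters for the synthetic bacterial RNA-seq generator. Defaults describe
#' the study conditions used throughout the package's validation: a 50-kb
#' genome at 40% GC (Acinetobacter-like base composition) carrying 40 CDS of
#' 300--900 nt on both strands plus two tRNA genes; 30 editing sites planted
#' in YTACGAA motifs inside 5-bp-stem hairpins with per-site editing levels
#' drawn uniformly from 10--60%; stranded 100-nt single-end reads at 50x mean
#' gene-body coverage with a 1e-3 per-base substitution error rate at constant
#' Q37; three biological replicates; and five strain-specific coding A>G SNPs
#' at ~100% allele frequency to exercise the <=98% frequency ceiling.
#'
#' @param genome_length genome size in bases.
#' @param gc_content GC fraction in `[0, 1]`.
#' @param n_genes number of protein-coding genes (CDS).
#' @param gene_length_range length range (bases) for CDS; rounded to codons.
#' @param n_trna number of tRNA genes (76 nt each).
#' @param n_edit_sites number of editing sites to plant.
#' @param level_distribution per-site designed editing level: either a
#'   length-2 numeric range for uniform sampling, or a longer vector of fixed
#'   levels sampled with replacement. All values in `[0, 1]`.
#' @param hairpin_fraction fraction of planted sites embedded in a stem-loop.
#' @param hairpin_stem_length stem length (base pairs) of planted hairpins.
#' @param read_length read length in bases.
#' @param mean_coverage mean fold coverage over gene bodies.
#' @param error_rate per-base substitution error probability.
#' @param base_quality constant Phred score, or a list
#'   `list(q =, tail_length =, tail_q =)` adding a low-quality 3' tail.
#' @param n_replicates number of biological replicates.
#' @param stranded logical; strand-specific library.
#' @param n_strain_snps number of strain-specific coding A>G SNPs planted at
#'   100% frequency in non-edited gene positions.
#' @param seed master RNG seed; replicate streams are derived from it by
#'   fixed offsets.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 50000L,
                       gc_content = 0.40,
                       n_genes = 40L,
                       gene_length_range = c(300L, 900L),
                       n_trna = 2L,
                       n_edit_sites = 30L,
                       level_distribution = c(0.10, 0.60),
                       hairpin_fraction = 1.0,
                       hairpin_stem_length = 5L,
                       read_length = 100L,
                       mean_coverage = 50,
                       error_rate = 1e-3,
                       base_quality = 37L,
                       n_replicates = 3L,
                       stranded = TRUE,
                       n_strain_snps = 5L,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_trna = as.integer(n_trna),
    n_edit_sites = as.integer(n_edit_sites),
    level_distribution = level_distribution,
    hairpin_fraction = hairpin_fraction,
    hairpin_stem_length = as.integer(hairpin_stem_length),
    read_length = as.integer(read_length), mean_coverage = mean_coverage,
    error_rate = error_rate, base_quality = base_quality,
    n_replicates = as.integer(n_replicates), stranded = isTRUE(stranded),
    n_strain_snps = as.integer(n_strain_snps), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$genome_length > 0L,
    cfg$gc_content >= 0, cfg$gc_content <= 1,
    cfg$n_genes >= 0L, length(cfg$gene_length_range) == 2L,
    cfg$gene_length_range[1] <= cfg$gene_length_range[2],
    cfg$n_edit_sites >= 0L,
    all(cfg$level_distribution >= 0), all(cfg$level_distribution <= 1),
    cfg$hairpin_fraction >= 0, cfg$hairpin_fraction <= 1,
    cfg$hairpin_stem_length >= 3L,
    # 17-nt window = stem + loop + stem with the 7-nt motif inside the loop
    cfg$hairpin_stem_length <= 5L,
    cfg$read_length > 0L, cfg$mean_coverage >= 0,
    cfg$error_rate >= 0, cfg$error_rate <= 1,
    cfg$n_replicates >= 1L, cfg$n_strain_snps >= 0L
  )
  # capacity: genes plus minimal spacing must fit the genome
  need <- cfg$n_genes * (cfg$gene_length_range[2] + 20L) + cfg$n_trna * 96L
  if (need > cfg$genome_length) {
    stop("genome_length too small for n_genes at the maximum gene length")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$genome_length, "bp genome,", x$n_genes, "CDS +",
      x$n_trna, "tRNA,", x$n_edit_sites, "edit sites,",
      x$n_replicates, "replicates @", x$mean_coverage, "x, seed", x$seed, "\n")
  invisible(x)
}
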