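#' Run a full simulation-to-discovery study
#'
#' Convenience wrapper exercising the whole pipeline end to end on synthetic
#' data: genome generation, site planting, read simulation, trimming,
#' mapping, per-sample QC and pileups, and the discovery cascade. The
#' default discovery profile matches the library the simulator emits
#' (stranded, no DNA-variant list, 100%-replicate intersection).
#'
#' @param config a [sim_config()].
#' @param profile a [discovery_profile()]; default `"cross_species"` with
#'   strand-specific filtering switched to the simulated library type.
#' @param call_args overrides for [call_variants()].
#' @return list with `genome`, `truth`, `snps`, `sim`, `pileups`, `sites`
#'   (the final `editing_sites` table), and `qc` (per-sample mapped
#'   fractions).
#' @export
run_editing_simulation <- function(config = sim_config(),
                                   profile = NULL, call_args = list()) {
  if (is.null(profile)) {
    profile <- discovery_profile("cross_species",
                                 stranded_filtering = config$stranded)
  }
  g0 <- generate_genome(config)
  planted <- plant_editing_sites(g0, config)
  sim <- simulate_reads(planted$genome, planted$truth, config)

  pileups <- list()
  qc <- list()
  for (r in seq_along(sim$replicates)) {
    sample_id <- sprintf("rep%d", r)
    reads <- trim_reads(sim$replicates[[r]])
    aln <- map_reads(reads, planted$genome)
    q <- sample_qc(aln, nrow(sim$replicates[[r]]))
    qc[[sample_id]] <- q$mapped_fraction
    if (!q$pass) next
    pileups[[sample_id]] <- build_pileup(aln, planted$genome,
                                         sample_id = sample_id)
  }
  sites <- discover_editing(pileups, planted$genome, profile,
                            library_stranded = config$stranded,
                            call_args = call_args)
  list(genome = planted$genome, truth = planted$truth, snps = sim$snps,
       sim = sim, pileups = pileups, sites = sites, qc = unlist(qc))
}

#' Score recovered sites against planted ground truth
#'
#' Sensitivity (planted sites recovered), false positives (recovered sites
#' not planted), strain-SNP leakage, and level accuracy: per recovered site
#' the total edited-read count across samples is compared with the central
#' 95% binomial interval implied by the designed level and the observed
#' total coverage.
#'
#' @param sites `editing_sites` table from [discover_editing()].
#' @param truth truth table from [plant_editing_sites()].
#' @param snps strain-SNP table from [simulate_reads()] (optional).
#' @return list with `n_truth`, `n_called`, `n_recovered`, `sensitivity`,
#'   `false_positives`, `snp_leakage`, `level_in_ci` (count), and
#'   `level_ci_coverage` (fraction of recovered sites whose estimate lies in
#'   the interval).
#' @export
evaluate_recovery <- function(sites, truth, snps = NULL) {
  called <- paste(sites$contig, sites$pos)
  planted <- paste(truth$contig, truth$pos)
  recovered <- intersect(called, planted)
  fp <- setdiff(called, planted)
  snp_leak <- if (!is.null(snps) && nrow(snps)) {
    sum(paste(snps$contig, snps$pos) %in% called)
  } else 0L

  lv <- attr(sites, "levels")
  in_ci <- 0L
  n_eval <- 0L
  if (!is.null(lv) && length(recovered)) {
    agg <- lv[!is.na(level),
              .(k = sum(count), n = sum(coverage)), by = .(contig, pos)]
    agg <- agg[paste(contig, pos) %in% recovered]
    agg <- merge(agg, truth[, .(contig, pos, designed_level)],
                 by = c("contig", "pos"))
    lo <- qbinom(0.025, agg$n, agg$designed_level)
    hi <- qbinom(0.975, agg$n, agg$designed_level)
    in_ci <- sum(agg$k >= lo & agg$k <= hi)
    n_eval <- nrow(agg)
  }
  list(n_truth = nrow(truth), n_called = length(called),
       n_recovered = length(recovered),
       sensitivity = length(recovered) / max(1L, nrow(truth)),
       false_positives = length(fp), snp_leakage = snp_leak,
       level_in_ci = in_ci,
       level_ci_coverage = if (n_eval) in_ci / n_eval else NA_real_)
}
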