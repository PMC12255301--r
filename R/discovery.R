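#' Editing-discovery filter profile
#'
#' Bundles the post-call filter cascade parameters. Two presets mirror the
#' two analyses the pipeline supports: `"cross_species"` (frequency band
#' 5--98%, variants required in 100% of replicates) and `"abaylyi"`
#' (frequency band 1--98%, at least 3 of 4 replicates, strand-specific
#' filtering and DNA-variant subtraction enabled).
#'
#' @param preset `"cross_species"` or `"abaylyi"`.
#' @param ... named overrides of any profile field: `min_unique_starts`,
#'   `min_unique_ends`, `min_freq_pct`, `max_freq_pct`, `max_alleles`,
#'   `replicate_rule` (`"all"` or `"at_least_k"`), `replicate_k`,
#'   `restrict_to_genes`, `stranded_filtering`, `dna_variant_subtraction`.
#' @return an object of class `discovery_profile`.
#' @export
discovery_profile <- function(preset = c("cross_species", "abaylyi"), ...) {
  preset <- match.arg(preset)
  prof <- list(
    min_unique_starts = 3L, min_unique_ends = 3L,
    min_freq_pct = if (preset == "abaylyi") 1.0 else 5.0,
    max_freq_pct = 98.0, max_alleles = 2L,
    replicate_rule = if (preset == "abaylyi") "at_least_k" else "all",
    replicate_k = if (preset == "abaylyi") 3L else NA_integer_,
    restrict_to_genes = TRUE,
    stranded_filtering = preset == "abaylyi",
    dna_variant_subtraction = preset == "abaylyi",
    preset = preset
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(prof))
  if (length(bad)) stop("unknown profile fields: ", paste(bad, collapse = ", "))
  prof[names(dots)] <- dots
  stopifnot(prof$min_freq_pct > 0, prof$min_freq_pct < prof$max_freq_pct,
            prof$max_freq_pct <= 100)
  structure(prof, class = "discovery_profile")
}

#' Apply the post-call variant filter cascade
#'
#' Retains calls with at least `min_unique_starts`/`min_unique_ends` distinct
#' supporting start/end coordinates, frequency inside the inclusive band
#' `[min_freq_pct, max_freq_pct]` (the 98% ceiling excludes strain-specific
#' mutations at ~100% frequency), and at most `max_alleles` alleles observed
#' at the position (hyper-allelic exclusion).
#'
#' @param calls `variant_calls` table.
#' @param profile a [discovery_profile()].
#' @return filtered `variant_calls` table.
#' @export
filter_variants <- function(calls, profile) {
  calls[ustarts >= profile$min_unique_starts &
          uends >= profile$min_unique_ends &
          freq_pct >= profile$min_freq_pct &
          freq_pct <= profile$max_freq_pct &
          n_alleles <= profile$max_alleles]
}

#' Keep variants by transcriptional strand (stranded libraries)
#'
#' For strand-specific data, a genuine transcript-to-genome mismatch must be
#' supported by reads on the transcribed strand of its host gene. Support and
#' coverage are recomputed from sense-strand reads only (antisense reads do
#' not count toward the level), and variants with no sense support, or
#' falling outside annotated genes, are dropped.
#'
#' @param calls `variant_calls` table (with per-strand counts).
#' @param genome an [annotated_genome()] supplying gene strands.
#' @param library_stranded logical; must be `TRUE` -- calling this on an
#'   unstranded library is a configuration error.
#' @return recomputed `variant_calls` restricted to sense-supported variants;
#'   gains a `gene_strand` column.
#' @export
stranded_filter <- function(calls, genome, library_stranded = TRUE) {
  if (!isTRUE(library_stranded)) {
    stop("stranded_filtering requested on an unstranded library")
  }
  ann <- .gene_at(calls, genome)
  out <- cbind(copy(calls), ann)
  out <- out[!is.na(gene_strand)]
  out[, `:=`(count = ifelse(gene_strand == "+", plus, minus),
             coverage = ifelse(gene_strand == "+", cov_plus, cov_minus))]
  out <- out[count > 0L & coverage > 0L]
  out[, freq_pct := 100 * count / coverage]
  out[, c("gene_id_hit", "rna_class_hit") := NULL]
  out[]
}

# annotate positions with host gene (NA if intergenic or ambiguous both-strand)
.gene_at <- function(tab, genome) {
  gr <- GenomicRanges::GRanges(tab$contig, IRanges::IRanges(tab$pos, tab$pos))
  hits <- GenomicRanges::findOverlaps(gr, genome$features,
                                      ignore.strand = TRUE)
  gene_id <- rep(NA_character_, nrow(tab))
  gene_strand <- rep(NA_character_, nrow(tab))
  rna_class <- rep(NA_character_, nrow(tab))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  amb <- character(0)
  for (q in unique(qh)) {
    f <- sh[qh == q]
    strands <- unique(as.character(GenomicRanges::strand(
      genome$features[f])))
    if (length(strands) > 1L) { amb <- c(amb, q); next }
    f1 <- f[1L]
    gene_id[q] <- genome$features$gene_id[f1]
    gene_strand[q] <- strands
    rna_class[q] <- switch(genome$features$type[f1],
                           CDS = "mRNA", tRNA = "tRNA", rRNA = "rRNA",
                           genome$features$type[f1])
  }
  if (length(amb)) {
    warning(length(amb), " variant(s) inside overlapping genes on both ",
            "strands dropped as ambiguous")
  }
  data.table(gene_id_hit = gene_id, gene_strand = gene_strand,
             rna_class_hit = rna_class)
}

#' Intersect variants across biological replicates
#'
#' A (position, alternative allele) key survives iff it is present in the
#' required number of samples of the same experiment; surviving keys are
#' unioned across experiments.
#'
#' @param per_sample_calls named list of (filtered) `variant_calls`, one per
#'   sample.
#' @param experiments named character vector mapping sample name to
#'   experiment id; defaults to one experiment containing all samples.
#' @param rule `"all"` (shared by 100% of replicates) or `"at_least_k"`.
#' @param k required replicate count for `"at_least_k"`.
#' @return `data.table(contig, pos, ref, alt)` of surviving keys.
#' @export
intersect_replicates <- function(per_sample_calls,
                                 experiments = NULL,
                                 rule = c("all", "at_least_k"), k = NULL) {
  rule <- match.arg(rule)
  samples <- names(per_sample_calls)
  if (is.null(samples)) stop("per_sample_calls must be a named list")
  if (is.null(experiments)) {
    experiments <- setNames(rep("exp1", length(samples)), samples)
  }
  keys_list <- vector("list", 0L)
  for (ex in unique(experiments)) {
    in_ex <- samples[experiments[samples] == ex]
    if (length(in_ex) < 2L) {
      stop("experiment '", ex, "' has fewer than two biological samples")
    }
    need <- if (rule == "all") length(in_ex) else {
      if (is.null(k)) stop("rule 'at_least_k' needs k")
      if (k > length(in_ex)) {
        stop("k = ", k, " exceeds the ", length(in_ex),
             " samples of experiment '", ex, "'")
      }
      as.integer(k)
    }
    tab <- rbindlist(lapply(in_ex, function(s) {
      unique(per_sample_calls[[s]][, .(contig, pos, ref, alt)])
    }))
    cnt <- tab[, .(n_present = .N), by = .(contig, pos, ref, alt)]
    keys_list[[ex]] <- cnt[n_present >= need, .(contig, pos, ref, alt)]
  }
  unique(rbindlist(keys_list))
}

#' Orient variants to gene strands and restrict to known genes
#'
#' Variants outside annotated genes (CDS/tRNA/rRNA) are dropped; sites in
#' genes are re-expressed on the coding strand, so a forward-strand T>C in a
#' minus-strand gene becomes a coding-strand A>G. Substitution types other
#' than coding-strand A>G are dropped. Sites inside overlapping genes on both
#' strands are ambiguous and dropped with a warning. The 21-base coding-strand
#' context (edited A at the center) and its 7-mer (edited A at position 3)
#' are attached; sites within 10 bases of a contig end are excluded.
#'
#' @param variants `data.table(contig, pos, ref, alt)` keys.
#' @param genome an [annotated_genome()].
#' @return editing-site skeleton `data.table(contig, pos, gene_id,
#'   gene_strand, rna_class, context21, context7)`.
#' @export
orient_and_restrict <- function(variants, genome) {
  if (nrow(variants) == 0L) {
    return(data.table(contig = character(), pos = integer(),
                      gene_id = character(), gene_strand = character(),
                      rna_class = character(), context21 = character(),
                      context7 = character()))
  }
  ann <- .gene_at(variants, genome)
  v <- cbind(copy(variants), ann)
  v <- v[!is.na(gene_strand)]
  v <- v[(gene_strand == "+" & ref == "A" & alt == "G") |
           (gene_strand == "-" & ref == "T" & alt == "C")]
  if (nrow(v) == 0L) {
    return(data.table(contig = character(), pos = integer(),
                      gene_id = character(), gene_strand = character(),
                      rna_class = character(), context21 = character(),
                      context7 = character()))
  }
  glen <- setNames(Biostrings::width(genome$sequences),
                   names(genome$sequences))
  near_end <- v$pos <= 10L | v$pos + 10L > glen[v$contig]
  if (any(near_end)) {
    warning(sum(near_end), " site(s) within 10 bases of a contig end excluded")
    v <- v[!near_end]
  }
  v[, context21 := {
    g <- .contig_str(genome, contig[1])
    ctx <- substring(g, pos - 10L, pos + 10L)
    ifelse(gene_strand == "-", revcomp(ctx), ctx)
  }, by = contig]
  v[, context7 := substr(context21, 9L, 15L)]
  out <- v[, .(contig, pos, gene_id = gene_id_hit, gene_strand,
               rna_class = rna_class_hit, context21, context7)]
  setorder(out, contig, pos)
  out[]
}

#' Remove sites matching DNA-seq variants
#'
#' Excludes putative editing sites whose genomic position and forward-strand
#' alternative allele were also seen as DNA variants (true strain mutations).
#'
#' @param sites editing-site table from [orient_and_restrict()].
#' @param dna_variants `data.table(contig, pos, alt)` of DNA-seq variants
#'   (forward-strand alleles); `NULL` or empty is the identity.
#' @return filtered site table.
#' @export
subtract_dna_variants <- function(sites, dna_variants) {
  if (is.null(dna_variants) || nrow(dna_variants) == 0L) return(sites)
  fwd_alt <- ifelse(sites$gene_strand == "+", "G", "C")
  key <- paste(sites$contig, sites$pos, fwd_alt)
  drop <- key %in% paste(dna_variants$contig, dna_variants$pos,
                         dna_variants$alt)
  sites[!drop]
}

#' Re-extract editing levels for final sites in every sample
#'
#' For each final site and every sample, reports the qualified coverage and
#' G-fraction (percent, on the coding strand) straight from the pileup, with
#' no count or positional-uniqueness thresholds -- this rescues sub-threshold
#' levels (down to below 1%) in samples where the variant was not called.
#' Sites with zero coverage in a sample are recorded as missing (`NA`), not
#' zero.
#'
#' @param sites editing-site table from [orient_and_restrict()].
#' @param pileups named list of `site_pileup`, one per sample.
#' @param stranded logical; count only reads on the transcribed strand.
#' @param floor_pct levels below this are flagged `sub_threshold` (they are
#'   still reported as observed).
#' @return long `data.table(contig, pos, sample_id, coverage, count, level,
#'   sub_threshold)` with `level` in percent.
#' @export
rescue_frequencies <- function(sites, pileups, stranded = FALSE,
                               floor_pct = 1.0) {
  if (nrow(sites) == 0L) {
    return(data.table(contig = character(), pos = integer(),
                      sample_id = character(), coverage = integer(),
                      count = integer(), level = numeric(),
                      sub_threshold = logical()))
  }
  fwd_alt <- ifelse(sites$gene_strand == "+", "G", "C")
  out <- vector("list", length(pileups))
  for (si in seq_along(pileups)) {
    pu <- pileups[[si]]
    key <- sites[, .(contig, pos)]
    posr <- merge(key, pu$positions, by = c("contig", "pos"),
                  all.x = TRUE, sort = FALSE)
    altr <- merge(data.table(contig = sites$contig, pos = sites$pos,
                             base = fwd_alt),
                  pu$alleles, by = c("contig", "pos", "base"),
                  all.x = TRUE, sort = FALSE)
    if (stranded) {
      cov <- ifelse(sites$gene_strand == "+", posr$cov_plus, posr$cov_minus)
      cnt <- ifelse(sites$gene_strand == "+", altr$plus, altr$minus)
    } else {
      cov <- posr$coverage
      cnt <- altr$count
    }
    cnt[is.na(cnt)] <- 0L
    level <- ifelse(is.na(cov) | cov == 0L, NA_real_, 100 * cnt / cov)
    out[[si]] <- data.table(
      contig = sites$contig, pos = sites$pos,
      sample_id = pu$sample_id, coverage = cov, count = cnt,
      level = level,
      sub_threshold = !is.na(level) & level < floor_pct
    )
  }
  rbindlist(out)
}

#' Run the full editing-discovery cascade
#'
#' Per-sample variant calling, post-call filtering, replicate intersection
#' within experiments, gene-strand orientation and restriction to known
#' genes, optional strand-specific filtering and DNA-variant subtraction,
#' and per-sample level rescue -- producing the final editing-site table.
#'
#' @param pileups named list of `site_pileup`, one per sample.
#' @param genome an [annotated_genome()].
#' @param profile a [discovery_profile()].
#' @param experiments named character vector sample -> experiment id;
#'   default: all samples form one experiment.
#' @param dna_variants optional `data.table(contig, pos, alt)`.
#' @param library_stranded logical; the library's actual orientation
#'   (required `TRUE` when the profile enables stranded filtering).
#' @param call_args list of overrides passed to [call_variants()].
#' @return `data.table` of class `editing_sites`: one row per site with
#'   `contig, pos, gene_id, gene_strand, rna_class, context21, context7`,
#'   `mean_level`, and one `level_<sample>` column per sample (percent;
#'   `NA` = not covered). The long rescue table (with coverages and counts)
#'   is attached as attribute `"levels"`.
#' @export
discover_editing <- function(pileups, genome, profile,
                             experiments = NULL, dna_variants = NULL,
                             library_stranded = profile$stranded_filtering,
                             call_args = list()) {
  stopifnot(is(profile, "discovery_profile"))
  samples <- names(pileups)
  if (is.null(samples)) stop("pileups must be a named list (sample ids)")

  calls <- lapply(pileups, function(pu) {
    do.call(call_variants, c(list(pileup = pu), call_args))
  })
  if (profile$stranded_filtering) {
    calls <- lapply(calls, stranded_filter, genome = genome,
                    library_stranded = library_stranded)
  }
  calls <- lapply(calls, filter_variants, profile = profile)

  keys <- intersect_replicates(calls, experiments,
                               rule = profile$replicate_rule,
                               k = profile$replicate_k)
  sites <- orient_and_restrict(keys, genome)
  if (profile$dna_variant_subtraction) {
    sites <- subtract_dna_variants(sites, dna_variants)
  }
  levels_long <- rescue_frequencies(sites, pileups,
                                    stranded = profile$stranded_filtering)
  wide <- if (nrow(sites)) {
    dcast(levels_long, contig + pos ~ sample_id, value.var = "level")
  } else NULL
  out <- copy(sites)
  if (!is.null(wide)) {
    setnames(wide, setdiff(names(wide), c("contig", "pos")),
             paste0("level_", setdiff(names(wide), c("contig", "pos"))))
    out <- merge(out, wide, by = c("contig", "pos"), sort = FALSE)
    lv <- as.matrix(out[, grep("^level_", names(out)), with = FALSE])
    # unweighted mean over non-missing samples
    out[, mean_level := rowMeans(lv, na.rm = TRUE)]
  } else {
    out[, mean_level := numeric(0)]
  }
  setattr(out, "levels", levels_long)
  setattr(out, "class", c("editing_sites", class(out)))
  out[]
}

#' Write the final editing-site table as TSV
#' @param sites `editing_sites` table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_editing_sites <- function(sites, path) {
  out <- copy(as.data.table(sites))
  setnames(out,
           c("contig", "pos", "gene_id", "gene_strand", "rna_class",
             "context21", "context7"),
           c("CHROM", "POS_1based", "GENE", "STRAND", "RNA_CLASS",
             "CONTEXT21", "CONTEXT7"), skip_absent = TRUE)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
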