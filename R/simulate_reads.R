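#' Simulate stranded RNA-seq reads with planted editing and strain SNPs
#'
#' Draws single-end reads uniformly from gene bodies on the transcribed strand
#' (or a random strand if unstranded). Each read overlapping a planted edited
#' adenosine carries G with probability equal to the site's designed level,
#' independently per read (binomial sampling of editing levels). Strain SNPs
#' (coding-strand A>G at non-edited gene positions) are substituted into every
#' read (~100% allele frequency). Sequencing errors are applied after editing.
#' Replicates differ only by their derived RNG stream.
#'
#' @param genome planted [annotated_genome()] (output of
#'   [plant_editing_sites()]).
#' @param truth truth `data.table` from [plant_editing_sites()].
#' @param config a [sim_config()].
#' @param outdir optional directory; if given, one FASTQ per replicate plus
#'   `truth.tsv` are written there.
#' @return an object of class `sim_reads`: list with `replicates` (list of
#'   `data.table(id, seq, qual)`), `truth`, `snps` (`data.table` of planted
#'   strain SNPs: contig, pos, ref, alt on the forward strand), and `config`.
#' @export
simulate_reads <- function(genome, truth, config, outdir = NULL) {
  validate_sim_config(config)
  contig <- names(genome$sequences)[1]
  seqstr <- .contig_str(genome, contig)
  feats <- genome$features
  genes <- data.table(
    gene_id = feats$gene_id, type = feats$type,
    start = GenomicRanges::start(feats), end = GenomicRanges::end(feats),
    strand = as.character(GenomicRanges::strand(feats))
  )

  # strain SNPs: coding-strand A at in-gene positions away from edit sites,
  # substituted A>G in the strain genome used for read generation
  set.seed(.child_seed(config$seed, 3L))
  snps <- data.table(contig = character(), pos = integer(),
                     ref = character(), alt = character())
  strain <- seqstr
  if (config$n_strain_snps > 0L) {
    chars <- strsplit(seqstr, "")[[1]]
    cand <- integer(0)
    cand_strand <- character(0)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i]
      idx <- g$start:g$end
      want <- if (g$strand == "+") "A" else "T"   # coding-strand A
      hit <- idx[chars[idx] == want]
      cand <- c(cand, hit)
      cand_strand <- c(cand_strand, rep(g$strand, length(hit)))
    }
    far <- !(cand %in% unlist(lapply(truth$pos, function(p) (p - 10L):(p + 10L))))
    cand <- cand[far]; cand_strand <- cand_strand[far]
    pick <- sample(length(cand), min(config$n_strain_snps, length(cand)))
    for (j in pick) {
      p <- cand[j]
      old <- substr(strain, p, p)
      new <- if (cand_strand[j] == "+") "G" else "C"
      substr(strain, p, p) <- new
      snps <- rbind(snps, data.table(contig = contig, pos = p,
                                     ref = old, alt = new))
    }
    setorder(snps, pos)
  }

  rl <- config$read_length
  qual_str <- .quality_string(config$base_quality, rl)
  reps <- vector("list", config$n_replicates)

  for (r in seq_len(config$n_replicates)) {
    set.seed(.child_seed(config$seed, 100L + r))
    per_gene <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i]
      glen <- g$end - g$start + 1L
      if (glen < rl) return(NULL)
      n_reads <- max(1L, round(config$mean_coverage * glen / rl))
      starts <- g$start + sample.int(glen - rl + 1L, n_reads,
                                     replace = TRUE) - 1L
      data.table(gene_id = g$gene_id, gstrand = g$strand,
                 start = starts, end = starts + rl - 1L)
    })
    rd <- rbindlist(per_gene)
    rd[, seq := substring(strain, start, end)]

    # per-read independent editing at overlapped truth sites
    for (k in seq_len(nrow(truth))) {
      tp <- truth$pos[k]
      hit <- which(rd$start <= tp & rd$end >= tp)
      if (!length(hit)) next
      edited <- hit[runif(length(hit)) < truth$designed_level[k]]
      if (!length(edited)) next
      # forward-strand base at the site: A for + genes, T for - genes
      sub <- if (truth$gene_strand[k] == "+") "G" else "C"
      off <- tp - rd$start[edited] + 1L
      s <- rd$seq[edited]
      for (m in seq_along(edited)) {
        substr(s[m], off[m], off[m]) <- sub
      }
      rd[edited, seq := s]
    }

    # orient to the transcribed strand
    if (config$stranded) {
      flip <- rd$gstrand == "-"
    } else {
      flip <- runif(nrow(rd)) < 0.5
    }
    if (any(flip)) rd[flip, seq := revcomp(seq)]

    # sequencing errors after editing
    n_bases <- nrow(rd) * rl
    n_err <- rbinom(1L, n_bases, config$error_rate)
    if (n_err > 0L) {
      at <- sample.int(n_bases, n_err)
      ri <- (at - 1L) %/% rl + 1L
      pi <- (at - 1L) %% rl + 1L
      for (m in seq_len(n_err)) {
        cur <- substr(rd$seq[ri[m]], pi[m], pi[m])
        s <- rd$seq[ri[m]]
        substr(s, pi[m], pi[m]) <- sample(setdiff(DNA_BASES, cur), 1L)
        rd[ri[m], seq := s]
      }
    }

    rd[, id := sprintf("rep%d_read%06d_%s", r, .I, gene_id)]
    reps[[r]] <- rd[, .(id, seq, qual = qual_str)]
  }

  out <- structure(list(replicates = reps, truth = truth, snps = snps,
                        config = config),
                   class = "sim_reads")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_along(reps)) {
      write_fastq(reps[[r]], file.path(outdir, sprintf("rep%d.fastq", r)))
    }
    write_truth(truth, file.path(outdir, "truth.tsv"))
  }
  out
}

# constant-quality string, optionally with a low-quality 3' tail
.quality_string <- function(base_quality, read_length) {
  if (is.list(base_quality)) {
    q <- rep(base_quality$q, read_length)
    tl <- min(base_quality$tail_length, read_length)
    if (tl > 0L) q[(read_length - tl + 1L):read_length] <- base_quality$tail_q
    int_to_phred(q)
  } else {
    int_to_phred(rep(base_quality, read_length))
  }
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", length(x$replicates), "replicate(s),",
      nrow(x$replicates[[1]]), "reads each,", nrow(x$truth),
      "planted sites,", nrow(x$snps), "strain SNPs\n")
  invisible(x)
}
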