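# coding-strand coordinate (1-based within gene) -> forward-strand genome pos
.coding_to_fwd <- function(gstart, gend, gstrand, p) {
  if (gstrand == "+") gstart + p - 1L else gend - p + 1L
}

# write a coding-strand segment (coding positions a..b of a gene) into the
# forward genome character string
.write_coding_segment <- function(seqstr, gstart, gend, gstrand, a, b, seg) {
  stopifnot(nchar(seg) == b - a + 1L)
  if (gstrand == "+") {
    substr(seqstr, gstart + a - 1L, gstart + b - 1L) <- seg
  } else {
    substr(seqstr, gend - b + 1L, gend - a + 1L) <- revcomp(seg)
  }
  seqstr
}

# extract the coding-strand sequence of a gene from the forward genome string
.coding_seq <- function(seqstr, gstart, gend, gstrand) {
  s <- substr(seqstr, gstart, gend)
  if (gstrand == "-") revcomp(s) else s
}

# TRUE if an ORF (coding strand) has an internal in-frame stop or lost start
.orf_broken <- function(orf) {
  n <- nchar(orf)
  if (substr(orf, 1L, 3L) != "ATG") return(TRUE)
  body <- substring(orf, seq(4L, n - 3L, by = 3L), seq(6L, n, by = 3L))
  any(head(body, -1L) %in% c("TAA", "TAG", "TGA"))
}

#' Plant editing sites into a synthetic genome
#'
#' Rewrites the local coding-strand sequence at each chosen in-CDS position to
#' the seven-base editing motif `YTACGAA` (edited A at motif position 3) and,
#' for hairpin sites, rewrites the 3' flank of the 17-nt anticodon-arm-sized
#' window to the reverse complement of the 5' flank so the motif sits in the
#' loop of a stem-loop. Placements that would introduce an internal stop codon
#' are retried elsewhere; gene reading frames are never broken. Minus-strand
#' genes receive the reverse complement on the forward strand.
#'
#' @param genome an [annotated_genome()] from [generate_genome()].
#' @param config a [sim_config()].
#' @return list with elements `genome` (modified [annotated_genome()]) and
#'   `truth`, a `data.table` of planted-site truth records: `contig`, `pos`
#'   (1-based forward-strand coordinate of the edited A), `gene_id`,
#'   `gene_strand`, `designed_level` (fraction), `context7` (coding strand),
#'   `in_hairpin`.
#' @export
plant_editing_sites <- function(genome, config) {
  validate_sim_config(config)
  set.seed(.child_seed(config$seed, 2L))
  n <- config$n_edit_sites
  stem <- config$hairpin_stem_length
  # keep motif, window and stem inside the gene, and stay a full read length
  # from the gene termini so the configured mean coverage holds at the site
  # (reads are drawn entirely within gene bodies)
  margin <- max(13L + stem + 5L, config$read_length)

  feats <- genome$features
  cds <- feats[feats$type == "CDS"]
  ok_genes <- which(GenomicRanges::width(cds) >= 2L * margin + 7L)
  if (n > 0L && length(ok_genes) == 0L) stop("no CDS long enough for planting")

  contig <- names(genome$sequences)[1]
  seqstr <- .contig_str(genome, contig)

  levels <- if (length(config$level_distribution) == 2L) {
    runif(n, config$level_distribution[1], config$level_distribution[2])
  } else {
    sample(config$level_distribution, n, replace = TRUE)
  }
  hairpin <- runif(n) < config$hairpin_fraction

  truth <- vector("list", n)
  used <- list()  # per gene: planted coding positions
  tries <- 0L
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > 200L * max(n, 1L)) {
      stop("placement failure: could not plant sites without premature stops")
    }
    gi <- ok_genes[sample.int(length(ok_genes), 1L)]
    g <- cds[gi]
    gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
    gstrand <- as.character(GenomicRanges::strand(g))
    glen <- ge - gs + 1L
    # coding position of the edited A
    p <- margin + sample.int(glen - 2L * margin + 1L, 1L) - 1L
    prev <- used[[g$gene_id]]
    if (!is.null(prev) && any(abs(prev - p) < 45L)) next

    y <- sample(c("C", "T"), 1L)
    motif <- paste0(y, "TACGAA")               # coding positions p-2 .. p+4
    cand <- .write_coding_segment(seqstr, gs, ge, gstrand, p - 2L, p + 4L, motif)
    if (hairpin[i]) {
      # 17-nt window at offset 0: coding positions p-7 .. p+9; the 7-mer
      # occupies window positions 6..12; pair window 1..stem with the 3' end
      win_start <- p - 7L
      five <- substr(.coding_seq(cand, gs, ge, gstrand),
                     win_start, win_start + stem - 1L)
      cand <- .write_coding_segment(cand, gs, ge, gstrand,
                                    p + 10L - stem, p + 9L, revcomp(five))
    }
    orf <- .coding_seq(cand, gs, ge, gstrand)
    if (.orf_broken(orf)) next

    seqstr <- cand
    used[[g$gene_id]] <- c(prev, p)
    truth[[i]] <- data.table(
      contig = contig,
      pos = .coding_to_fwd(gs, ge, gstrand, p),
      gene_id = g$gene_id, gene_strand = gstrand,
      designed_level = levels[i],
      context7 = motif, in_hairpin = hairpin[i]
    )
    i <- i + 1L
  }

  newseq <- Biostrings::DNAStringSet(seqstr)
  names(newseq) <- contig
  out_truth <- if (n) rbindlist(truth) else data.table(
    contig = character(), pos = integer(), gene_id = character(),
    gene_strand = character(), designed_level = numeric(),
    context7 = character(), in_hairpin = logical()
  )
  setorder(out_truth, pos)
  list(genome = annotated_genome(newseq, genome$features), truth = out_truth)
}

#' Write a planted-site truth table to TSV
#' @param truth truth `data.table` from [plant_editing_sites()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  out <- data.table(
    contig = truth$contig, pos_1based = truth$pos,
    strand = truth$gene_strand, gene_id = truth$gene_id,
    level = truth$designed_level, context7 = truth$context7,
    in_hairpin = truth$in_hairpin
  )
  fwrite(out, path, sep = "\t")
  invisible(path)
}
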