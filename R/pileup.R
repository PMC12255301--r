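#' Build a quality-filtered site pileup
#'
#' A read base contributes to a position only if its own quality is at least
#' `min_central_quality` and every base within `neighborhood_radius` of it on
#' the same read has quality at least `min_neighborhood_quality`; the
#' neighborhood is truncated at read boundaries. Coverage counts contributing
#' bases only. Per allele, the number of distinct supporting alignment start
#' and end coordinates is recorded (positional-artifact filter), as are
#' per-strand counts for stranded libraries.
#'
#' @param alignments alignment table from [map_reads()] or [read_sam()].
#' @param genome an [annotated_genome()] (for reference bases).
#' @param neighborhood_radius bases each side of the central base.
#' @param min_central_quality,min_neighborhood_quality Phred thresholds.
#' @param sample_id sample label carried into downstream tables.
#' @return an object of class `site_pileup`: list with `alleles`
#'   (`data.table(contig, pos, base, count, ustarts, uends, plus, minus)`),
#'   `positions` (`data.table(contig, pos, ref, coverage, cov_plus,
#'   cov_minus)`), and `sample_id`.
#' @export
build_pileup <- function(alignments, genome, neighborhood_radius = 2L,
                         min_central_quality = 30L,
                         min_neighborhood_quality = 30L,
                         sample_id = "sample") {
  unknown <- setdiff(unique(alignments$contig), names(genome$sequences))
  if (length(unknown)) {
    stop("alignment references unknown contig(s): ",
         paste(unknown, collapse = ", "))
  }
  empty_alleles <- data.table(contig = character(), pos = integer(),
                              base = character(), count = integer(),
                              ustarts = integer(), uends = integer(),
                              plus = integer(), minus = integer())
  empty_pos <- data.table(contig = character(), pos = integer(),
                          ref = character(), coverage = integer(),
                          cov_plus = integer(), cov_minus = integer())
  if (nrow(alignments) == 0L) {
    return(structure(list(alleles = empty_alleles, positions = empty_pos,
                          sample_id = sample_id), class = "site_pileup"))
  }

  lens <- nchar(alignments$seq)
  dt <- data.table(
    aid = rep(seq_len(nrow(alignments)), lens),
    contig = rep(alignments$contig, lens),
    pos = sequence(lens) + rep(alignments$start, lens) - 1L,
    base = unlist(strsplit(alignments$seq, "", fixed = TRUE)),
    qual = as.numeric(unlist(lapply(alignments$qual,
                                    function(s) utf8ToInt(s) - 33L))),
    start = rep(alignments$start, lens),
    end = rep(alignments$end, lens),
    strand = rep(alignments$strand, lens)
  )

  # neighborhood minimum quality, truncated at read boundaries: rows of one
  # alignment are contiguous, so shifted neighbours crossing a boundary are
  # masked to +Inf
  nmin <- rep(Inf, nrow(dt))
  r <- as.integer(neighborhood_radius)
  if (r > 0L) {
    for (d in c(-seq_len(r), seq_len(r))) {
      type <- if (d > 0L) "lead" else "lag"
      v <- shift(dt$qual, abs(d), fill = Inf, type = type)
      same <- shift(dt$aid, abs(d), fill = -1L, type = type) == dt$aid
      v[!same] <- Inf
      nmin <- pmin(nmin, v)
    }
  }
  dt[, nmin := nmin]

  ok <- dt[base %chin% DNA_BASES & qual >= min_central_quality &
             nmin >= min_neighborhood_quality]
  if (nrow(ok) == 0L) {
    return(structure(list(alleles = empty_alleles, positions = empty_pos,
                          sample_id = sample_id), class = "site_pileup"))
  }

  alleles <- ok[, .(count = .N, ustarts = uniqueN(start),
                    uends = uniqueN(end), plus = sum(strand == "+"),
                    minus = sum(strand == "-")),
                by = .(contig, pos, base)]
  positions <- alleles[, .(coverage = sum(count), cov_plus = sum(plus),
                           cov_minus = sum(minus)), by = .(contig, pos)]
  # reference base per position
  positions[, ref := {
    g <- .contig_str(genome, contig[1])
    substring(g, pos, pos)
  }, by = contig]
  setcolorder(positions, c("contig", "pos", "ref", "coverage",
                           "cov_plus", "cov_minus"))
  setorder(alleles, contig, pos, base)
  setorder(positions, contig, pos)
  structure(list(alleles = alleles, positions = positions,
                 sample_id = sample_id), class = "site_pileup")
}

#' @export
print.site_pileup <- function(x, ...) {
  cat("site_pileup '", x$sample_id, "': ", nrow(x$positions),
      " positions, ", nrow(x$alleles), " allele records\n", sep = "")
  invisible(x)
}
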