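#' Write reads to FASTQ (Phred+33)
#' @param reads `data.table` with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  dss <- Biostrings::DNAStringSet(reads$seq)
  names(dss) <- reads$id
  qs <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qs)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ path.
#' @return `data.table(id, seq, qual)`.
#' @export
read_fastq <- function(path) {
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e))
  )
  data.table(id = names(dss), seq = as.character(dss),
             qual = as.character(S4Vectors::mcols(dss)$qualities))
}

#' Ingest alignments from a SAM file
#'
#' Pass-through for externally aligned reads. The SAM text (header required)
#' is converted and scanned via Rsamtools; each record's SEQ/QUAL are
#' projected onto the reference through its CIGAR (insertions and clips
#' dropped, deletions padded with `-` at quality -1 so they contribute no
#' alleles), yielding the same alignment table the built-in mapper produces.
#'
#' @param path SAM file path.
#' @return alignment `data.table(read_id, contig, start, end, strand, seq,
#'   qual, aligned_fraction, identity)` with `seq`/`qual` in reference
#'   orientation and reference coordinates 1-based inclusive.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos) & bitwAnd(x$flag, 4L) == 0L
  n <- sum(keep)
  if (n == 0L) {
    return(data.table(read_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      seq = character(), qual = character(),
                      aligned_fraction = numeric(), identity = numeric()))
  }
  qname <- x$qname[keep]; flag <- x$flag[keep]
  rname <- as.character(x$rname[keep]); pos <- x$pos[keep]
  cigar <- x$cigar[keep]
  seqs <- as.character(x$seq)[keep]
  quals <- as.character(x$qual)[keep]

  out <- vector("list", n)
  for (i in seq_len(n)) {
    proj <- .project_cigar(seqs[i], quals[i], cigar[i])
    rlen <- nchar(seqs[i])
    out[[i]] <- data.table(
      read_id = qname[i], contig = rname[i],
      start = pos[i], end = pos[i] + nchar(proj$seq) - 1L,
      strand = if (bitwAnd(flag[i], 16L) != 0L) "-" else "+",
      seq = proj$seq, qual = proj$qual,
      aligned_fraction = proj$aligned / rlen, identity = NA_real_
    )
  }
  rbindlist(out)
}

# project read SEQ/QUAL onto the reference via CIGAR; '-'/qual 0 for deletions
.project_cigar <- function(seq, qual, cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  kind <- sub("^[0-9]+", "", toks)
  rs <- character(0); rq <- character(0)
  qpos <- 1L; aligned <- 0L
  for (j in seq_along(toks)) {
    l <- lens[j]
    switch(kind[j],
      "M" = , "=" = , "X" = {
        rs <- c(rs, substr(seq, qpos, qpos + l - 1L))
        rq <- c(rq, substr(qual, qpos, qpos + l - 1L))
        qpos <- qpos + l; aligned <- aligned + l
      },
      "I" = , "S" = { qpos <- qpos + l },
      "D" = , "N" = {
        rs <- c(rs, strrep("-", l))
        rq <- c(rq, strrep("!", l))   # Phred 0: never passes quality filters
      },
      "H" = , "P" = NULL
    )
  }
  list(seq = paste(rs, collapse = ""), qual = paste(rq, collapse = ""),
       aligned = aligned)
}

#' Write an alignment table to SAM
#'
#' Minimal SAM export for the built-in (ungapped) mapper so its output can be
#' round-tripped through [read_sam()] or external tools.
#'
#' @param alignments alignment `data.table` from [map_reads()].
#' @param genome [annotated_genome()] supplying the header.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(alignments, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(genome$sequences)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome$sequences)[i],
                       Biostrings::width(genome$sequences)[i]), con)
  }
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       alignments$read_id, flag, alignments$contig,
                       alignments$start, nchar(alignments$seq),
                       alignments$seq, alignments$qual), con)
  }
  invisible(path)
}
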