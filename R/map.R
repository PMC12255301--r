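#' Map reads to a reference with the built-in ungapped mapper
#'
#' Exact k-mer seeding with full ungapped extension, counting mismatches.
#' Candidate placements come from seed hits at several offsets along the read
#' (both orientations); each candidate is scored as the number of matching
#' bases over the full read. Reported alignments must cover the whole read
#' (`aligned_fraction` 1 by construction, satisfying the length-fraction
#' bound) and reach `identity >= similarity_fraction`. Reads with two or more
#' equal-best placements are discarded entirely (nonspecific match handling:
#' ignore). Gapped alignments enter the pipeline only via [read_sam()].
#'
#' @param reads `data.table(id, seq, qual)`.
#' @param genome an [annotated_genome()].
#' @param length_fraction minimum aligned fraction of the read (default 0.95;
#'   the built-in mapper only emits full-length placements).
#' @param similarity_fraction minimum identity over aligned columns.
#' @param k seed k-mer length.
#' @return alignment `data.table(read_id, contig, start, end, strand, seq,
#'   qual, aligned_fraction, identity)`; `seq`/`qual` oriented to the
#'   reference strand, coordinates 1-based inclusive.
#' @export
map_reads <- function(reads, genome, length_fraction = 0.95,
                      similarity_fraction = 0.95, k = 18L) {
  if (sum(Biostrings::width(genome$sequences)) == 0L) stop("empty genome")
  empty <- data.table(read_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      seq = character(), qual = character(),
                      aligned_fraction = numeric(), identity = numeric())
  if (nrow(reads) == 0L) return(empty)

  # genome k-mer index (forward strand, all contigs)
  idx <- rbindlist(lapply(names(genome$sequences), function(cn) {
    g <- .contig_str(genome, cn)
    L <- nchar(g)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.table(kmer = substring(g, starts, starts + k - 1L),
               contig = cn, gpos = starts)
  }))
  setkey(idx, kmer)
  gstr <- setNames(lapply(names(genome$sequences), .contig_str,
                          genome = genome), names(genome$sequences))
  glen <- vapply(gstr, nchar, 1L)

  rlen <- nchar(reads$seq)
  fwd <- reads$seq
  rc <- revcomp(reads$seq)

  # seed queries: up to three offsets per read and orientation
  q <- rbindlist(lapply(c("+", "-"), function(st) {
    rs <- if (st == "+") fwd else rc
    rbindlist(lapply(1:3, function(j) {
      off <- switch(j, rep(1L, length(rlen)), pmax(1L, rlen %/% 2L),
                    pmax(1L, rlen - k + 1L))
      data.table(ri = seq_along(rs), strand = st, off = off,
                 kmer = substring(rs, off, off + k - 1L))
    }))
  }))
  q <- q[nchar(kmer) == k & off + k - 1L <= rlen[ri]]
  if (nrow(q) == 0L) return(empty)

  hit <- idx[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hit) == 0L) return(empty)
  cand <- unique(hit[, .(ri, strand, contig,
                         start = gpos - off + 1L)])
  cand <- cand[start >= 1L & start + rlen[ri] - 1L <= glen[contig]]
  if (nrow(cand) == 0L) return(empty)

  # full ungapped extension: mismatches over the whole read
  rseq <- ifelse(cand$strand == "+", fwd[cand$ri], rc[cand$ri])
  refseq <- substring(unlist(gstr[cand$contig], use.names = FALSE),
                      cand$start, cand$start + rlen[cand$ri] - 1L)
  cand[, identity := (rlen[ri] - mapply(.str_mismatches, refseq, rseq,
                                        USE.NAMES = FALSE)) / rlen[ri]]
  cand[, rseq := rseq]

  # best placement per read; ties at the best score are discarded
  cand <- cand[identity >= similarity_fraction]
  if (nrow(cand) == 0L) return(empty)
  cand[, best := max(identity), by = ri]
  top <- cand[identity == best]
  nbest <- top[, .N, by = ri]
  top <- top[ri %in% nbest[N == 1L, ri]]
  if (nrow(top) == 0L) return(empty)

  rcq <- vapply(reads$qual[top$ri],
                function(s) intToUtf8(rev(utf8ToInt(s))), "",
                USE.NAMES = FALSE)
  data.table(
    read_id = reads$id[top$ri], contig = top$contig,
    start = top$start, end = top$start + rlen[top$ri] - 1L,
    strand = top$strand, seq = top$rseq,
    qual = ifelse(top$strand == "+", reads$qual[top$ri], rcq),
    aligned_fraction = 1.0, identity = top$identity
  )
}

#' Per-sample mapping-rate QC
#'
#' Samples where fewer than `min_mapped_fraction` of input reads map to their
#' genome are excluded from all downstream stages. The bound is inclusive
#' (`>=`), consistent with the inclusive semantics of every other threshold
#' in the pipeline.
#'
#' @param alignments alignment table for the sample.
#' @param n_input_reads number of reads that entered mapping.
#' @param min_mapped_fraction minimum mapped fraction (default 0.5).
#' @return list with `pass` (logical) and `mapped_fraction`.
#' @export
sample_qc <- function(alignments, n_input_reads, min_mapped_fraction = 0.5) {
  stopifnot(n_input_reads > 0)
  frac <- length(unique(alignments$read_id)) / n_input_reads
  list(pass = frac >= min_mapped_fraction, mapped_fraction = frac)
}
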