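#' Quality-trim reads (modified-Mott, error-probability limit)
#'
#' Realizes an error-probability-limit trimmer: per base the error probability
#' is `p_i = 10^(-Q_i/10)`; the retained segment is the contiguous subsegment
#' maximizing `sum(quality_limit - p_i)`, i.e. the maximal-scoring run under
#' the limit. Flanking ambiguous bases are then trimmed. Reads are dropped if
#' the retained segment contains more than `max_ambiguous` N's or is shorter
#' than `min_length`.
#'
#' @param reads `data.table(id, seq, qual)` with Phred+33 qualities.
#' @param quality_limit error-probability limit (default 0.05).
#' @param max_ambiguous maximum N's tolerated in the retained segment.
#' @param min_length minimum retained length.
#' @return trimmed `data.table(id, seq, qual)`; dropped reads removed.
#' @export
trim_reads <- function(reads, quality_limit = 0.05, max_ambiguous = 2L,
                       min_length = 50L) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  n <- nrow(reads)
  if (n == 0L) return(reads)
  keep <- logical(n)
  seq_out <- character(n)
  qual_out <- character(n)
  for (i in seq_len(n)) {
    q <- utf8ToInt(reads$qual[i]) - 33L
    s <- quality_limit - 10^(-q / 10)
    cs <- cumsum(s)
    pre <- cummin(c(0, cs[-length(cs)]))      # best prefix min before j
    gain <- cs - pre
    j <- which.max(gain)
    if (gain[j] <= 0) next                     # nothing above the limit
    i0 <- which.min(c(0, cs)[seq_len(j)])      # segment starts after the min
    a <- i0; b <- j
    sseq <- substr(reads$seq[i], a, b)
    # trim flanking ambiguous bases
    m <- regmatches(sseq, regexpr("^N+", sseq))
    if (length(m)) { a <- a + nchar(m); sseq <- substr(reads$seq[i], a, b) }
    m <- regmatches(sseq, regexpr("N+$", sseq))
    if (length(m)) { b <- b - nchar(m); sseq <- substr(reads$seq[i], a, b) }
    if (b - a + 1L < min_length) next
    if (lengths(regmatches(sseq, gregexpr("N", sseq, fixed = TRUE))) >
        max_ambiguous) next
    keep[i] <- TRUE
    seq_out[i] <- sseq
    qual_out[i] <- substr(reads$qual[i], a, b)
  }
  data.table(id = reads$id[keep], seq = seq_out[keep], qual = qual_out[keep])
}
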