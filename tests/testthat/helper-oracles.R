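# Independent oracles: deliberately brute-force implementations kept free of
# the package's own code paths.

# exhaustive ungapped placement scan over all (position, strand) pairs
oracle_map <- function(read_seq, genome_str, min_identity = 0.95) {
  n <- nchar(read_seq)
  L <- nchar(genome_str)
  hits <- list()
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") read_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(read_seq)))
    for (s in seq_len(L - n + 1L)) {
      ref <- substr(genome_str, s, s + n - 1L)
      mm <- sum(strsplit(ref, "")[[1]] != strsplit(rs, "")[[1]])
      ident <- (n - mm) / n
      if (ident >= min_identity) {
        hits[[length(hits) + 1L]] <- list(start = s, strand = strand,
                                          identity = ident)
      }
    }
  }
  if (!length(hits)) return(NULL)
  idents <- vapply(hits, `[[`, 0.0, "identity")
  best <- max(idents)
  top <- hits[idents == best]
  if (length(top) >= 2L) return(NULL)   # nonspecific: ignore
  top[[1]]
}

# position-by-position recount of qualified bases over an alignment table
oracle_pileup_counts <- function(alignments, radius = 2L, minc = 30L,
                                 minn = 30L) {
  rows <- list()
  for (i in seq_len(nrow(alignments))) {
    bases <- strsplit(alignments$seq[i], "")[[1]]
    quals <- utf8ToInt(alignments$qual[i]) - 33L
    n <- length(bases)
    for (j in seq_len(n)) {
      lo <- max(1L, j - radius); hi <- min(n, j + radius)
      if (quals[j] >= minc && all(quals[lo:hi] >= minn) &&
          bases[j] %in% c("A", "C", "G", "T")) {
        rows[[length(rows) + 1L]] <- data.frame(
          pos = alignments$start[i] + j - 1L, base = bases[j])
      }
    }
  }
  if (!length(rows)) return(data.frame(pos = integer(), base = character(),
                                       count = integer()))
  df <- do.call(rbind, rows)
  agg <- aggregate(rep(1L, nrow(df)), by = list(pos = df$pos, base = df$base),
                   FUN = sum)
  names(agg)[3] <- "count"
  agg[order(agg$pos, agg$base), ]
}

# BH step-up definition evaluated literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Welch statistic from the textbook formula
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# pooled-variance Student statistic from the textbook formula
oracle_student <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# per-position Hamming distance to YTACGAA, plain loop
oracle_hamming7 <- function(s) {
  cons <- c("CT", "T", "A", "C", "G", "A", "A")
  d <- 0L
  for (j in 1:7) {
    if (!grepl(substr(s, j, j), cons[j], fixed = TRUE)) d <- d + 1L
  }
  d
}

# maximum nested base pairs by exhaustive recursion (min loop 3)
oracle_max_pairs <- function(seq) {
  s <- strsplit(chartr("T", "U", seq), "")[[1]]
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - 4L)) {
      if (pairable(s[k], s[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, left + rec(k + 1L, j - 1L) + 1L)
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, length(s))
}

# all forward/reverse occurrences of YTACGAA anchored at the edited A,
# by sliding-window character comparison (regex-free)
oracle_motif_scan <- function(genome_str) {
  chars <- strsplit(genome_str, "")[[1]]
  L <- length(chars)
  match_at <- function(i, pat) {
    for (j in seq_along(pat)) {
      if (!grepl(chars[i + j - 1L], pat[j], fixed = TRUE)) return(FALSE)
    }
    TRUE
  }
  fwd_pat <- c("CT", "T", "A", "C", "G", "A", "A")
  rev_pat <- c("T", "T", "C", "G", "T", "A", "AG")  # revcomp(YTACGAA)
  out <- list()
  for (i in seq_len(L - 6L)) {
    if (match_at(i, fwd_pat)) {
      out[[length(out) + 1L]] <- data.frame(pos = i + 2L, strand = "+")
    }
    if (match_at(i, rev_pat)) {
      out[[length(out) + 1L]] <- data.frame(pos = i + 4L, strand = "-")
    }
  }
  if (!length(out)) return(data.frame(pos = integer(), strand = character()))
  do.call(rbind, out)
}
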