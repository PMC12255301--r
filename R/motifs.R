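ALL_XAYZ <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b,
                  function(xy, z) paste0(substr(xy, 1, 1), "A",
                                         substr(xy, 2, 2), z)))
}

#' Observed 4-mer motif counts around editing sites
#'
#' For each site the 4-mer is the coding-strand sequence at offsets
#' (-1, A, +1, +2) relative to the edited adenosine, i.e. characters 10--13
#' of the 21-base context. Counts are tabulated over the 64 categories
#' `X A Y Z` (adenosine fixed at the second position).
#'
#' @param sites editing-site table with a `context21` column (or a character
#'   vector of 21-base contexts).
#' @return named integer vector of length 64 (all `XAYZ` categories).
#' @export
count_observed_motifs <- function(sites) {
  ctx <- if (is.character(sites)) sites else sites$context21
  stopifnot(all(nchar(ctx) == 21L), all(substr(ctx, 11L, 11L) == "A"))
  four <- substr(ctx, 10L, 13L)
  tab <- table(factor(four, levels = ALL_XAYZ))
  setNames(as.integer(tab), ALL_XAYZ)
}

#' Expected 4-mer counts from a genome-sampled null
#'
#' Per species, the frequency of each `X A Y Z` 4-mer (adenosine at the
#' second position) over both strands of the genome is computed; expected
#' counts are the species' frequencies weighted by its number of sites, so
#' the expected total equals the observed total.
#'
#' @param genomes named list of [annotated_genome()] (one per species).
#' @param per_species_site_counts named integer vector of site counts; names
#'   must match `genomes`.
#' @return named numeric vector of length 64 summing to `sum(counts)`.
#' @export
genomic_motif_null <- function(genomes, per_species_site_counts) {
  sp <- names(per_species_site_counts)
  missing_g <- setdiff(sp, names(genomes))
  if (length(missing_g)) {
    stop("species with sites but no genome: ", paste(missing_g, collapse = ", "))
  }
  expected <- setNames(numeric(64L), ALL_XAYZ)
  for (s in sp) {
    seqs <- genomes[[s]]$sequences
    both <- c(seqs, Biostrings::reverseComplement(seqs))
    cnt <- colSums(Biostrings::oligonucleotideFrequency(both, width = 4L))
    cnt <- cnt[ALL_XAYZ]
    freq <- cnt / sum(cnt)
    expected <- expected + per_species_site_counts[[s]] * freq
  }
  expected
}

#' Chi-square goodness-of-fit test
#'
#' `statistic = sum((O - E)^2 / E)` with `df = categories - 1` and an
#' upper-tail p-value. Categories with expected count below 1 are pooled
#' into a rest class (df reduced accordingly) to keep the statistic stable;
#' whole-genome motif nulls never trigger the pooling.
#'
#' @param observed,expected same-length numeric vectors over identical
#'   categories; `sum(expected)` is rescaled to `sum(observed)`.
#' @return list with `statistic`, `df`, `p`, and `n_categories` (after
#'   pooling).
#' @export
chi_square_gof <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  expected <- expected * sum(observed) / sum(expected)
  pool <- expected < 1
  if (any(pool)) {
    observed <- c(observed[!pool], sum(observed[pool]))
    expected <- c(expected[!pool], sum(expected[pool]))
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE),
       n_categories = length(observed))
}

#' Classify a 7-mer against the YTACGAA consensus
#'
#' Hamming distance to the consensus `YTACGAA` (Y matches C or T), with the
#' offsets of mismatching positions. Distance bins 0 / 1 / >=2 are the ones
#' used in summaries.
#'
#' @param context7 character vector of 7-mers (ACGT only).
#' @return `data.table(context7, hamming, mismatch_offsets)` where
#'   `mismatch_offsets` is a list column of 1-based positions.
#' @export
classify_seven_mer <- function(context7) {
  stopifnot(all(nchar(context7) == 7L))
  if (any(grepl("[^ACGT]", context7))) {
    stop("non-ACGT character in 7-mer context")
  }
  cons <- c("Y", "T", "A", "C", "G", "A", "A")
  m <- do.call(rbind, strsplit(context7, "", fixed = TRUE))
  mis <- matrix(FALSE, nrow(m), 7L)
  for (j in 1:7) {
    mis[, j] <- if (cons[j] == "Y") !(m[, j] %in% c("C", "T"))
                else m[, j] != cons[j]
  }
  data.table(
    context7 = context7,
    hamming = as.integer(rowSums(mis)),
    mismatch_offsets = lapply(seq_len(nrow(mis)), function(i) which(mis[i, ]))
  )
}

#' Position frequency matrix and information content of 21-base contexts
#'
#' Column-stochastic base frequencies per position, and per-position
#' information content in bits with the small-sample correction
#' `IC_i = 2 - H_i - e_n`, `e_n = 3 / (2 ln(2) n)` -- the quantities a
#' sequence-logo renderer consumes.
#'
#' @param contexts21 character vector of 21-base coding-strand contexts
#'   (edited A at the center, reported as position 0).
#' @return list with `pfm` (4 x 21 matrix, columns sum to 1), `ic` (length
#'   21, names -10..10), and `n`.
#' @export
position_frequency_matrix <- function(contexts21) {
  if (length(unique(nchar(contexts21))) != 1L) {
    stop("contexts have heterogeneous lengths")
  }
  w <- nchar(contexts21[1])
  dss <- Biostrings::DNAStringSet(contexts21)
  cm <- Biostrings::consensusMatrix(dss, baseOnly = TRUE)[DNA_BASES, ,
                                                          drop = FALSE]
  n <- length(contexts21)
  pfm <- sweep(cm, 2, colSums(cm), "/")
  h <- apply(pfm, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  en <- 3 / (2 * log(2) * n)
  ic <- 2 - h - en
  names(ic) <- colnames(pfm) <- seq_len(w) - (w + 1L) %/% 2L
  list(pfm = pfm, ic = ic, n = n)
}

#' Write motif summary tables
#' @param observed,expected length-64 vectors from [count_observed_motifs()]
#'   and [genomic_motif_null()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_motif_counts <- function(observed, expected, path) {
  fwrite(data.table(category = names(observed),
                    observed = as.numeric(observed),
                    expected = as.numeric(expected[names(observed)])),
         path, sep = "\t")
  invisible(path)
}
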