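#' @import data.table
#' @importFrom methods is
#' @importFrom stats pchisq pt qbinom runif rbinom setNames p.adjust t.test
#'   ks.test chisq.test sd
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".I", ".SD", "aid", "alt", "base", "contig", "count", "coverage",
  "end", "freq_pct", "gene_id", "gene_strand", "identity", "in_hairpin",
  "key", "level", "minus", "mismatches", "n_alleles", "nmin", "plus", "pos",
  "qual", "read_id", "ref", "sample_id", "score", "seqstr", "start", "strand",
  "ustarts", "uends", "designed_level", "context7", "context21", "rna_class",
  "sense_count", "sense_cov", "present", "n_present", "effect", "experiment",
  "offset", "mfe", "se", "kmer", "cand", "width", "qualstr", "x", "y",
  "off", "gpos", "ri", "best", "N", "gstrand", "id", "seq", "gene_id_hit",
  "rna_class_hit", "cov_plus", "cov_minus", "mean_level", "aa_ref",
  "aa_edited", "codon_position", "codon_ref", "codon_edited", "coding_pos",
  "n_species_key", "n_species_same", "protein_key", "protein_position",
  "substitution", "species", "mean_a", "mean_b", "p", "q", "relative_change",
  "mean_mfe", "k", "n", "hamming", "sub_threshold"
))

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character DNA sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] that
#' keeps plain character vectors as the working currency of the pipeline.
#'
#' @param x character vector of DNA sequences (ACGTN and IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Phred+33 quality string to integer scores
#' @param qual character vector of Phred+33 quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(s) utf8ToInt(s) - 33L)
}

#' Integer quality scores to a Phred+33 string
#' @param q integer vector of Phred scores.
#' @return single character string.
#' @export
int_to_phred <- function(q) {
  intToUtf8(as.integer(q) + 33L)
}

# count mismatches between two equal-length strings
.str_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# derive a child RNG seed from a master seed, kept inside 32-bit range
.child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 10007) %% 2147483629)
}
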