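library(data.table)

# small simulation configuration used across tests
tiny_config <- function(...) {
  args <- list(genome_length = 8000L, n_genes = 6L, n_trna = 1L,
               n_edit_sites = 4L, mean_coverage = 30, n_replicates = 2L,
               n_strain_snps = 2L, seed = 42L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# a hand-built single-gene genome: one plus-strand CDS spanning the given ORF
# embedded in fixed flanks
make_orf_genome <- function(orf, flank = 30L, strand = "+") {
  set.seed(99)
  left <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  gene_fwd <- if (strand == "-") bacedit::revcomp(orf) else orf
  seqs <- Biostrings::DNAStringSet(paste0(left, gene_fwd, right))
  names(seqs) <- "contig_1"
  gr <- GenomicRanges::GRanges(
    "contig_1",
    IRanges::IRanges(flank + 1L, flank + nchar(orf)),
    strand = strand
  )
  gr$type <- "CDS"
  gr$gene_id <- "gene_001"
  annotated_genome(seqs, gr)
}

# perfect-quality reads table
make_reads <- function(seqs, q = 40L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read_%03d", seq_along(seqs))
  data.table(id = ids, seq = seqs,
             qual = vapply(nchar(seqs),
                           function(n) int_to_phred(rep(q, n)), ""))
}

# build an alignment table directly (bypassing the mapper) for pileup tests
make_alignments <- function(seqs, starts, strand = "+", quals = NULL,
                            contig = "contig_1") {
  n <- length(seqs)
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(m) int_to_phred(rep(40L, m)), "")
  }
  data.table(read_id = sprintf("read_%03d", seq_len(n)), contig = contig,
             start = as.integer(starts),
             end = as.integer(starts) + nchar(seqs) - 1L,
             strand = rep(strand, length.out = n), seq = seqs, qual = quals,
             aligned_fraction = 1, identity = 1)
}
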