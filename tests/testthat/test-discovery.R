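mk_call <- function(pos, ref = "A", alt = "G", freq = 20, ustarts = 5L,
                    uends = 5L, n_alleles = 2L, count = 10L, coverage = 50L,
                    plus = count, minus = 0L, cov_plus = coverage,
                    cov_minus = 0L, sample_id = "s1") {
  data.table(contig = "contig_1", pos = as.integer(pos), ref = ref, alt = alt,
             count = as.integer(count), coverage = as.integer(coverage),
             freq_pct = freq, ustarts = as.integer(ustarts),
             uends = as.integer(uends), n_alleles = as.integer(n_alleles),
             plus = as.integer(plus), minus = as.integer(minus),
             cov_plus = as.integer(cov_plus), cov_minus = as.integer(cov_minus),
             sample_id = sample_id)
}

test_that("the post-call filter cascade applies every bound inclusively", {
  prof <- discovery_profile("cross_species")
  # 99% frequency: strain-specific mutation, excluded; 98% kept (inclusive)
  expect_identical(nrow(filter_variants(mk_call(10, freq = 99), prof)), 0L)
  expect_identical(nrow(filter_variants(mk_call(10, freq = 98), prof)), 1L)
  # 5% boundary inclusive; 4.9% out
  expect_identical(nrow(filter_variants(mk_call(10, freq = 5), prof)), 1L)
  expect_identical(nrow(filter_variants(mk_call(10, freq = 4.9), prof)), 0L)
  # unique starts / ends below 3: excluded
  expect_identical(nrow(filter_variants(mk_call(10, ustarts = 2L), prof)), 0L)
  expect_identical(nrow(filter_variants(mk_call(10, uends = 2L), prof)), 0L)
  # hyper-allelic (3 alleles with support): excluded
  expect_identical(nrow(filter_variants(mk_call(10, n_alleles = 3L), prof)), 0L)
})

test_that("frequency and uniqueness filters commute", {
  set.seed(4)
  calls <- rbindlist(lapply(1:50, function(i) {
    mk_call(i, freq = runif(1, 0, 100),
            ustarts = sample(1:6, 1), uends = sample(1:6, 1))
  }))
  prof <- discovery_profile("cross_species")
  freq_only <- function(x) x[freq_pct >= prof$min_freq_pct &
                               freq_pct <= prof$max_freq_pct]
  uniq_only <- function(x) x[ustarts >= 3L & uends >= 3L]
  expect_identical(freq_only(uniq_only(calls)), uniq_only(freq_only(calls)))
})

test_that("replicate intersection honors the all / at-least-k rules", {
  c1 <- mk_call(c(100, 200), sample_id = "s1")
  c2 <- mk_call(c(100, 300), sample_id = "s2")
  c3 <- mk_call(c(100, 200), sample_id = "s3")
  # rule "all": only the site in all three replicates survives
  keys <- intersect_replicates(list(s1 = c1, s2 = c2, s3 = c3), rule = "all")
  expect_identical(keys$pos, 100L)
  # present in 2 of 3 with rule "all": excluded
  expect_false(200L %in% keys$pos)
  # at_least_k(3) over four replicates keeps a 3-of-4 site
  c4 <- mk_call(c(300, 400), sample_id = "s4")
  keys34 <- intersect_replicates(list(s1 = c1, s2 = c2, s3 = c3, s4 = c4),
                                 rule = "at_least_k", k = 3L)
  expect_true(100L %in% keys34$pos)     # 3 of 4
  expect_false(200L %in% keys34$pos)    # 2 of 4
  # single-sample experiment: configuration error
  expect_error(intersect_replicates(list(s1 = c1), rule = "all"),
               "fewer than two")
  # k exceeding the number of samples: configuration error
  expect_error(intersect_replicates(list(s1 = c1, s2 = c2),
                                    rule = "at_least_k", k = 3L),
               "exceeds")
  # intersection is per experiment, union across experiments
  keys2 <- intersect_replicates(
    list(s1 = c1, s3 = c3, s2 = c2, s4 = mk_call(c(100, 300),
                                                 sample_id = "s4")),
    experiments = c(s1 = "e1", s3 = "e1", s2 = "e2", s4 = "e2"),
    rule = "all")
  expect_setequal(keys2$pos, c(100L, 200L, 300L))
})

test_that("orientation keeps only coding-strand A>G inside known genes", {
  # one plus-strand and one minus-strand gene with known sequence
  set.seed(12)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  orf_p <- paste0("ATG", "TAC", "GAA", strrep("AAC", 20), "TAA")  # + strand
  orf_m <- paste0("ATG", "TAC", "GAA", strrep("AAC", 20), "TAA")  # - strand
  gstr <- paste0(substr(bg, 1, 50), orf_p, substr(bg, 51, 150),
                 revcomp(orf_m), substr(bg, 151, 400))
  seqs <- Biostrings::DNAStringSet(gstr); names(seqs) <- "contig_1"
  p_start <- 51L; p_end <- p_start + nchar(orf_p) - 1L
  m_start <- p_end + 101L; m_end <- m_start + nchar(orf_m) - 1L
  gr <- GenomicRanges::GRanges("contig_1",
                               IRanges::IRanges(c(p_start, m_start),
                                                c(p_end, m_end)),
                               strand = c("+", "-"))
  gr$type <- c("CDS", "CDS"); gr$gene_id <- c("gp", "gm")
  g <- annotated_genome(seqs, gr)

  # the edited A of the plus gene motif: position of A in TAC (orf offset 4)
  pos_p <- p_start + 4L
  # for the minus gene, coding position 5 maps to m_end - 4 on the forward
  # strand, where the forward base is T
  pos_m <- m_end - 4L
  vars <- data.table(
    contig = "contig_1",
    pos = c(pos_p, pos_m, 20L, pos_p + 1L),
    ref = c("A", "T", "A", "C"),
    alt = c("G", "C", "G", "T")
  )
  sites <- orient_and_restrict(vars, g)
  # plus-gene A>G retained; minus-gene forward T>C retained as coding A>G
  expect_setequal(sites$pos, c(pos_p, pos_m))
  expect_identical(sites[pos == pos_m, gene_strand], "-")
  # both report the same coding-strand 7-mer core
  expect_true(all(substr(sites$context7, 2, 5) == "TACG"))
  expect_true(all(substr(sites$context21, 11, 11) == "A"))
  expect_identical(sites$context7, substr(sites$context21, 9, 15))
  expect_true(all(sites$rna_class == "mRNA"))
})

test_that("DNA-variant subtraction removes matching strain mutations", {
  sites <- data.table(contig = "contig_1", pos = c(100L, 200L),
                      gene_id = c("g1", "g2"), gene_strand = c("+", "-"),
                      rna_class = "mRNA", context21 = strrep("A", 21),
                      context7 = "CTACGAA")
  dna <- data.table(contig = "contig_1", pos = 100L, alt = "G")
  out <- subtract_dna_variants(sites, dna)
  expect_identical(out$pos, 200L)
  # non-matching allele: kept
  dna_c <- data.table(contig = "contig_1", pos = 100L, alt = "T")
  expect_identical(nrow(subtract_dna_variants(sites, dna_c)), 2L)
  # empty list: identity
  expect_identical(subtract_dna_variants(sites, NULL), sites)
  expect_identical(nrow(subtract_dna_variants(sites, dna[0])), 2L)
})

test_that("level rescue reports sub-threshold and missing values faithfully", {
  g <- make_orf_genome(paste0("ATG", strrep("AAC", 30), "TAA"))
  sites <- data.table(contig = "contig_1", pos = 40L, gene_id = "gene_001",
                      gene_strand = "+", rna_class = "mRNA",
                      context21 = strrep("A", 21), context7 = "CTACGAA")
  gstr <- as.character(g$sequences[[1]])
  mk_pu <- function(n_ref, n_alt, id) {
    base <- substring(gstr, 31L, 60L)
    reads <- rep(base, n_ref + n_alt)
    if (n_alt > 0) for (i in seq_len(n_alt)) substr(reads[i], 10L, 10L) <- "G"
    aln <- make_alignments(reads, starts = rep(31L, n_ref + n_alt))
    build_pileup(aln, g, sample_id = id)
  }
  pu1 <- mk_pu(80L, 20L, "s1")    # called sample: 20%
  pu2 <- mk_pu(98L, 2L, "s2")     # sub-threshold sample: 2%
  pu3 <- mk_pu(0L, 0L, "s3")      # no coverage
  lv <- rescue_frequencies(sites, list(pu1, pu2, pu3))
  expect_equal(lv[sample_id == "s1", level], 20)
  expect_equal(lv[sample_id == "s2", level], 2)
  expect_false(lv[sample_id == "s2", sub_threshold])
  expect_true(is.na(lv[sample_id == "s3", level]))
  # a 0.5% observation is reported as observed but flagged sub-threshold
  pu4 <- mk_pu(199L, 1L, "s4")
  lv4 <- rescue_frequencies(sites, list(pu4))
  expect_equal(lv4$level, 0.5)
  expect_true(lv4$sub_threshold)
})

test_that("stranded filtering keeps sense support and recounts levels", {
  g <- make_orf_genome(paste0("ATG", strrep("AAC", 30), "TAA"))
  # antisense-only support for an A>G in the plus-strand gene
  anti <- mk_call(40L, plus = 0L, minus = 10L, cov_plus = 0L, cov_minus = 50L)
  expect_identical(nrow(stranded_filter(anti, g)), 0L)
  # sense support: kept
  sense <- mk_call(40L, plus = 10L, minus = 0L, cov_plus = 50L, cov_minus = 0L)
  expect_identical(nrow(stranded_filter(sense, g)), 1L)
  # mixed support: only sense reads count toward the level
  mixed <- mk_call(40L, count = 15L, coverage = 100L, freq = 15,
                   plus = 10L, minus = 5L, cov_plus = 50L, cov_minus = 50L)
  out <- stranded_filter(mixed, g)
  expect_identical(out$count, 10L)
  expect_identical(out$coverage, 50L)
  expect_equal(out$freq_pct, 20)
  # unstranded library: configuration error
  expect_error(stranded_filter(sense, g, library_stranded = FALSE),
               "unstranded")
  # intergenic variant: dropped
  outside <- mk_call(5L)
  expect_identical(nrow(stranded_filter(outside, g)), 0L)
})

test_that("planted 100%-frequency strain SNPs never reach the final table", {
  cfg <- tiny_config(genome_length = 12000L, n_genes = 8L, n_edit_sites = 3L,
                     n_strain_snps = 4L, n_replicates = 2L, seed = 101L)
  res <- run_editing_simulation(cfg)
  ev <- evaluate_recovery(res$sites, res$truth, res$snps)
  expect_identical(ev$snp_leakage, 0L)
  expect_identical(ev$false_positives, 0L)
})
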