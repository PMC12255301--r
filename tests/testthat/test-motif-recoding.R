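ctx21 <- function(core4, pad = "C") {
  # build a 21-mer whose characters 10..13 are the given 4-mer (edited A at 11)
  paste0(strrep(pad, 9), core4, strrep(pad, 8))
}

test_that("observed 4-mer counting extracts (-1, A, +1, +2) per site", {
  ctx <- c(ctx21("TACG"), ctx21("CAAA"), ctx21("TACG"))
  obs <- count_observed_motifs(ctx)
  expect_identical(sum(obs), 3L)
  expect_identical(obs[["TACG"]], 2L)
  expect_identical(obs[["CAAA"]], 1L)
  expect_length(obs, 64L)
  # sites must carry A at the center
  expect_error(count_observed_motifs(ctx21("TTCG")), "A")
})

test_that("the genomic motif null enumerates A-anchored 4-mers exhaustively", {
  # toy genome: exhaustive enumeration over both strands by hand
  toy <- "TACGTTAAGG"
  seqs <- Biostrings::DNAStringSet(toy); names(seqs) <- "c1"
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, nchar(toy)),
                               strand = "+")
  gr$type <- "CDS"; gr$gene_id <- "g"
  g <- annotated_genome(seqs, gr)
  both <- c(toy, revcomp(toy))
  enum <- unlist(lapply(both, function(s) {
    sapply(1:(nchar(s) - 3), function(i) substr(s, i, i + 3))
  }))
  enum <- enum[substr(enum, 2, 2) == "A"]
  expected <- genomic_motif_null(list(sp = g), c(sp = length(enum)))
  oracle <- table(enum)
  for (cat in names(oracle)) {
    expect_equal(unname(expected[cat]), unname(as.numeric(oracle[cat])))
  }
  expect_equal(sum(expected), length(enum))

  # linearity: two species, one site each -> average of the two frequencies
  toy2 <- "CAAACAAACC"
  seqs2 <- Biostrings::DNAStringSet(toy2); names(seqs2) <- "c1"
  g2 <- annotated_genome(seqs2, gr)
  e_pair <- genomic_motif_null(list(a = g, b = g2), c(a = 1, b = 1))
  e_a <- genomic_motif_null(list(a = g), c(a = 1))
  e_b <- genomic_motif_null(list(b = g2), c(b = 1))
  expect_equal(e_pair, e_a + e_b)
  expect_equal(sum(e_pair), 2)

  # species with sites but no genome: error
  expect_error(genomic_motif_null(list(a = g), c(a = 1, zz = 5)), "zz")
})

test_that("chi-square goodness of fit matches the direct formula", {
  r <- chi_square_gof(c(30, 10), c(20, 20))
  expect_equal(r$statistic, 10)
  expect_identical(r$df, 1L)
  expect_equal(r$p, pchisq(10, 1, lower.tail = FALSE))
  # observed equal to expected: statistic 0, p 1
  r0 <- chi_square_gof(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # 64 motif categories give df 63
  obs <- setNames(rep(10, 64), paste0("cat", 1:64))
  r64 <- chi_square_gof(obs, rep(10, 64))
  expect_identical(r64$df, 63L)
  # agreement with stats::chisq.test on a non-trivial table
  o <- c(12, 40, 8, 25); e <- c(20, 30, 10, 25)
  ours <- chi_square_gof(o, e)
  ref <- suppressWarnings(chisq.test(o, p = e / sum(e)))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
})

test_that("7-mer classification agrees with per-position comparison", {
  expect_identical(classify_seven_mer("CTACGAA")$hamming, 0L)
  expect_identical(classify_seven_mer("TTACGAA")$hamming, 0L)
  # G at the Y position is a mismatch
  g1 <- classify_seven_mer("GTACGAA")
  expect_identical(g1$hamming, 1L)
  expect_identical(g1$mismatch_offsets[[1]], 1L)
  expect_error(classify_seven_mer("CTACGAN"), "non-ACGT")

  # exhaustive: all 4^7 7-mers against the brute-force oracle
  b <- c("A", "C", "G", "T")
  all7 <- do.call(paste0, expand.grid(b, b, b, b, b, b, b,
                                      stringsAsFactors = FALSE))
  got <- classify_seven_mer(all7)$hamming
  want <- vapply(all7, oracle_hamming7, 0L, USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("position frequency matrix and information content behave", {
  # identical contexts: zero entropy, IC = 2 - e_n everywhere
  ctx <- rep(ctx21("TACG"), 40)
  r <- position_frequency_matrix(ctx)
  en <- 3 / (2 * log(2) * 40)
  expect_equal(unname(r$ic), rep(2 - en, 21), tolerance = 1e-12)
  expect_true(all(abs(colSums(r$pfm) - 1) < 1e-12))
  # center column is pure A
  expect_equal(unname(r$pfm["A", "0"]), 1)

  # uniform random contexts: IC near zero at non-motif positions
  set.seed(8)
  rand <- vapply(1:2000, function(i) {
    paste0(paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""),
           "A",
           paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""))
  }, "")
  rr <- position_frequency_matrix(rand)
  expect_lt(max(abs(rr$ic[-11])), 0.05)
  expect_gt(rr$ic[["0"]], 1.9)   # the fixed center A is fully informative

  expect_error(position_frequency_matrix(c(ctx21("TACG"), "ACGT")),
               "heterogeneous")
})

test_that("codon effects reproduce the canonical recoding outcomes", {
  # TAC (Tyr) edited at codon position 2 -> TGC (Cys)
  r <- codon_effect("TAC", 2L)
  expect_identical(r$codon_edited, "TGC")
  expect_identical(r$aa_ref, "Y"); expect_identical(r$aa_edited, "C")
  expect_identical(r$effect, "nonsynonymous")
  # ACG (Thr) at position 1 -> GCG (Ala)
  r2 <- codon_effect("ACG", 1L)
  expect_identical(r2$codon_edited, "GCG")
  expect_identical(r2$aa_ref, "T"); expect_identical(r2$aa_edited, "A")
  # GTA (Val) at position 3 -> GTG: synonymous
  r3 <- codon_effect("GTA", 3L)
  expect_identical(r3$effect, "synonymous")

  # exhaustive: every codon x position with an A, against a brute-force
  # translation-table classification
  b <- c("A", "C", "G", "T")
  codons <- do.call(paste0, expand.grid(b, b, b, stringsAsFactors = FALSE))
  gc <- Biostrings::GENETIC_CODE
  for (cod in codons) {
    for (p in 1:3) {
      if (substr(cod, p, p) != "A") {
        expect_error(codon_effect(cod, p))
        next
      }
      got <- codon_effect(cod, p)
      ed <- cod; substr(ed, p, p) <- "G"
      aa1 <- gc[[cod]]; aa2 <- gc[[ed]]
      want <- if (aa1 == aa2) "synonymous" else if (aa2 == "*") "stop_gain"
              else if (aa1 == "*") "stop_loss" else "nonsynonymous"
      expect_identical(got$effect, want)
      expect_identical(got$aa_ref, aa1)
      expect_identical(got$aa_edited, aa2)
    }
  }
})

test_that("site annotation locates codons through gene frames and strands", {
  for (strand in c("+", "-")) {
    orf <- paste0("ATG", "TAC", "GAA", "GTA", "TAA")
    g <- make_orf_genome(orf, strand = strand)
    feats <- g$features
    gs <- GenomicRanges::start(feats); ge <- GenomicRanges::end(feats)
    # coding position of the A in TAC is 5; of the A in GTA (pos 3) is 12
    cpos <- function(p) if (strand == "+") gs + p - 1L else ge - p + 1L
    sites <- data.table(contig = "contig_1", pos = c(cpos(5L), cpos(12L)),
                        gene_id = "gene_001", gene_strand = strand,
                        rna_class = "mRNA", context21 = NA, context7 = NA)
    ann <- annotate_codon_effect(sites, g)
    tac <- ann[pos == cpos(5L)]
    expect_identical(tac$codon_ref, "TAC")
    expect_identical(tac$codon_position, 2L)
    expect_identical(tac$effect, "nonsynonymous")
    gta <- ann[pos == cpos(12L)]
    expect_identical(gta$codon_ref, "GTA")
    expect_identical(gta$codon_position, 3L)
    expect_identical(gta$effect, "synonymous")
  }
  # tRNA sites get NA effect, not an error
  g <- make_orf_genome("ATGTACGAAGTATAA")
  s <- data.table(contig = "contig_1", pos = 35L, gene_id = "gene_001",
                  gene_strand = "+", rna_class = "tRNA",
                  context21 = NA, context7 = NA)
  expect_true(is.na(annotate_codon_effect(s, g)$effect))
})

test_that("the codon-position null enumerates TACG adenosines in CDS", {
  # toy CDS ATG TAC GAA TAA: single TACG-context A at codon position 2
  g <- make_orf_genome("ATGTACGAATAA")
  null <- bacedit:::.tacg_cds_null(g)
  expect_identical(nrow(null), 1L)
  expect_identical(null$codon_position, 2L)
  exp <- codon_expected_distributions(list(sp = g), c(sp = 10))
  expect_equal(unname(exp$position), c(0, 10, 0))
  # observed equal to expected: p ~ 1
  r <- chi_square_gof(c(0, 10, 0) + 1e-9, unname(exp$position) + 1e-9)
  expect_gt(r$p, 0.99)
})

test_that("site-table summaries recompute the classifier fractions", {
  ctx <- c(rep(ctx21("TACG", pad = "T"), 6), rep(ctx21("CACG"), 4))
  tab <- data.table(
    context21 = ctx,
    rna_class = c(rep("mRNA", 4), "tRNA", "rRNA", rep("mRNA", 4)),
    effect = c(rep("nonsynonymous", 3), "synonymous", NA, NA,
               rep("nonsynonymous", 2), rep("synonymous", 2)),
    aa_ref = c(rep("Y", 3), "V", NA, NA, "T", "T", "V", "V"),
    aa_edited = c(rep("C", 3), "V", NA, NA, "A", "A", "V", "V")
  )
  s <- summarize_site_table(tab)
  expect_identical(s$n_sites, 10L)
  expect_identical(s$n_tacg, 6L)
  expect_equal(s$tacg_fraction_pct, 60)
  expect_identical(unname(s$tacg_partition), c(4L, 1L, 1L))
  expect_identical(s$n_recoding, 5L)
  expect_equal(s$recoding_fraction_pct, 100 * 5 / 8)
  expect_identical(s$n_tyr_to_cys, 3L)
  expect_identical(s$n_thr_to_ala, 2L)
  expect_identical(s$n_synonymous, 3L)
})
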