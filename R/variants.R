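#' Call RNA--DNA differences from a pileup
#'
#' Emits one candidate variant per (position, alternative base) passing the
#' initial-calling thresholds. Frequency is `100 * count / coverage` with the
#' coverage denominator being the qualified bases at the position (so the
#' frequency doubles as the putative editing level). Positions with coverage
#' above `max_coverage` are skipped. `n_alleles` counts the alleles at the
#' position with support of at least `min_count` reads (used downstream by
#' the hyper-allelic filter).
#'
#' @param pileup a `site_pileup` from [build_pileup()].
#' @param min_coverage minimum qualified coverage (default 20).
#' @param min_count minimum supporting reads for the alternative allele.
#' @param min_frequency_pct minimum variant frequency in percent.
#' @param max_coverage ignore positions above this coverage.
#' @return `data.table(contig, pos, ref, alt, count, coverage, freq_pct,
#'   ustarts, uends, n_alleles, plus, minus, cov_plus, cov_minus, sample_id)`
#'   of class `variant_calls`.
#' @export
call_variants <- function(pileup, min_coverage = 20L, min_count = 3L,
                          min_frequency_pct = 1.0, max_coverage = 1e6) {
  al <- copy(pileup$alleles)
  al <- merge(al, pileup$positions, by = c("contig", "pos"))
  al[, n_alleles := sum(count >= min_count), by = .(contig, pos)]
  calls <- al[base != ref &
                coverage >= min_coverage & coverage <= max_coverage &
                count >= min_count]
  calls[, freq_pct := 100 * count / coverage]
  calls <- calls[freq_pct >= min_frequency_pct]
  out <- calls[, .(contig, pos, ref, alt = base, count, coverage, freq_pct,
                   ustarts, uends, n_alleles, plus, minus,
                   cov_plus, cov_minus)]
  out[, sample_id := pileup$sample_id]
  setorder(out, contig, pos, alt)
  setattr(out, "class", c("variant_calls", class(out)))
  out[]
}

#' Write variant calls as a VCF-like TSV
#' @param calls `variant_calls` table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_variant_calls <- function(calls, path) {
  out <- data.table(
    CHROM = calls$contig, POS = calls$pos, REF = calls$ref, ALT = calls$alt,
    COUNT = calls$count, COV = calls$coverage, FREQ_PCT = calls$freq_pct,
    USTARTS = calls$ustarts, UENDS = calls$uends, SAMPLE = calls$sample_id
  )
  fwrite(out, path, sep = "\t")
  invisible(path)
}
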