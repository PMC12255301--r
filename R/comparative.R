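#' Benjamini--Hochberg FDR correction
#'
#' Step-up q-values `q_i = min_{j >= rank(i)} p_(j) * m / j`, capped at 1,
#' original order restored; delegated to [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Differential editing between two strains
#'
#' Per site, a two-sided pooled-variance (Student's) t-test on per-replicate
#' editing levels, followed by Benjamini--Hochberg FDR correction across the
#' site set. Relative change is the signed fraction of the group-A mean,
#' `(mean_b - mean_a) / mean_a` (missing when `mean_a` is 0). Sites with
#' identical values in both groups get `p = 1` by convention.
#'
#' @param levels_a,levels_b numeric matrices (sites x replicates) of editing
#'   levels in percent; same number of rows. Vectors are treated as one site.
#' @param site_ids optional row labels.
#' @return `data.table(site, mean_a, mean_b, t, p, q, relative_change)`.
#' @export
differential_editing <- function(levels_a, levels_b, site_ids = NULL) {
  if (is.vector(levels_a)) levels_a <- matrix(levels_a, nrow = 1L)
  if (is.vector(levels_b)) levels_b <- matrix(levels_b, nrow = 1L)
  stopifnot(nrow(levels_a) == nrow(levels_b),
            ncol(levels_a) >= 2L, ncol(levels_b) >= 2L)
  n <- nrow(levels_a)
  if (is.null(site_ids)) site_ids <- sprintf("site_%03d", seq_len(n))
  res <- lapply(seq_len(n), function(i) {
    a <- levels_a[i, ]; b <- levels_b[i, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.table(site = site_ids[i], mean_a = mean(a),
                        mean_b = mean(b), t = NA_real_, p = NA_real_))
    }
    if (sd(a) == 0 && sd(b) == 0) {
      tt <- if (mean(a) == mean(b)) list(t = 0, p = 1) else
        list(t = Inf * sign(mean(b) - mean(a)), p = 0)
      return(data.table(site = site_ids[i], mean_a = mean(a),
                        mean_b = mean(b), t = tt$t, p = tt$p))
    }
    ht <- t.test(a, b, var.equal = TRUE)
    data.table(site = site_ids[i], mean_a = mean(a), mean_b = mean(b),
               t = unname(ht$statistic), p = ht$p.value)
  })
  out <- rbindlist(res)
  out[, q := NA_real_]
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out[, relative_change := ifelse(mean_a == 0, NA_real_,
                                  (mean_b - mean_a) / mean_a)]
  out[]
}

#' Compare average editing levels of two site sets
#'
#' Welch's unequal-variance t-test on the vectors of per-site mean levels
#' (e.g. overexpression sites versus control sites).
#'
#' @param site_means_a,site_means_b per-site average levels (each n >= 2).
#' @return list with `t`, `df`, `p` (see [welch_t()]).
#' @export
group_comparison <- function(site_means_a, site_means_b) {
  if (length(site_means_a) < 2L || length(site_means_b) < 2L) {
    stop("each site group needs at least two sites")
  }
  welch_t(site_means_a, site_means_b)
}

#' Classify editing events by cross-species conservation
#'
#' Events are grouped by protein identity (`protein_key`, a normalized gene
#' symbol or protein-family name from an external homology analysis). An
#' event is `conserved` when at least two species recode the same amino-acid
#' position with the same substitution, `partially_conserved` when at least
#' two species share the protein but not the recoded position/substitution,
#' and `unique` otherwise. Every input row receives exactly one class.
#'
#' @param site_table `data.table(species, protein_key, protein_position,
#'   substitution)` -- one row per editing event.
#' @return the input with a `class` column added, plus attribute
#'   `"group_summary"` (`data.table(protein_key, n_species, n_events,
#'   class)` at the group level).
#' @export
classify_conservation <- function(site_table) {
  st <- copy(as.data.table(site_table))
  stopifnot(all(c("species", "protein_key", "protein_position",
                  "substitution") %in% names(st)))
  st[, n_species_key := uniqueN(species), by = protein_key]
  st[, n_species_same := uniqueN(species),
     by = .(protein_key, protein_position, substitution)]
  st[, class := ifelse(n_species_same >= 2L, "conserved",
                       ifelse(n_species_key >= 2L, "partially_conserved",
                              "unique"))]
  grp <- st[, .(n_species = uniqueN(species), n_events = .N,
                class = if (any(class == "conserved")) "conserved"
                        else if (any(class == "partially_conserved"))
                          "partially_conserved" else "unique"),
            by = protein_key]
  st[, c("n_species_key", "n_species_same") := NULL]
  setattr(st, "group_summary", grp)
  st[]
}

#' Amino-acid frequencies at an alignment column
#'
#' Maps an ungapped reference position to its alignment column and tabulates
#' residue frequencies over the sequences passing the exclusion flags
#' (partial sequences, uncultured/unclassified species, hypothetical
#' proteins). Gap characters do not count toward frequencies.
#'
#' @param msa an [Biostrings::AAStringSet] (aligned, equal widths) or a named
#'   character vector; gaps as `-`.
#' @param ref_id name of the reference sequence in the alignment.
#' @param ref_position 1-based position in the *ungapped* reference.
#' @param exclusions optional `data.frame(id, partial, uncultured,
#'   hypothetical)`; sequences with any `TRUE` flag are excluded.
#' @return list with `column` (alignment column index), `frequencies`
#'   (named numeric, sums to 1), `counts`, and `n_used`.
#' @export
alignment_column_identity <- function(msa, ref_id, ref_position,
                                      exclusions = NULL) {
  seqs <- if (is(msa, "XStringSet")) {
    setNames(as.character(msa), names(msa))
  } else msa
  if (!ref_id %in% names(seqs)) stop("ref_id not present in the alignment")
  if (length(unique(nchar(seqs))) != 1L) stop("sequences not aligned")
  ref <- strsplit(seqs[[ref_id]], "")[[1]]
  ungapped <- cumsum(ref != "-")
  if (ref_position > max(ungapped)) {
    stop("ref_position beyond the ungapped reference length")
  }
  col <- which(ungapped == ref_position & ref != "-")[1]
  use <- names(seqs)
  if (!is.null(exclusions)) {
    ex <- as.data.table(exclusions)
    flagged <- ex[rowSums(ex[, setdiff(names(ex), "id"), with = FALSE],
                          na.rm = TRUE) > 0, id]
    use <- setdiff(use, flagged)
  }
  res <- vapply(seqs[use], function(s) substr(s, col, col), "")
  res <- res[res != "-"]
  counts <- table(res)
  freqs <- setNames(as.numeric(counts) / sum(counts), names(counts))
  list(column = col, frequencies = freqs,
       counts = setNames(as.integer(counts), names(counts)),
       n_used = length(res))
}
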