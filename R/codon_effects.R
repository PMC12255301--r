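.GC <- Biostrings::GENETIC_CODE   # standard code (bacterial, mid-gene)

.translate1 <- function(codon) {
  aa <- unname(.GC[codon])
  ifelse(is.na(aa), "X", aa)
}

# effect of one A->G codon change
.effect_of <- function(codon_ref, codon_edited) {
  aa_ref <- .translate1(codon_ref)
  aa_ed <- .translate1(codon_edited)
  ifelse(aa_ref == aa_ed, "synonymous",
    ifelse(aa_ed == "*", "stop_gain",
      ifelse(aa_ref == "*", "stop_loss", "nonsynonymous")))
}

#' Effect of editing a single codon
#'
#' Substitutes A->G at the given in-codon position and classifies the change
#' under the standard genetic code.
#'
#' @param codon_ref DNA codon (3 characters) containing A at `codon_position`.
#' @param codon_position 1, 2, or 3.
#' @return list with `codon_ref`, `codon_edited`, `codon_position`, `aa_ref`,
#'   `aa_edited`, `effect` (synonymous / nonsynonymous / stop_gain /
#'   stop_loss).
#' @export
codon_effect <- function(codon_ref, codon_position) {
  stopifnot(nchar(codon_ref) == 3L, codon_position %in% 1:3)
  if (substr(codon_ref, codon_position, codon_position) != "A") {
    stop("codon has no A at the requested position")
  }
  edited <- codon_ref
  substr(edited, codon_position, codon_position) <- "G"
  list(codon_ref = codon_ref, codon_edited = edited,
       codon_position = as.integer(codon_position),
       aa_ref = .translate1(codon_ref), aa_edited = .translate1(edited),
       effect = .effect_of(codon_ref, edited))
}

#' Annotate the codon-level effect of an editing site
#'
#' For sites inside a CDS, computes the codon and in-codon position on the
#' coding strand, substitutes A->G at that position, and classifies the
#' recoding effect under the standard genetic code. Sites in tRNA/rRNA have
#' no codon effect (`NA` fields), which is not an error.
#'
#' @param sites editing-site table from [orient_and_restrict()] /
#'   [discover_editing()].
#' @param genome an [annotated_genome()].
#' @return the site table with added columns `codon_position` (1/2/3),
#'   `codon_ref`, `codon_edited`, `aa_ref`, `aa_edited`, `effect`.
#' @export
annotate_codon_effect <- function(sites, genome) {
  out <- copy(as.data.table(sites))
  n <- nrow(out)
  out[, `:=`(codon_position = NA_integer_, codon_ref = NA_character_,
             codon_edited = NA_character_, aa_ref = NA_character_,
             aa_edited = NA_character_, effect = NA_character_)]
  if (n == 0L) return(out)
  feats <- genome$features
  fmap <- setNames(seq_along(feats), feats$gene_id)
  for (i in seq_len(n)) {
    if (is.na(out$rna_class[i]) || out$rna_class[i] != "mRNA") next
    f <- feats[fmap[[out$gene_id[i]]]]
    gs <- GenomicRanges::start(f); ge <- GenomicRanges::end(f)
    gstrand <- as.character(GenomicRanges::strand(f))
    cseq <- .coding_seq(.contig_str(genome, out$contig[i]), gs, ge, gstrand)
    p <- if (gstrand == "+") out$pos[i] - gs + 1L else ge - out$pos[i] + 1L
    cpos <- ((p - 1L) %% 3L) + 1L
    c0 <- p - cpos + 1L
    codon <- substr(cseq, c0, c0 + 2L)
    stopifnot(substr(codon, cpos, cpos) == "A")
    edited <- codon
    substr(edited, cpos, cpos) <- "G"
    out[i, `:=`(codon_position = cpos, codon_ref = codon,
                codon_edited = edited,
                aa_ref = .translate1(codon), aa_edited = .translate1(edited),
                effect = .effect_of(codon, edited))]
  }
  out[]
}

#' Expected codon-position and effect distributions under a genomic null
#'
#' The null is the set of all adenosines lying in a `TACG` context
#' (coding-strand `T[A]CG`, the minimal motif editing requires) inside
#' annotated CDS, per species; their codon positions and predicted A->G
#' effects form the expected distributions, combined across species weighted
#' by per-species site counts.
#'
#' @param genomes named list of [annotated_genome()].
#' @param per_species_site_counts named numeric vector of site counts.
#' @return list with `position` (length-3 expected counts, positions 1--3)
#'   and `effect` (expected counts over effect classes).
#' @export
codon_expected_distributions <- function(genomes, per_species_site_counts) {
  sp <- names(per_species_site_counts)
  pos_exp <- setNames(numeric(3L), as.character(1:3))
  eff_levels <- c("synonymous", "nonsynonymous", "stop_gain", "stop_loss")
  eff_exp <- setNames(numeric(4L), eff_levels)
  for (s in sp) {
    null <- .tacg_cds_null(genomes[[s]])
    if (nrow(null) == 0L) next
    w <- per_species_site_counts[[s]]
    pfreq <- table(factor(null$codon_position, levels = 1:3)) / nrow(null)
    efreq <- table(factor(null$effect, levels = eff_levels)) / nrow(null)
    pos_exp <- pos_exp + w * as.numeric(pfreq)
    eff_exp <- eff_exp + w * as.numeric(efreq)
  }
  list(position = pos_exp, effect = eff_exp)
}

# all TACG-context adenosines in CDS of one genome, with codon annotation
.tacg_cds_null <- function(genome) {
  feats <- genome$features
  cds <- feats[feats$type == "CDS"]
  out <- vector("list", length(cds))
  for (i in seq_along(cds)) {
    gs <- GenomicRanges::start(cds[i]); ge <- GenomicRanges::end(cds[i])
    gstrand <- as.character(GenomicRanges::strand(cds[i]))
    contig <- as.character(GenomicRanges::seqnames(cds[i]))
    cseq <- .coding_seq(.contig_str(genome, contig), gs, ge, gstrand)
    hits <- gregexpr("(?=TACG)", cseq, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    p <- as.integer(hits) + 1L          # position of the A in TACG
    cpos <- ((p - 1L) %% 3L) + 1L
    c0 <- p - cpos + 1L
    codon <- substring(cseq, c0, c0 + 2L)
    valid <- nchar(codon) == 3L
    p <- p[valid]; cpos <- cpos[valid]; codon <- codon[valid]
    if (!length(p)) next
    edited <- codon
    for (j in seq_along(edited)) substr(edited[j], cpos[j], cpos[j]) <- "G"
    out[[i]] <- data.table(gene_id = cds$gene_id[i], coding_pos = p,
                           codon_position = cpos, codon_ref = codon,
                           codon_edited = edited,
                           effect = .effect_of(codon, edited))
  }
  res <- rbindlist(out)
  if (is.null(res) || nrow(res) == 0L) {
    res <- data.table(gene_id = character(), coding_pos = integer(),
                      codon_position = integer(), codon_ref = character(),
                      codon_edited = character(), effect = character())
  }
  res
}

#' Summary statistics of an editing-site table
#'
#' Runs the deterministic classifiers over a final site table: the fraction
#' of sites in a TACG 4-mer context, the mRNA/tRNA/rRNA partition of
#' TACG-context sites, the exact-YTACGAA / one-mismatch / >=2-mismatch
#' 7-mer fractions, and -- for mRNA sites with codon annotation -- the
#' recoding (nonsynonymous) fraction, Tyr->Cys and Thr->Ala substitution
#' counts, and the synonymous count.
#'
#' @param sites site table with `context21` (and, when available,
#'   `rna_class`, `aa_ref`, `aa_edited`, `effect` columns).
#' @return named list of summary statistics.
#' @export
summarize_site_table <- function(sites) {
  sites <- as.data.table(sites)
  n <- nrow(sites)
  four <- substr(sites$context21, 10L, 13L)
  is_tacg <- four == "TACG"
  out <- list(
    n_sites = n,
    n_tacg = sum(is_tacg),
    tacg_fraction_pct = 100 * mean(is_tacg)
  )
  if ("rna_class" %in% names(sites)) {
    cls <- table(factor(sites$rna_class[is_tacg],
                        levels = c("mRNA", "tRNA", "rRNA")))
    out$tacg_partition <- setNames(as.integer(cls), names(cls))
  }
  sm <- classify_seven_mer(substr(sites$context21, 9L, 15L))
  out$exact_motif_fraction_pct <- 100 * mean(sm$hamming == 0L)
  out$one_mismatch_fraction_pct <- 100 * mean(sm$hamming == 1L)
  out$two_plus_mismatch_fraction_pct <- 100 * mean(sm$hamming >= 2L)
  if ("effect" %in% names(sites)) {
    mr <- sites[!is.na(effect)]
    out$n_with_effect <- nrow(mr)
    out$n_recoding <- sum(mr$effect %in% c("nonsynonymous", "stop_gain",
                                           "stop_loss"))
    out$recoding_fraction_pct <- 100 * out$n_recoding / max(1L, nrow(mr))
    out$n_tyr_to_cys <- mr[aa_ref == "Y" & aa_edited == "C", .N]
    out$n_thr_to_ala <- mr[aa_ref == "T" & aa_edited == "A", .N]
    out$n_synonymous <- mr[effect == "synonymous", .N]
  }
  out
}
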