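#' Extract the 17-nt folding window around an editing site
#'
#' At offset 0 the window spans coding-strand positions `pos - 7 .. pos + 9`,
#' placing the edited adenosine at window position 8 (1-based) -- its location
#' in the tRNA-Arg2 anticodon arm (`NNNNNYT[A]CGAANNNNN`). Offset `d` shifts
#' the window `d` bases downstream along the coding strand. Windows running
#' off a contig end return `NA`. Sequences are returned in the RNA alphabet.
#'
#' @param sites editing-site table (needs `contig`, `pos`, `gene_strand`).
#' @param genome an [annotated_genome()].
#' @param offset window displacement in bases (0 = centered geometry).
#' @param length window length (default 17).
#' @return character vector of RNA windows (`NA` where off-contig).
#' @export
extract_window <- function(sites, genome, offset = 0L, length = 17L) {
  sites <- as.data.table(sites)
  glen <- setNames(Biostrings::width(genome$sequences),
                   names(genome$sequences))
  n <- nrow(sites)
  out <- rep(NA_character_, n)
  up <- 7L                    # bases upstream of the edited A at offset 0
  down <- length - up - 1L    # bases downstream (9 for the 17-nt window)
  for (cn in unique(sites$contig)) {
    g <- .contig_str(genome, cn)
    idx <- which(sites$contig == cn)
    plus <- sites$gene_strand[idx] == "+"
    # coding-strand window start/end expressed on the forward strand
    a <- ifelse(plus, sites$pos[idx] - up + offset,
                sites$pos[idx] - down - offset)
    b <- a + length - 1L
    okw <- a >= 1L & b <= glen[[cn]]
    s <- rep(NA_character_, length(idx))
    if (any(okw)) s[okw] <- substring(g, a[okw], b[okw])
    flip <- okw & !plus
    if (any(flip)) s[flip] <- revcomp(s[flip])
    out[idx] <- s
  }
  chartr("T", "U", out)
}

#' Minimum free energy of RNA sequences
#'
#' Folds each sequence under a nearest-neighbor thermodynamic model at 37 C
#' via the ViennaRNA `RNAfold` program when available (`engine = "vienna"`,
#' the default resolution of `"auto"`). The built-in `"nussinov"` engine is a
#' simplified base-pair-maximization scorer (-1 kcal/mol per nested pair,
#' minimum hairpin loop 3) provided for engine-free testing; it is *not*
#' thermodynamic and is only meaningful for relative comparisons.
#'
#' @param sequences character vector of RNA (or DNA) sequences.
#' @param engine `"auto"`, `"vienna"`, or `"nussinov"`.
#' @return numeric vector of MFE values (kcal/mol; 0 = no structure).
#' @export
fold_mfe <- function(sequences, engine = c("auto", "vienna", "nussinov")) {
  engine <- match.arg(engine)
  if (engine == "auto") {
    engine <- if (nzchar(Sys.which("RNAfold"))) "vienna" else "nussinov"
  }
  out <- rep(NA_real_, length(sequences))
  ok <- !is.na(sequences)
  if (!any(ok)) return(out)
  seqs <- chartr("Tt", "Uu", toupper(sequences[ok]))
  if (engine == "vienna") {
    if (!nzchar(Sys.which("RNAfold"))) {
      stop("RNAfold not found on PATH; use engine = 'nussinov'")
    }
    res <- system2("RNAfold", c("--noPS", "-T", "37"), input = seqs,
                   stdout = TRUE)
    # output alternates sequence / structure lines
    struct <- res[seq(2L, length(res), by = 2L)]
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", struct))
    out[ok] <- mfe
  } else {
    out[ok] <- vapply(seqs, .nussinov_score, 0.0, USE.NAMES = FALSE)
  }
  out
}

# base-pair maximization (Nussinov) with minimum loop length 3;
# returns -(max pairs) as a pseudo-energy
.nussinov_score <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < 5L) return(0)
  can_pair <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "U") || (a == "U" && b == "G")
  }
  M <- matrix(0L, n, n)
  for (span in 4:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      for (k in i:(j - 4L)) {
        if (can_pair(s[k], s[j])) {
          left <- if (k > i) M[i, k - 1L] else 0L
          inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
          best <- max(best, left + inner + 1L)
        }
      }
      M[i, j] <- best
    }
  }
  -as.numeric(M[1L, n])
}

#' MFE sliding-window profile around editing sites
#'
#' Per offset, the mean and standard error of the MFE over all sites whose
#' window lies inside the contig (skipped windows are excluded from `n`).
#'
#' @param sites editing-site table (>= 2 sites).
#' @param genome an [annotated_genome()].
#' @param offsets integer vector of window displacements.
#' @param engine folding engine, see [fold_mfe()].
#' @return `data.table(offset, mean_mfe, se, n)`.
#' @export
mfe_profile <- function(sites, genome, offsets = -30:30,
                        engine = c("auto", "vienna", "nussinov")) {
  engine <- match.arg(engine)
  stopifnot(nrow(sites) >= 2L)
  # batch all windows into one folding call per engine invocation
  wins <- lapply(offsets, function(d) extract_window(sites, genome, d))
  allw <- unlist(wins)
  mfe <- fold_mfe(allw, engine)
  idx <- rep(seq_along(offsets), each = nrow(sites))
  dt <- data.table(offset = offsets[idx], mfe = mfe)[!is.na(mfe)]
  prof <- dt[, .(mean_mfe = mean(mfe),
                 se = sd(mfe) / sqrt(.N), n = .N), by = offset]
  setorder(prof, offset)
  prof[]
}

#' Locate motif-matched control sites in a genome
#'
#' Every match of the IUPAC pattern (default `YTACGAA`) on either strand,
#' anchored at the would-be edited adenosine (pattern position 3 on the
#' matched strand); real editing sites are removed.
#'
#' @param genome an [annotated_genome()].
#' @param pattern IUPAC pattern with the edited A at position 3.
#' @param exclude editing-site table (or `data.table(contig, pos,
#'   gene_strand)`) of real sites to remove.
#' @return `data.table(contig, pos, gene_strand)` of control anchors;
#'   `gene_strand` is the strand carrying the motif, so the controls can be
#'   fed to [extract_window()] and [mfe_profile()] like real sites.
#' @export
locate_control_sites <- function(genome, pattern = "YTACGAA",
                                 exclude = NULL) {
  anchor_off <- 2L   # edited A at pattern position 3 (1-based)
  pat <- Biostrings::DNAString(pattern)
  out <- vector("list", 2L * length(genome$sequences))
  k <- 0L
  for (cn in names(genome$sequences)) {
    subj <- genome$sequences[[cn]]
    fwd <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
    k <- k + 1L
    out[[k]] <- data.table(contig = cn,
                           pos = Biostrings::start(fwd) + anchor_off,
                           gene_strand = "+")
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    subj, fixed = FALSE)
    # reverse-strand match: the motif A sits anchor_off bases from the
    # match *end* on the forward strand
    k <- k + 1L
    out[[k]] <- data.table(contig = cn,
                           pos = Biostrings::end(rev) - anchor_off,
                           gene_strand = "-")
  }
  ctl <- rbindlist(out)
  if (!is.null(exclude) && nrow(exclude)) {
    ctl <- ctl[!paste(contig, pos) %in%
                 paste(exclude$contig, exclude$pos)]
  }
  setorder(ctl, contig, pos)
  ctl[]
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t statistic with Welch--Satterthwaite degrees of freedom,
#' delegated to [stats::t.test()].
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least two values")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    return(list(t = 0, df = length(group_a) + length(group_b) - 2L, p = 1))
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random Eulerian-walk shuffle preserving the dinucleotide composition;
#' the standard null for secondary-structure stability comparisons.
#'
#' @param seq a single sequence (character scalar).
#' @return shuffled sequence of the same dinucleotide composition.
#' @export
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < 3L) return(seq)
  for (attempt in 1:1000) {
    edges <- lapply(split(s[-1L], s[-n]), sample)
    counts <- lapply(edges, function(x) 0L)
    out <- character(n)
    out[1] <- s[1]
    stuck <- FALSE
    for (i in 2:n) {
      src <- out[i - 1L]
      j <- counts[[src]] + 1L
      if (is.null(edges[[src]]) || j > length(edges[[src]])) {
        stuck <- TRUE
        break
      }
      out[i] <- edges[[src]][j]
      counts[[src]] <- j
    }
    if (!stuck) return(paste(out, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find a complete walk")
}
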