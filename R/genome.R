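#' Annotated genome container
#'
#' Bundles reference sequences with typed gene features; the coordinate frame
#' for every downstream stage.
#'
#' @param sequences a named [Biostrings::DNAStringSet] of contigs.
#' @param features a [GenomicRanges::GRanges] with metadata columns `type`
#'   (CDS/tRNA/rRNA) and `gene_id`; strand must be `+` or `-`.
#' @return an object of class `annotated_genome`.
#' @export
annotated_genome <- function(sequences, features) {
  stopifnot(is(sequences, "DNAStringSet"), is(features, "GRanges"))
  if (is.null(names(sequences))) stop("contigs must be named")
  if (!all(c("type", "gene_id") %in% names(S4Vectors::mcols(features)))) {
    stop("features need 'type' and 'gene_id' metadata columns")
  }
  structure(list(sequences = sequences, features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome:", length(x$sequences), "contig(s),",
      sum(Biostrings::width(x$sequences)), "bp,",
      length(x$features), "features (",
      paste(names(table(x$features$type)), table(x$features$type),
            collapse = ", "), ")\n")
  invisible(x)
}

# sample a random codon with roughly the requested GC content, no stop codons
.sample_codons <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  stops <- c("TAA", "TAG", "TGA")
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- paste0(sample(DNA_BASES, length(need), TRUE, p),
                   sample(DNA_BASES, length(need), TRUE, p),
                   sample(DNA_BASES, length(need), TRUE, p))
    ok <- !(cand %in% stops)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic annotated bacterial genome
#'
#' Draws a random background sequence at the configured GC content and places
#' non-overlapping CDS on both strands (each an open reading frame: ATG start,
#' stop codon, no internal in-frame stops) plus short tRNA genes. Deterministic
#' for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an [annotated_genome()]; single contig named `"contig_1"`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(.child_seed(config$seed, 1L))
  gc <- config$gc_content
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bg <- sample(DNA_BASES, config$genome_length, TRUE, p)

  # gene lengths in codons
  lo <- config$gene_length_range[1] %/% 3L
  hi <- config$gene_length_range[2] %/% 3L
  n_cds <- config$n_genes
  cds_codons <- if (n_cds) {
    lo + sample.int(hi - lo + 1L, n_cds, replace = TRUE) - 1L
  } else integer(0)
  cds_len <- cds_codons * 3L
  trna_len <- rep(76L, config$n_trna)
  lens <- c(cds_len, trna_len)
  types <- c(rep("CDS", n_cds), rep("tRNA", config$n_trna))
  n_feat <- length(lens)

  # sequential placement with random gaps
  slack <- config$genome_length - sum(lens) - 10L * n_feat
  if (slack < 0L) stop("gene placement exceeds genome capacity")
  gaps <- if (n_feat) {
    g <- runif(n_feat)
    10L + floor(g / sum(g) * slack * 0.9)
  } else integer(0)
  starts <- integer(n_feat)
  cur <- 1L
  for (i in seq_len(n_feat)) {
    cur <- cur + gaps[i]
    starts[i] <- cur
    cur <- cur + lens[i]
  }
  strands <- if (n_feat) sample(c("+", "-"), n_feat, TRUE) else character(0)

  for (i in seq_len(n_feat)) {
    if (types[i] == "CDS") {
      body <- .sample_codons(cds_codons[i] - 2L, gc)
      orf <- paste0("ATG", paste(body, collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      s <- strsplit(orf, "")[[1]]
    } else {
      s <- sample(DNA_BASES, lens[i], TRUE, p)
    }
    if (strands[i] == "-") s <- rev(chartr("ACGT", "TGCA", s))
    bg[starts[i]:(starts[i] + lens[i] - 1L)] <- s
  }

  seqs <- Biostrings::DNAStringSet(paste(bg, collapse = ""))
  names(seqs) <- "contig_1"
  ids <- sprintf("%s_%03d", ifelse(types == "CDS", "gene", "trna"),
                 seq_len(n_feat))
  feats <- GenomicRanges::GRanges(
    seqnames = rep("contig_1", n_feat),
    ranges = IRanges::IRanges(start = starts, width = lens),
    strand = strands
  )
  feats$type <- types
  feats$gene_id <- ids
  annotated_genome(seqs, feats)
}

#' Write an annotated genome to FASTA + GFF3
#' @param genome an [annotated_genome()].
#' @param fasta_path,gff_path output file paths.
#' @return invisibly, the input genome.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  Biostrings::writeXStringSet(genome$sequences, fasta_path)
  gr <- genome$features
  gr$ID <- gr$gene_id
  # all CDS start in frame 0 by construction
  gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(genome)
}

#' Read an annotated genome from FASTA + GFF3
#' @param fasta_path,gff_path input file paths.
#' @return an [annotated_genome()].
#' @export
read_genome <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (is.null(gr$gene_id)) gr$gene_id <- gr$ID
  gr$type <- as.character(gr$type)
  keep <- c("type", "gene_id")
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep]
  annotated_genome(seqs, gr)
}

# contig sequence as plain character string
.contig_str <- function(genome, contig) {
  as.character(genome$sequences[[contig]])
}
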