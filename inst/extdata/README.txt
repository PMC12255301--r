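Optional external data
======================

supplementary_sites.tsv (not distributed with the package): an externally
obtained full-scale per-site table of A>G mismatches. When saved here, the
acceptance suite recomputes its classifier summaries with
summarize_site_table(). Required columns:

  context21   21-base coding-strand context, edited A at position 11
  rna_class   mRNA | tRNA | rRNA
  effect      synonymous | nonsynonymous | stop_gain | stop_loss (mRNA only)
  aa_ref      reference amino acid (one letter, mRNA only)
  aa_edited   edited amino acid (one letter, mRNA only)
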