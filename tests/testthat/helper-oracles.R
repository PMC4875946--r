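# Independent oracles and tiny fixture builders.  Oracles deliberately use
# a different computational path than the package (direct translation and
# enumeration) so agreement is informative.

oracle_translate <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

# brute-force effect call: translate both codons and compare
oracle_effect <- function(codon, offset, alt) {
  alt_codon <- codon
  substr(alt_codon, offset, offset) <- alt
  a1 <- oracle_translate(codon)
  a2 <- oracle_translate(alt_codon)
  if (a1 == a2) "synonymous" else "nonsynonymous"
}

# brute-force fractional site counts by enumerating all 9 changes
oracle_site_counts <- function(codon) {
  syn <- 0
  for (off in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, off, off))) {
      if (oracle_effect(codon, off, alt) == "synonymous") syn <- syn + 1
    }
  }
  c(syn = syn / 3, nonsyn = 3 - syn / 3)
}

# build a coding_sequence from a bare CDS string (single contig, + strand:
# the contig IS the CDS; for "-" the contig holds the reverse complement)
make_cds <- function(seq, gene_id = "g1", strand = "+") {
  contig <- if (strand == "+") seq else
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  extract_cds(stats::setNames(contig, "chrT"),
              gene_model(gene_id, paste0(gene_id, ".t"), "chrT",
                         strand, c(1L, nchar(seq))))
}

# write VCF lines (header + body rows given as character vector)
write_vcf_text <- function(rows, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}

# small standard synthetic bundle shared by several tests
small_sim <- function(seed = 5, n_genes = 30, theta = 0.03, ...) {
  cfg <- sim_config(n_genes = n_genes, aa_len_range = c(60L, 160L),
                    theta = theta, seed = seed, ...)
  prot <- generate_proteome(cfg)
  list(cfg = cfg, prot = prot)
}
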