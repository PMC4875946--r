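# Confounder controls: amino-acid composition matching between the two
# region classes (Pearson chi-square on the 2 x 20 residue table) and
# codon-usage bias via Wright's effective number of codons (ENC).

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# synonymous-family partition of the standard code (Met/Trp singletons
# excluded): 9 two-fold, 1 three-fold (Ile), 5 four-fold, 3 six-fold
CODON_FAMILIES <- list(
  `2` = list(Phe = c("TTT", "TTC"), Tyr = c("TAT", "TAC"),
             His = c("CAT", "CAC"), Gln = c("CAA", "CAG"),
             Asn = c("AAT", "AAC"), Lys = c("AAA", "AAG"),
             Asp = c("GAT", "GAC"), Glu = c("GAA", "GAG"),
             Cys = c("TGT", "TGC")),
  `3` = list(Ile = c("ATT", "ATC", "ATA")),
  `4` = list(Val = c("GTT", "GTC", "GTA", "GTG"),
             Pro = c("CCT", "CCC", "CCA", "CCG"),
             Thr = c("ACT", "ACC", "ACA", "ACG"),
             Ala = c("GCT", "GCC", "GCA", "GCG"),
             Gly = c("GGT", "GGC", "GGA", "GGG")),
  `6` = list(Leu = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
             Ser = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
             Arg = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")))

#' Amino-acid composition test between domain and unassigned regions
#'
#' Pearson chi-square (no continuity correction) on the 2 x 20 table of
#' residue counts per region; amino acids absent from both regions are
#' dropped, so the degrees of freedom are (number of observed amino
#' acids) - 1.  Proteins with an empty region are not testable.
#'
#' @param protein_seq Amino-acid sequence (single-letter codes), length
#'   `aa_len`.
#' @param partition The protein's [build_partition()].
#' @return Object of class `composition_test`: `table` (2 x k counts),
#'   `statistic`, `dof`, `p_value`, `keep` (`p >= alpha`), `alpha`.
#' @param alpha Significance level for the `keep` flag (default 0.05).
#' @export
aa_composition_test <- function(protein_seq, partition, alpha = 0.05) {
  aa <- strsplit(toupper(protein_seq), "")[[1]]
  if (length(aa) != attr(partition, "aa_len"))
    stop("aa_composition_test: sequence length does not match partition")
  reg <- assign_region(seq_along(aa), partition)
  if (!all(c("domain", "unassigned") %in% unique(reg)))
    stop("aa_composition_test: a region has zero residues; protein not testable")
  tab <- table(factor(reg, c("domain", "unassigned")), factor(aa, AA20))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) {
    stat <- 0; dof <- 0L; p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (any(ct$expected < 5))
      message("aa_composition_test: expected counts < 5 for ",
              attr(partition, "protein_id") %||% "protein")
    stat <- unname(ct$statistic); dof <- unname(ct$parameter)
    p <- ct$p.value
  }
  structure(list(protein_id = attr(partition, "protein_id"),
                 table = tab, statistic = stat, dof = dof, p_value = p,
                 keep = p >= alpha, alpha = alpha),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("composition_test %s: X2 = %.3f, df = %d, p = %.3g -> %s\n",
              x$protein_id %||% "?", x$statistic, x$dof, x$p_value,
              if (x$keep) "keep" else "exclude"))
  invisible(x)
}

# Wright's homozygosity estimator for one family's codon counts
family_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n <= 1) return(NA_real_)
  p <- counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC, `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, with the family
#' homozygosities `F̄` averaged over the observed families of each
#' degeneracy class (families with <= 1 codon, or a zero homozygosity
#' estimate, are excluded); a missing three-fold class (Ile absent) is
#' imputed as `(F̄2 + F̄4)/2`.  Values are capped at 61; genes with
#' `ENC > 50` are flagged unbiased.  Stop codons are excluded.
#'
#' @param cds A [extract_cds()] result or a bare CDS string (length a
#'   multiple of 3, internal-stop-free).
#' @return Object of class `enc_result`: `gene_id`, `enc` (in \[20, 61\],
#'   `NA` when undeterminable), `unbiased`, `flagged`.
#' @export
enc <- function(cds) {
  if (inherits(cds, "coding_sequence")) {
    seq_up <- toupper(cds$nt_seq)
    L <- 3L * cds$aa_len
    gid <- cds$gene_id
  } else {
    seq_up <- toupper(cds)
    L <- nchar(seq_up)
    if (L %% 3L != 0L) stop("enc: CDS length not a multiple of 3")
    last <- substring(seq_up, L - 2L, L)
    if (is_stop_codon(last)) L <- L - 3L
    gid <- NA_character_
  }
  if (L < 3L) stop("enc: empty CDS")
  idx <- seq_len(L %/% 3L)
  cods <- substring(seq_up, 3L * idx - 2L, 3L * idx)
  if (any(is_stop_codon(cods))) stop("enc: internal stop codon")
  counts <- table(factor(cods, sense_codons()))
  Fbar <- sapply(names(CODON_FAMILIES), function(deg) {
    fs <- vapply(CODON_FAMILIES[[deg]],
                 function(members) family_homozygosity(counts[members]),
                 numeric(1))
    fs <- fs[!is.na(fs) & fs > 0]
    if (length(fs)) mean(fs) else NA_real_
  })
  if (is.na(Fbar["3"]) && !is.na(Fbar["2"]) && !is.na(Fbar["4"]))
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  if (anyNA(Fbar)) {
    return(structure(list(gene_id = gid, enc = NA_real_, unbiased = NA,
                          flagged = TRUE), class = "enc_result"))
  }
  val <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] + 5 / Fbar[["4"]] +
    3 / Fbar[["6"]]
  val <- min(val, 61)
  structure(list(gene_id = gid, enc = val, unbiased = val > 50,
                 flagged = FALSE), class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("enc_result %s: ENC = %s%s\n", x$gene_id %||% "?",
              if (is.na(x$enc)) "NA" else sprintf("%.2f", x$enc),
              if (isTRUE(x$flagged)) " (flagged: too few families)" else ""))
  invisible(x)
}

#' Gene filters from the composition and codon-bias controls
#'
#' The two controls are applied independently (`mode = "composition"`:
#' keep genes whose regions do not differ in amino-acid composition at
#' `p >= 0.05`; `mode = "codon"`: keep genes with `ENC > 50`).
#'
#' @param tests List of [aa_composition_test()] results (used for
#'   `mode = "composition"`).
#' @param enc_results List of [enc()] results (for `mode = "codon"`).
#' @param mode `"composition"` or `"codon"`.
#' @return Character vector of retained gene/protein ids.
#' @export
filter_genes <- function(tests = NULL, enc_results = NULL,
                         mode = c("composition", "codon")) {
  mode <- match.arg(mode)
  if (mode == "composition") {
    keep <- vapply(tests, function(t) isTRUE(t$keep), logical(1))
    ids <- vapply(tests, function(t) t$protein_id %||% NA_character_,
                  character(1))
  } else {
    keep <- vapply(enc_results, function(e)
      !is.na(e$enc) && e$enc > 50, logical(1))
    ids <- vapply(enc_results, function(e) e$gene_id %||% NA_character_,
                  character(1))
  }
  ids[keep]
}

#' Translate a coding sequence to protein
#' @param cds A [extract_cds()] result.
#' @return Amino-acid string of length `aa_len` (terminal stop dropped).
#' @export
translate_cds <- function(cds) {
  if (cds$aa_len == 0L) return("")
  idx <- seq_len(cds$aa_len)
  cods <- substring(toupper(cds$nt_seq), 3L * idx - 2L, 3L * idx)
  paste(translate_codon(cods), collapse = "")
}
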