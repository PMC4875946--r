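# Survey of domain families devoid of SNPs: occurrence table, the
# randomization null for the zero-SNP count, domain-length comparison,
# and protein-length vs SNP-count correlations.

#' Per-accession domain occurrence table
#'
#' One row per domain accession across all supplied transcripts:
#' occurrence (number of hit instances), mean instance length, and
#' whether any instance harbours a SNP.
#'
#' @param hits data.frame of domain hits (`protein_id`, `accession`,
#'   `ali_start`, `ali_end`) across all transcripts.
#' @param variants_aa data.frame with `protein_id` and `aa_pos` for each
#'   classified variant.
#' @return data.frame with `accession`, `occurrence`, `mean_length`,
#'   `has_snp`.
#' @export
domain_occurrence_table <- function(hits, variants_aa) {
  if (!nrow(hits))
    return(data.frame(accession = character(0), occurrence = integer(0),
                      mean_length = numeric(0), has_snp = logical(0)))
  h <- data.table::as.data.table(hits)
  h[, inst := .I]
  hit_has <- rep(FALSE, nrow(h))
  if (!is.null(variants_aa) && nrow(variants_aa)) {
    v <- data.table::as.data.table(variants_aa)
    ov <- h[v, .(inst),
            on = .(protein_id, ali_start <= aa_pos, ali_end >= aa_pos),
            nomatch = NULL]
    hit_has[unique(ov$inst)] <- TRUE
  }
  h[, snp := hit_has]
  out <- h[, .(occurrence = .N,
               mean_length = mean(ali_end - ali_start + 1),
               has_snp = any(snp)), by = accession]
  as.data.frame(out[order(accession)])
}

#' Domain accessions devoid of SNPs
#'
#' An accession is SNP-free iff no variant falls inside any instance of
#' it in any transcript.
#'
#' @inheritParams domain_occurrence_table
#' @return The SNP-free rows of [domain_occurrence_table()].
#' @export
zero_snp_domains <- function(hits, variants_aa) {
  tab <- domain_occurrence_table(hits, variants_aa)
  tab[!tab$has_snp, , drop = FALSE]
}

#' Randomization null for the number of SNP-free domains
#'
#' Each replicate throws the N observed SNPs uniformly at random over all
#' protein residues (positions independent within a replicate) and
#' recomputes the number of SNP-free domain accessions and the mean
#' occurrence of that set.  Empirical p-values use the >= convention
#' (`p_count`: zero-SNP count >= observed; `p_occurrence`: mean
#' occurrence of the zero-SNP set >= observed); `+1/(n+1)`-corrected
#' variants are reported alongside.
#'
#' @param protein_lengths Named integer vector, residues per protein.
#' @param hits Domain hits across all transcripts (as in
#'   [domain_occurrence_table()]).
#' @param variants_aa Observed variants (`protein_id`, `aa_pos`); N is
#'   taken as `nrow(variants_aa)`.
#' @param n_reps Replicates (default 1000).
#' @param seed Integer seed.
#' @param per_protein Preserve per-protein SNP totals instead of pooling
#'   all proteins (alternative null; default `FALSE`, pooled-uniform).
#' @return Object of class `randomization_result`.
#' @export
randomization_test <- function(protein_lengths, hits, variants_aa,
                               n_reps = 1000L, seed = 1L,
                               per_protein = FALSE) {
  if (!length(protein_lengths) || sum(protein_lengths) == 0)
    stop("randomization_test: empty proteome")
  stopifnot(n_reps >= 1)
  N <- nrow(variants_aa)
  obs <- zero_snp_domains(hits, variants_aa)
  obs_count <- nrow(obs)
  obs_occ <- if (obs_count) mean(obs$occurrence) else 0
  # global residue coordinates
  prot <- names(protein_lengths)
  offs <- c(0L, cumsum(as.integer(protein_lengths)))
  total <- offs[length(offs)]
  h <- hits
  pidx <- match(h$protein_id, prot)
  if (anyNA(pidx))
    stop("randomization_test: hit protein absent from protein_lengths")
  gs <- offs[pidx] + h$ali_start
  ge <- offs[pidx] + h$ali_end
  acc_f <- factor(h$accession)
  occ_all <- as.integer(table(acc_f))
  # observed per-protein totals for the per-protein-preserving variant
  v_per <- if (per_protein) table(factor(variants_aa$protein_id, prot))
           else NULL
  rep_count <- integer(n_reps)
  rep_occ <- numeric(n_reps)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      pos <- if (per_protein) {
        unlist(lapply(which(v_per > 0), function(k)
          offs[k] + sample.int(protein_lengths[k], v_per[k], replace = TRUE)),
          use.names = FALSE)
      } else {
        sample.int(total, N, replace = TRUE)
      }
      spos <- sort(pos)
      inst_hit <- findInterval(ge, spos) > findInterval(gs - 1L, spos)
      acc_hit <- tapply(inst_hit, acc_f, any)
      zero <- !acc_hit
      rep_count[b] <- sum(zero)
      rep_occ[b] <- if (any(zero)) mean(occ_all[zero]) else 0
    }
  })
  p_count <- mean(rep_count >= obs_count)
  p_occ <- mean(rep_occ >= obs_occ)
  structure(list(N = N, n_reps = as.integer(n_reps),
                 observed_zero_count = obs_count,
                 observed_mean_occurrence = obs_occ,
                 replicate_zero_counts = rep_count,
                 replicate_mean_occurrence = rep_occ,
                 p_count = p_count, p_occurrence = p_occ,
                 p_count_corrected = (sum(rep_count >= obs_count) + 1) /
                   (n_reps + 1),
                 p_occurrence_corrected = (sum(rep_occ >= obs_occ) + 1) /
                   (n_reps + 1),
                 seed = as.integer(seed), per_protein = per_protein),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(paste0("randomization_result: N = %d, observed zero-SNP",
                     " domains = %d (mean occurrence %.2f)\n",
                     "  p_count = %.4g, p_occurrence = %.4g (%d reps)\n"),
              x$N, x$observed_zero_count, x$observed_mean_occurrence,
              x$p_count, x$p_occurrence, x$n_reps))
  invisible(x)
}

#' Compare domain lengths with and without SNPs
#'
#' Medians plus a two-sided Mann-Whitney (Wilcoxon rank-sum) test;
#' exact p for small untied samples, normal approximation with tie
#' correction otherwise.
#'
#' @param lengths_with,lengths_without Length samples (amino acids).
#' @return List with `median_with`, `median_without`, `U`, `p_value`.
#' @export
length_comparison <- function(lengths_with, lengths_without) {
  if (!length(lengths_with) || !length(lengths_without))
    stop("length_comparison: both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(lengths_with, lengths_without,
                                            alternative = "two.sided"))
  list(median_with = stats::median(lengths_with),
       median_without = stats::median(lengths_without),
       U = unname(wt$statistic), p_value = wt$p.value)
}

#' Spearman correlations between protein length and SNP counts
#'
#' One correlation per effect x MAF class: Spearman's rho with
#' average-rank ties and the corresponding test p-value.
#'
#' @param per_gene data.frame with `cds_length` plus count columns named
#'   `<effect>_<class>` (effects `nonsynonymous`/`synonymous`; classes
#'   `rare`/`low`/`common`), e.g. from [length_snp_table()].
#' @return data.frame rows = effects, with `rho_*` and `p_*` columns; a
#'   constant count vector yields `NA` with a message.
#' @export
length_snp_correlation <- function(per_gene) {
  if (nrow(per_gene) < 3) stop("length_snp_correlation: need >= 3 genes")
  effects <- c("nonsynonymous", "synonymous")
  classes <- c("rare", "low", "common")
  out <- data.frame(effect = effects, stringsAsFactors = FALSE)
  for (cls in classes) {
    rho <- p <- rep(NA_real_, 2)
    for (k in 1:2) {
      col <- paste0(effects[k], "_", cls)
      y <- per_gene[[col]]
      if (is.null(y)) next
      if (length(unique(y)) < 2 || length(unique(per_gene$cds_length)) < 2) {
        message("length_snp_correlation: constant input for ", col,
                "; rho undefined")
        next
      }
      ct <- suppressWarnings(stats::cor.test(per_gene$cds_length, y,
                                             method = "spearman"))
      rho[k] <- unname(ct$estimate); p[k] <- ct$p.value
    }
    out[[paste0("rho_", cls)]] <- rho
    out[[paste0("p_", cls)]] <- p
  }
  out
}

#' Per-gene SNP count table for the length correlation
#'
#' @param classified [classify_variants()] output.
#' @param cds_set Named list of coding sequences (provides lengths, and
#'   genes with zero SNPs).
#' @return data.frame with `gene_id`, `cds_length` and the six
#'   effect x class count columns.
#' @export
length_snp_table <- function(classified, cds_set) {
  genes <- names(cds_set)
  out <- data.frame(gene_id = genes,
                    cds_length = vapply(cds_set, function(cs)
                      3L * cs$aa_len, integer(1)),
                    stringsAsFactors = FALSE)
  for (eff in c("nonsynonymous", "synonymous"))
    for (cls in c("rare", "low", "common")) {
      sel <- classified$effect == eff & classified$maf_class == cls
      cnt <- table(factor(classified$gene_id[sel], genes))
      out[[paste0(eff, "_", cls)]] <- as.integer(cnt)
    }
  rownames(out) <- NULL
  out
}
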