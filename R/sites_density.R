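# Fractional synonymous / non-synonymous site counting (unweighted
# Nei-Gojobori) and the Fisher-exact density contrast between domain and
# unassigned regions.

#' Synonymous and non-synonymous site counts of a codon
#'
#' Unweighted Nei-Gojobori fractional counting: at each codon position the
#' fraction of its three possible single-base changes that are synonymous
#' contributes to the synonymous site count, the remainder to the
#' non-synonymous count; the two always sum to exactly 3.  Changes that
#' create a stop codon count as non-synonymous.
#'
#' @param codon A sense codon (3 uppercase DNA letters).
#' @return Named numeric vector `c(syn, nonsyn)`.
#' @examples
#' codon_site_counts("TTT")  # c(syn = 1/3, nonsyn = 8/3)
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (is_stop_codon(codon)) stop("codon_site_counts: stop codon")
  tab <- site_count_table()
  unlist(tab[codon, ])
}

# per-codon site counts for all 61 sense codons, derived once from
# classify_effect so the genetic code is applied in a single place
site_count_table <- function() {
  if (!is.null(.domseln_cache$site_counts)) return(.domseln_cache$site_counts)
  cods <- sense_codons()
  syn <- vapply(cods, function(cod) {
    s <- 0
    for (off in 1:3)
      for (alt in setdiff(BASES, substr(cod, off, off)))
        if (classify_effect(cod, off, alt) == "synonymous") s <- s + 1
    s / 3
  }, numeric(1))
  .domseln_cache$site_counts <- data.frame(syn = syn, nonsyn = 3 - syn,
                                           row.names = cods)
  .domseln_cache$site_counts
}

#' Region-wise site counts of a coding sequence
#'
#' Sums [codon_site_counts()] over codons grouped by the region label of
#' their residue; the terminal stop codon is excluded.
#'
#' @param cds A [extract_cds()] result.
#' @param partition The protein's [build_partition()].
#' @return data.frame with rows `domain` and `unassigned`, columns
#'   `syn_sites`, `nonsyn_sites`, `n_codons`.
#' @export
region_site_counts <- function(cds, partition) {
  out <- data.frame(region = c("domain", "unassigned"), syn_sites = 0,
                    nonsyn_sites = 0, n_codons = 0L,
                    stringsAsFactors = FALSE)
  if (cds$aa_len == 0L) return(out)
  seq_up <- toupper(cds$nt_seq)
  idx <- seq_len(cds$aa_len)
  cods <- substring(seq_up, 3L * idx - 2L, 3L * idx)
  reg <- assign_region(idx, partition)
  tab <- site_count_table()
  sc <- tab[cods, ]
  for (r in c("domain", "unassigned")) {
    sel <- reg == r
    out[out$region == r, 2:4] <- c(sum(sc$syn[sel]), sum(sc$nonsyn[sel]),
                                   sum(sel))
  }
  out
}

#' SNP-density contrast between domain and unassigned regions
#'
#' Builds the 2x2 table `[SNPs, sites - SNPs]` for the two regions and
#' reports the sample odds ratio (a*d)/(b*c) — the density ratio — with a
#' two-sided Fisher exact p-value.  Real-valued site totals are rounded
#' half-up to integers for the exact test.  The conditional-MLE odds ratio
#' printed by [stats::fisher.test()] is exposed alongside.
#'
#' @param snp_dom,snp_un SNP counts in domain / unassigned regions.
#' @param sites_dom,sites_un Site counts (real) per region.
#' @return Object of class `density_result`: list with `odds_ratio`
#'   (sample OR), `or_cmle`, `p_value`, `table`.
#' @export
density_test <- function(snp_dom, snp_un, sites_dom, sites_un) {
  if (sites_dom <= 0 || sites_un <= 0)
    stop("density_test: site totals must be positive")
  sd_i <- round_half_up(sites_dom); su_i <- round_half_up(sites_un)
  if (snp_dom > sd_i || snp_un > su_i)
    stop("density_test: SNP count exceeds site count")
  tab <- matrix(c(snp_dom, sd_i - snp_dom, snp_un, su_i - snp_un),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("domain", "unassigned"),
                                c("snp", "non_snp")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  ft <- stats::fisher.test(tab)
  structure(list(odds_ratio = or, or_cmle = unname(ft$estimate),
                 p_value = ft$p.value, table = tab),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("density_result: OR = %.4f (CMLE %.4f), p = %.3g\n",
              x$odds_ratio, x$or_cmle, x$p_value))
  invisible(x)
}

#' Density contrasts for every effect and frequency class
#'
#' Runs [density_test()] for synonymous and non-synonymous variants,
#' overall and per MAF class, and (when divergence records are supplied)
#' for fixed differences — the full set of panels of the density figure.
#'
#' @param classified [classify_variants()] output.
#' @param site_totals Aggregate site counts: data.frame with `region`,
#'   `syn_sites`, `nonsyn_sites` (summed [region_site_counts()]).
#' @param divergence Optional divergence records with `region`, `effect`.
#' @return data.frame with one row per effect x class contrast.
#' @export
density_table <- function(classified, site_totals, divergence = NULL) {
  sdom <- site_totals[site_totals$region == "domain", ]
  sun <- site_totals[site_totals$region == "unassigned", ]
  rows <- list()
  pull <- function(df, eff, cls) {
    n <- df[df$effect == eff &
              (cls == "all" | df$.cls == cls), , drop = FALSE]
    c(dom = sum(n$region == "domain"), un = sum(n$region == "unassigned"))
  }
  run <- function(df, kind, eff, cls) {
    sites <- if (eff == "synonymous") c(sdom$syn_sites, sun$syn_sites)
             else c(sdom$nonsyn_sites, sun$nonsyn_sites)
    cnt <- pull(df, eff, cls)
    dt <- density_test(cnt["dom"], cnt["un"], sites[1], sites[2])
    data.frame(kind = kind, effect = eff, class = cls,
               snp_dom = cnt[["dom"]], snp_un = cnt[["un"]],
               sites_dom = sites[1], sites_un = sites[2],
               odds_ratio = dt$odds_ratio, p_value = dt$p_value,
               stringsAsFactors = FALSE)
  }
  cl <- classified; cl$.cls <- cl$maf_class
  for (eff in c("nonsynonymous", "synonymous")) {
    for (cls in c("all", "rare", "low", "common"))
      rows[[paste("poly", eff, cls)]] <- run(cl, "polymorphism", eff, cls)
  }
  if (!is.null(divergence) && nrow(divergence)) {
    dv <- divergence; dv$.cls <- "all"
    for (eff in c("nonsynonymous", "synonymous"))
      rows[[paste("div", eff)]] <- run(dv, "divergence", eff, "all")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
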