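# Mapping variants onto codons; effect / region / MAF-class assignment;
# fixed-divergence calling against an ancestral sequence; and the
# region x effect x frequency-class count table that feeds the density
# and Direction-of-Selection analyses.

#' Minor-allele-frequency class
#'
#' Classes: rare (MAF < 0.5%), low (0.5% <= MAF <= 5%, boundaries
#' inclusive), common (MAF > 5%).
#'
#' @param maf Minor allele frequency in (0, 0.5] (vectorised).
#' @param breaks The two thresholds, default `c(0.005, 0.05)`.
#' @return Character vector in `{"rare", "low", "common"}`.
#' @export
maf_class <- function(maf, breaks = c(0.005, 0.05)) {
  if (any(maf <= 0))
    stop("maf_class: maf must be > 0 (monomorphic/fixed sites are not classifiable)")
  if (any(maf > 0.5)) stop("maf_class: maf must be <= 0.5")
  ifelse(maf < breaks[1], "rare", ifelse(maf <= breaks[2], "low", "common"))
}

#' Region label of an amino-acid position
#'
#' @param aa_position Residue index, 1-based (vectorised).
#' @param partition A [build_partition()] result.
#' @return `"domain"` or `"unassigned"` per position.
#' @export
assign_region <- function(aa_position, partition) {
  aa_len <- attr(partition, "aa_len")
  if (any(aa_position < 1 | aa_position > aa_len))
    stop("assign_region: position outside 1..", aa_len)
  idx <- findInterval(aa_position, partition$aa_start)
  lab <- partition$label[idx]
  bad <- aa_position > partition$aa_end[idx]
  if (any(bad)) stop("assign_region: partition does not tile the protein")
  lab
}

#' Classify population variants against coding sequences
#'
#' Joins genomic SNVs to CDS positions through each gene model's genomic
#' map (strand-aware: ref/alt are complemented for minus-strand genes),
#' then assigns effect, region and MAF class per variant.  Variants in the
#' terminal stop codon are excluded; variants whose (oriented) reference
#' base disagrees with the extracted CDS base are skipped and counted in
#' the QC attribute.  Monomorphic records (MAF 0) are skipped.
#'
#' @param variants data.frame from [read_variants()].
#' @param cds_set Named list of [extract_cds()] results (names = gene id).
#' @param partitions Named list of [build_partition()] results keyed like
#'   `cds_set`.
#' @return data.frame of classified variants (columns `chrom`, `pos`,
#'   `ref`, `alt`, `gene_id`, `cds_pos`, `codon_index`, `offset_in_codon`,
#'   `ref_codon`, `alt_codon`, `effect`, `region`, `maf`, `maf_class`,
#'   `aa_pos`); attribute `qc` lists skip counts by reason.
#' @export
classify_variants <- function(variants, cds_set, partitions) {
  maps <- data.table::rbindlist(lapply(cds_set, function(cs) {
    L <- 3L * cs$aa_len
    if (L == 0L) return(NULL)
    data.table::data.table(chrom = cs$chrom, pos = cs$genomic_map[seq_len(L)],
                           gene_id = cs$gene_id, cds_pos = seq_len(L),
                           strand = cs$strand)
  }))
  v <- data.table::as.data.table(variants)
  qc <- c(noncoding = 0L, ref_mismatch = 0L, monomorphic = 0L)
  if (nrow(v) == 0L || nrow(maps) == 0L) {
    out <- data.frame()
    attr(out, "qc") <- qc
    return(out)
  }
  m <- merge(v, maps, by = c("chrom", "pos"))
  qc["noncoding"] <- nrow(v) - nrow(m)
  mono <- m$maf <= 0
  qc["monomorphic"] <- sum(mono)
  m <- m[!mono]
  if (nrow(m) == 0L) {
    out <- data.frame()
    attr(out, "qc") <- qc
    return(out)
  }
  flip <- m$strand == "-"
  m[, `:=`(ref_cds = ifelse(flip, complement_chr(ref), ref),
           alt_cds = ifelse(flip, complement_chr(alt), alt))]
  m[, `:=`(codon_index = (cds_pos - 1L) %/% 3L + 1L,
           offset_in_codon = (cds_pos - 1L) %% 3L + 1L)]
  seqs <- vapply(cds_set, function(cs) toupper(cs$nt_seq), character(1))
  m[, ref_codon := substring(seqs[gene_id], 3L * codon_index - 2L,
                             3L * codon_index)]
  cds_base <- substring(m$ref_codon, m$offset_in_codon, m$offset_in_codon)
  mism <- cds_base != m$ref_cds
  qc["ref_mismatch"] <- sum(mism)
  m <- m[!mism]
  if (nrow(m) == 0L) {
    out <- data.frame()
    attr(out, "qc") <- qc
    return(out)
  }
  lk <- effect_lookup()
  m[, effect := unname(lk[paste0(ref_codon, offset_in_codon, alt_cds)])]
  m[, alt_codon := {
    ac <- ref_codon
    substr(ac, offset_in_codon, offset_in_codon) <- alt_cds
    ac
  }, by = seq_len(nrow(m))]
  m[, region := assign_region(codon_index, partitions[[gene_id[1]]]),
    by = gene_id]
  m[, maf_class := maf_class(maf)]
  m[, aa_pos := codon_index]
  out <- as.data.frame(m[, .(chrom, pos, ref, alt, allele_number, alt_count,
                             gene_id, cds_pos, codon_index, offset_in_codon,
                             ref_codon, alt_codon, effect, region, maf,
                             maf_class, aa_pos)])
  attr(out, "qc") <- qc
  out
}

#' Call fixed human-ancestor divergences on one coding sequence
#'
#' A position yields a divergence record when the (uppercased) human and
#' ancestral bases differ, the ancestral call is high-confidence (upper
#' case, or `TRUE` in `confidence_mask`), outgroup information is present
#' (ancestral base in A/C/G/T), and the position is not polymorphic.  The
#' effect is the human-derived change: the human base substituted into the
#' ancestral codon context; codons with several divergent sites are
#' classified one at a time, left to right.  Terminal stop codons are
#' excluded.
#'
#' @param cds A [extract_cds()] result (human).
#' @param ancestral_cds Ancestral CDS as a character string, aligned
#'   position-wise to `cds$nt_seq` (case carries confidence) — or a
#'   `coding_sequence` extracted from the ancestral genome.
#' @param confidence_mask Optional logical vector, `TRUE` = high
#'   confidence; default derives from upper case in `ancestral_cds`.
#' @param polymorphic_positions Integer CDS positions polymorphic in the
#'   population sample.
#' @return data.frame with columns `gene_id`, `cds_pos`, `aa_pos`,
#'   `ancestral_base`, `derived_base`, `effect`.
#' @export
call_fixed_divergence <- function(cds, ancestral_cds,
                                  confidence_mask = NULL,
                                  polymorphic_positions = integer(0)) {
  anc <- if (inherits(ancestral_cds, "coding_sequence")) ancestral_cds$nt_seq
         else ancestral_cds
  if (nchar(anc) != nchar(cds$nt_seq))
    stop("call_fixed_divergence: sequence length mismatch (",
         nchar(cds$nt_seq), " vs ", nchar(anc), ")")
  L <- 3L * cds$aa_len
  if (L == 0L) return(empty_divergence())
  hum_v <- strsplit(toupper(substring(cds$nt_seq, 1L, L)), "")[[1]]
  anc_raw <- strsplit(substring(anc, 1L, L), "")[[1]]
  anc_v <- toupper(anc_raw)
  if (is.null(confidence_mask)) {
    confidence_mask <- anc_raw == anc_v  # upper case = high confidence
  } else {
    confidence_mask <- confidence_mask[seq_len(L)]
  }
  diff <- which(hum_v != anc_v & confidence_mask & anc_v %in% BASES &
                  !(seq_len(L) %in% polymorphic_positions))
  if (!length(diff)) return(empty_divergence())
  rows <- lapply(sort(diff), function(p) {
    cod_i <- (p - 1L) %/% 3L + 1L
    off <- (p - 1L) %% 3L + 1L
    anc_cod <- paste(anc_v[(3L * cod_i - 2L):(3L * cod_i)], collapse = "")
    if (is_stop_codon(anc_cod) || !all(strsplit(anc_cod, "")[[1]] %in% BASES))
      return(NULL)  # unclassifiable ancestral context
    data.frame(gene_id = cds$gene_id, cds_pos = p, aa_pos = cod_i,
               ancestral_base = anc_v[p], derived_base = hum_v[p],
               effect = classify_effect(anc_cod, off, hum_v[p]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_divergence())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_divergence <- function() {
  data.frame(gene_id = character(0), cds_pos = integer(0),
             aa_pos = integer(0), ancestral_base = character(0),
             derived_base = character(0), effect = character(0))
}

#' Cross-tabulate polymorphism and divergence counts
#'
#' Builds the region x effect x class count table, classes being the
#' three MAF strata plus `fixed` for divergences.  `Pn`/`Ps` per region
#' are the sums over polymorphic classes; `Dn`/`Ds` are the fixed cells.
#'
#' @param classified data.frame from [classify_variants()] (needs
#'   `region`, `effect`, `maf_class`), or `NULL`.
#' @param divergence data.frame with `region` and `effect` columns (e.g.
#'   [call_fixed_divergence()] output joined to regions), or `NULL`.
#' @return Object of class `counts_table`: data.frame with one row per
#'   region x effect x class and a `count` column.
#' @export
tabulate_counts <- function(classified = NULL, divergence = NULL) {
  grid <- expand.grid(region = c("domain", "unassigned"),
                      effect = c("nonsynonymous", "synonymous"),
                      class = c("rare", "low", "common", "fixed"),
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  add <- function(grid, df, cls) {
    if (is.null(df) || nrow(df) == 0) return(grid)
    key <- paste(df$region, df$effect, cls)
    tab <- table(key)
    gkey <- paste(grid$region, grid$effect, grid$class)
    hit <- match(names(tab), gkey)
    if (anyNA(hit)) stop("tabulate_counts: unknown region/effect label")
    grid$count[hit] <- grid$count[hit] + as.integer(tab)
    grid
  }
  if (!is.null(classified) && nrow(classified))
    grid <- add(grid, classified, classified$maf_class)
  if (!is.null(divergence) && nrow(divergence))
    grid <- add(grid, divergence, "fixed")
  structure(grid, class = c("counts_table", "data.frame"))
}

#' Construct a counts table from explicit cells
#'
#' Convenience constructor for printed tables: supply counts per
#' region x effect x class.
#'
#' @param cells data.frame with columns `region`, `effect`, `class`,
#'   `count`.
#' @return A `counts_table`.
#' @export
counts_table <- function(cells) {
  stopifnot(all(c("region", "effect", "class", "count") %in% names(cells)))
  if (any(cells$count < 0)) stop("counts_table: negative cell")
  structure(as.data.frame(cells), class = c("counts_table", "data.frame"))
}

#' Marginal Pn/Ps/Dn/Ds sums of a counts table
#'
#' @param ct A `counts_table`.
#' @param region `"domain"`, `"unassigned"`, or `"all"` (summed).
#' @return Named numeric vector with `Pn`, `Ps`, `Dn`, `Ds`.
#' @export
counts_marginals <- function(ct, region = "all") {
  sel <- if (region == "all") rep(TRUE, nrow(ct)) else ct$region == region
  poly <- ct$class %in% c("rare", "low", "common")
  c(Pn = sum(ct$count[sel & poly & ct$effect == "nonsynonymous"]),
    Ps = sum(ct$count[sel & poly & ct$effect == "synonymous"]),
    Dn = sum(ct$count[sel & ct$class == "fixed" &
                        ct$effect == "nonsynonymous"]),
    Ds = sum(ct$count[sel & ct$class == "fixed" &
                        ct$effect == "synonymous"]))
}

#' @export
print.counts_table <- function(x, ...) {
  cat("counts_table (region x effect x class)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a counts table as TSV and JSON
#' @param ct A `counts_table`.
#' @param stem Output path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @export
write_counts_table <- function(ct, stem) {
  write_tsv(as.data.frame(ct), paste0(stem, ".tsv"))
  jsonlite::write_json(list(cells = as.data.frame(ct),
                            marginals = list(
                              domain = as.list(counts_marginals(ct, "domain")),
                              unassigned = as.list(counts_marginals(ct, "unassigned")),
                              all = as.list(counts_marginals(ct, "all")))),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
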