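# Core domain types and readers/writers for the standard formats the
# pipeline consumes: genome/ancestral FASTA, GFF3/GTF gene models (CDS
# features), VCF SNVs, and pfam_scan-style domain-hit TSV.
#
# Coordinate conventions: genomic and amino-acid coordinates are 1-based
# inclusive everywhere (GFF/VCF convention); CDS positions are 1-based along
# the spliced, strand-corrected coding sequence.

# ---- GeneModel ----------------------------------------------------------

#' Construct a gene model
#'
#' A gene model is one principal transcript: an ordered set of genomic CDS
#' intervals (1-based, inclusive), a strand, and the phase of the first CDS
#' segment in transcript orientation.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals Two-column matrix (start, end), genomic coordinates.
#' @param phase Phase of the 5'-most CDS segment, 0, 1 or 2.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, cds_intervals,
                       phase = 0L) {
  cds_intervals <- matrix(as.integer(cds_intervals), ncol = 2,
                          dimnames = list(NULL, c("start", "end")))
  cds_intervals <- cds_intervals[order(cds_intervals[, 1]), , drop = FALSE]
  if (any(cds_intervals[, 2] < cds_intervals[, 1]))
    stop("gene_model: interval end precedes start for ", transcript_id)
  if (nrow(cds_intervals) > 1 &&
      any(cds_intervals[-1, 1] <= cds_intervals[-nrow(cds_intervals), 2]))
    stop("gene_model: overlapping CDS intervals for ", transcript_id)
  if (!strand %in% c("+", "-")) stop("gene_model: bad strand")
  if (!phase %in% 0:2) stop("gene_model: bad phase")
  len <- sum(cds_intervals[, 2] - cds_intervals[, 1] + 1L) - as.integer(phase)
  if (len %% 3L != 0L)
    stop("gene_model: CDS length ", len, " not a multiple of 3 for ",
         transcript_id)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand,
                 cds_intervals = cds_intervals, phase = as.integer(phase)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "(", x$transcript_id, ")", x$chrom, x$strand,
      nrow(x$cds_intervals), "CDS segment(s),",
      sum(x$cds_intervals[, 2] - x$cds_intervals[, 1] + 1), "nt\n")
  invisible(x)
}

#' Read gene models from GFF3 or GTF
#'
#' Retains CDS features, groups them by transcript, and validates each
#' model: intervals must be sorted and non-overlapping and the total CDS
#' length (after phase adjustment) must be a multiple of 3.  Models failing
#' validation are skipped with a logged reason (attribute `"skipped"`).
#'
#' @param path GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @return Named list of [gene_model()] objects (class `gene_model_set`),
#'   keyed by transcript id, with a `skipped` attribute data frame.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0) stop("read_gene_models: no CDS features in ", path)
  meta <- S4Vectors::mcols(gr)
  tx <- if ("transcript_id" %in% names(meta)) as.character(meta$transcript_id)
        else if ("Parent" %in% names(meta))
          vapply(meta$Parent, function(p) as.character(p)[1], character(1))
        else stop("read_gene_models: CDS features lack transcript ids")
  gene <- if ("gene_id" %in% names(meta)) as.character(meta$gene_id)
          else if ("gene" %in% names(meta)) as.character(meta$gene)
          else tx
  phase <- if ("phase" %in% names(meta)) suppressWarnings(as.integer(meta$phase))
           else rep(NA_integer_, length(gr))
  df <- data.frame(tx = tx, gene = gene,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   phase = phase, stringsAsFactors = FALSE)
  out <- list(); skipped <- list()
  for (t in unique(df$tx)) {
    d <- df[df$tx == t, , drop = FALSE]
    strand <- d$strand[1]
    d <- d[order(d$start), , drop = FALSE]
    first <- if (strand == "-") nrow(d) else 1L
    ph <- d$phase[first]
    if (is.na(ph)) ph <- 0L
    m <- tryCatch(
      gene_model(d$gene[1], t, d$chrom[1], strand,
                 cbind(d$start, d$end), ph),
      error = function(e) conditionMessage(e))
    if (is.character(m)) {
      skipped[[length(skipped) + 1L]] <- data.frame(transcript_id = t,
                                                    reason = m)
      message("read_gene_models: skipping ", t, ": ", m)
    } else out[[t]] <- m
  }
  structure(out, class = "gene_model_set",
            skipped = if (length(skipped)) do.call(rbind, skipped)
                      else data.frame(transcript_id = character(0),
                                      reason = character(0)))
}

#' Write gene models as GFF3
#'
#' @param models A `gene_model_set` or list of [gene_model()] objects.
#' @param path Output GFF3 path.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    n <- nrow(m$cds_intervals)
    # per-segment phase along transcript orientation
    lens <- m$cds_intervals[, 2] - m$cds_intervals[, 1] + 1L
    ord <- if (m$strand == "-") rev(seq_len(n)) else seq_len(n)
    ph <- integer(n)
    carry <- m$phase
    for (k in ord) {
      ph[k] <- carry
      carry <- (3L - ((lens[k] - carry) %% 3L)) %% 3L
    }
    data.frame(seqid = m$chrom, source = "domseln", type = "CDS",
               start = m$cds_intervals[, 1], end = m$cds_intervals[, 2],
               score = ".", strand = m$strand, phase = ph,
               attributes = paste0("ID=CDS:", m$transcript_id,
                                   ";Parent=", m$transcript_id,
                                   ";transcript_id=", m$transcript_id,
                                   ";gene_id=", m$gene_id),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- FASTA --------------------------------------------------------------

#' Read a FASTA file as named character strings
#'
#' Case is preserved (lower case marks low-confidence calls in ancestral
#' sequences, mirroring the 1000 Genomes convention).
#'
#' @param path FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

# ---- CodingSequence -----------------------------------------------------

#' Extract a spliced, strand-corrected coding sequence
#'
#' Splices the CDS intervals of a gene model out of the genome, reverse
#' complements on the minus strand, trims the leading phase bases, and
#' builds the CDS-position to genomic-position map.  The terminal stop
#' codon, when present, is retained in `nt_seq` but excluded from `aa_len`
#' (and hence from all downstream counting windows).  An internal stop
#' codon is an error unless `check_stops = FALSE` (used for ancestral
#' sequences, which may legitimately differ).
#'
#' @param genome Named character vector from [read_fasta()] (or a path).
#' @param model A [gene_model()].
#' @param check_stops Error on internal stop codons (default `TRUE`).
#' @return Object of class `coding_sequence`: fields `gene_id`, `nt_seq`,
#'   `aa_len`, `chrom`, `strand`, and `genomic_map` (integer vector, genomic
#'   position of each CDS position).
#' @export
extract_cds <- function(genome, model, check_stops = TRUE) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_fasta(genome)
  if (!model$chrom %in% names(genome))
    stop("extract_cds: chromosome ", model$chrom, " not in FASTA")
  contig <- genome[[model$chrom]]
  iv <- model$cds_intervals
  if (any(iv[, 1] < 1L) || any(iv[, 2] > nchar(contig)))
    stop("extract_cds: CDS interval out of contig bounds for ",
         model$transcript_id)
  pieces <- substring(contig, iv[, 1], iv[, 2])
  seq <- paste(pieces, collapse = "")
  map <- unlist(lapply(seq_len(nrow(iv)), function(k) iv[k, 1]:iv[k, 2]),
                use.names = FALSE)
  if (model$strand == "-") {
    seq <- revcomp_chr(seq)
    map <- rev(map)
  }
  if (model$phase > 0L) {
    seq <- substring(seq, model$phase + 1L)
    map <- map[-seq_len(model$phase)]
  }
  L <- nchar(seq)
  if (L %% 3L != 0L) stop("extract_cds: CDS length not a multiple of 3")
  codons <- substring(toupper(seq), seq(1L, L - 2L, 3L), seq(3L, L, 3L))
  n_cod <- length(codons)
  has_stop <- is_stop_codon(codons[n_cod])
  aa_len <- if (has_stop) n_cod - 1L else n_cod
  if (check_stops && aa_len > 0 && any(is_stop_codon(codons[seq_len(aa_len)])))
    stop("extract_cds: internal stop codon in ", model$transcript_id)
  structure(list(gene_id = model$gene_id, transcript_id = model$transcript_id,
                 chrom = model$chrom, strand = model$strand,
                 nt_seq = seq, aa_len = aa_len, genomic_map = map),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("coding_sequence", x$gene_id, ":", nchar(x$nt_seq), "nt,",
      x$aa_len, "aa,", x$strand, "strand\n")
  invisible(x)
}

# ---- Domain hits and region partitions ----------------------------------

#' Read pfam_scan-style domain hits
#'
#' Accepts a TSV with (at least) columns `protein_id`, `ali_start`,
#' `ali_end`, `accession`, `e_value`; alignment coordinates are amino-acid,
#' 1-based inclusive.  Hits above the E-value threshold are dropped at read
#' time.
#'
#' @param path TSV path.
#' @param e_max E-value acceptance threshold (default `1e-3`).
#' @return data.frame of retained hits.
#' @export
read_domain_hits <- function(path, e_max = 1e-3) {
  d <- read_tsv(path)
  need <- c("protein_id", "ali_start", "ali_end", "accession", "e_value")
  if (!all(need %in% names(d)))
    stop("read_domain_hits: missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d <- d[, need]
  if (any(d$e_value < 0)) stop("read_domain_hits: negative E-value")
  if (any(d$ali_start < 1 | d$ali_end < d$ali_start))
    stop("read_domain_hits: malformed alignment coordinates")
  d[d$e_value <= e_max, , drop = FALSE]
}

#' Write domain hits
#' @param hits data.frame as returned by [read_domain_hits()].
#' @param path Output TSV.
#' @export
write_domain_hits <- function(hits, path) write_tsv(hits, path)

#' Partition a protein into domain and unassigned segments
#'
#' The union of the hit intervals (overlaps merged) is labelled `domain`;
#' the complement is labelled `unassigned`.  The segments exactly tile
#' `1..aa_len` with alternating labels.
#'
#' @param hits data.frame of domain hits for one protein (may be empty).
#' @param aa_len Protein length in residues.
#' @param protein_id Optional id (defaults to the hits' id).
#' @return Object of class `region_partition`: data.frame with columns
#'   `aa_start`, `aa_end`, `label`, attributes `protein_id` and `aa_len`.
#' @export
build_partition <- function(hits, aa_len, protein_id = NULL) {
  aa_len <- as.integer(aa_len)
  if (aa_len < 1) stop("build_partition: aa_len must be >= 1")
  if (is.null(protein_id))
    protein_id <- if (nrow(hits)) hits$protein_id[1] else NA_character_
  if (nrow(hits)) {
    if (any(hits$ali_start < 1 | hits$ali_end > aa_len))
      stop("build_partition: hit outside 1..aa_len for ", protein_id, " (",
           paste(hits$accession[hits$ali_start < 1 | hits$ali_end > aa_len],
                 collapse = ","), ")")
    dom <- IRanges::reduce(IRanges::IRanges(hits$ali_start, hits$ali_end))
    un <- IRanges::gaps(dom, start = 1L, end = aa_len)
    seg_of <- function(ir, lab) {
      if (length(ir) == 0L)
        data.frame(aa_start = integer(0), aa_end = integer(0),
                   label = character(0), stringsAsFactors = FALSE)
      else data.frame(aa_start = IRanges::start(ir),
                      aa_end = IRanges::end(ir), label = lab,
                      stringsAsFactors = FALSE)
    }
    seg <- rbind(seg_of(dom, "domain"), seg_of(un, "unassigned"))
    seg <- seg[order(seg$aa_start), , drop = FALSE]
    rownames(seg) <- NULL
  } else {
    seg <- data.frame(aa_start = 1L, aa_end = aa_len, label = "unassigned",
                      stringsAsFactors = FALSE)
  }
  structure(seg, class = c("region_partition", "data.frame"),
            protein_id = protein_id, aa_len = aa_len)
}

#' Nucleotide projection of an amino-acid interval
#'
#' Residues `s..e` project onto CDS positions `3(s-1)+1 .. 3e`.
#' @param aa_start,aa_end Amino-acid interval, 1-based inclusive.
#' @return Integer vector of CDS nucleotide positions.
#' @export
aa_to_nt <- function(aa_start, aa_end) {
  (3L * (as.integer(aa_start) - 1L) + 1L):(3L * as.integer(aa_end))
}

# ---- Variants -----------------------------------------------------------

#' Read biallelic SNVs from a VCF
#'
#' One row per alt allele: multi-allelic SNV records are split.  Allele
#' frequencies come from `AC`/`AN` INFO fields when present, otherwise from
#' GT genotypes (biallelic records only).  Non-SNV records are skipped and
#' counted.
#'
#' @param path VCF path (plain or bgzipped).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `allele_number`, `alt_count`, `aaf`, `maf`; attribute `n_skipped`
#'   records how many non-SNV/unusable records were dropped.
#' @export
read_variants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  n_in <- length(vcf)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES & ref != alt
  info <- VariantAnnotation::info(vcf)
  ac <- if ("AC" %in% names(info)) suppressWarnings(as.integer(unlist(info$AC)))
        else rep(NA_integer_, length(vcf))
  an <- if ("AN" %in% names(info)) suppressWarnings(as.integer(info$AN))
        else rep(NA_integer_, length(vcf))
  if (anyNA(ac) || anyNA(an)) {
    gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
    if (!is.null(gt)) {
      need <- which(is.na(ac) | is.na(an))
      for (i in need) {
        g <- unlist(strsplit(gt[i, ], "[/|]"))
        g <- g[g != "."]
        if (length(g)) {
          an[i] <- length(g)
          ac[i] <- sum(g == "1")
        }
      }
    }
  }
  usable <- snv & !is.na(ac) & !is.na(an) & an > 0 & ac >= 0 & ac <= an
  if (any(snv & !usable))
    warning("read_variants: ", sum(snv & !usable),
            " SNV record(s) lacked AC/AN and genotypes; skipped")
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr))[usable],
                  pos = GenomicRanges::start(rr)[usable],
                  ref = ref[usable], alt = alt[usable],
                  allele_number = an[usable], alt_count = ac[usable],
                  stringsAsFactors = FALSE)
  d$aaf <- d$alt_count / d$allele_number
  d$maf <- pmin(d$aaf, 1 - d$aaf)
  attr(d, "n_skipped") <- sum(!usable)
  d
}

#' Write variants as a minimal VCF
#'
#' Emits VCFv4.2 with `AC` (per-alt) and `AN` INFO fields, the dialect
#' [read_variants()] consumes.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `allele_number`, `alt_count`.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele count\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
    writeLines(paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                     paste0("AC=", v$alt_count, ";AN=", v$allele_number),
                     sep = "\t"), con)
  }
  invisible(path)
}
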