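# Synthetic proteomes, domain annotations, population variants and
# ancestral sequences with known ground truth, plus direct Poisson
# simulation of paired site-frequency spectra for the DFE stage.
#
# Every generator is a pure function of (inputs, seed): the caller's RNG
# stream is left untouched.

#' Simulation configuration
#'
#' Defaults describe a small genome shaped like the real study system:
#' ~44% of residues inside Pfam domains, 2n = 2184 sampled chromosomes
#' (1092 diploid genomes), a per-site polymorphic-candidate intensity that
#' yields roughly 1.5 SNPs per 100 coding nucleotides, a mild
#' non-synonymous acceptance deficit inside domains for polymorphism and a
#' stronger one for fixation, and a human-ancestor divergence rate of a
#' few differences per kilobase.
#'
#' @param n_genes Number of genes.
#' @param aa_len_range Uniform range of protein lengths (residues).
#' @param domain_fraction Target fraction of residues inside domains.
#' @param n_chrom Sample size in chromosomes (allele number).
#' @param theta Per-site candidate mutation intensity (polymorphism).
#' @param accept_dom,accept_un Acceptance probability of a non-synonymous
#'   polymorphic candidate in domain / unassigned regions, each in (0, 1].
#' @param accept_fixed_dom,accept_fixed_un Acceptance probability of a
#'   non-synonymous fixed difference in domain / unassigned regions;
#'   defaults are the squares of the polymorphism probabilities (fixation
#'   of deleterious changes is rarer than segregation).
#' @param divergence_rate Per-site human-ancestor divergence rate.
#' @param mask_fraction Fraction of ancestral sites masked low-confidence.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, aa_len_range = c(100L, 500L),
                       domain_fraction = 0.44, n_chrom = 2184L,
                       theta = 0.015, accept_dom = 0.9, accept_un = 1.0,
                       accept_fixed_dom = accept_dom^2,
                       accept_fixed_un = accept_un^2,
                       divergence_rate = 0.005, mask_fraction = 0.1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              aa_len_range = as.integer(aa_len_range),
              domain_fraction = domain_fraction, n_chrom = as.integer(n_chrom),
              theta = theta, accept_dom = accept_dom, accept_un = accept_un,
              accept_fixed_dom = accept_fixed_dom,
              accept_fixed_un = accept_fixed_un,
              divergence_rate = divergence_rate,
              mask_fraction = mask_fraction, seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1, length(cfg$aa_len_range) == 2,
            cfg$aa_len_range[1] >= 5, diff(cfg$aa_len_range) >= 0,
            cfg$n_chrom >= 2, cfg$theta >= 0, cfg$divergence_rate >= 0,
            cfg$mask_fraction >= 0, cfg$mask_fraction <= 1)
  if (cfg$domain_fraction < 0 || cfg$domain_fraction > 1)
    stop("sim_config: domain_fraction must be in [0, 1]")
  for (f in c("accept_dom", "accept_un", "accept_fixed_dom",
              "accept_fixed_un"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop("sim_config: ", f, " must be in (0, 1]")
  structure(cfg, class = "sim_config")
}

random_sense_codons <- function(n) {
  sample(sense_codons(), n, replace = TRUE)
}

#' Generate a synthetic proteome
#'
#' Lays `n_genes` ORFs (ATG start, stop-free body, terminal stop) on a
#' single chromosome with random intergenic spacers, random strands and
#' 1-3 exons per gene, and assigns each gene zero or more disjoint domain
#' intervals whose per-gene coverage is jittered around
#' `domain_fraction`.  Writes genome FASTA, gene-model GFF3 and a domain
#' TSV when `dir` is given; always returns the objects in memory.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for `genome.fa`, `genes.gff3`,
#'   `domains.tsv`.
#' @return List with `genome` (named character), `models`
#'   (`gene_model_set`-style list), `hits` (domain data.frame), `cds`
#'   (list of [extract_cds()] results), `partitions`, `paths` (if written).
#' @export
generate_proteome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    chrom <- "chr1"
    seq_parts <- character(0)
    pos <- 0L
    models <- list()
    hits <- list()
    rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                  collapse = "")
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("g%04d", g)
      tid <- sprintf("t%04d", g)
      aa <- resample(config$aa_len_range[1]:config$aa_len_range[2], 1L)
      cds <- paste0("ATG", paste(random_sense_codons(aa - 1L), collapse = ""),
                    resample(c("TAA", "TAG", "TGA"), 1L))
      L <- nchar(cds)
      strand <- resample(c("+", "-"), 1L)
      n_ex <- resample(1:3, 1L)
      cuts <- if (n_ex > 1L) sort(sample(seq_len(L - 1L), n_ex - 1L)) else integer(0)
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, L)
      gseq <- if (strand == "+") cds else revcomp_chr(cds)
      # exon order along the genome: transcript order for +, reversed for -
      ex_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      gap <- resample(50:200, 1L)
      seq_parts <- c(seq_parts, rand_dna(gap))
      pos <- pos + gap
      iv <- matrix(0L, n_ex, 2)
      glens <- (ends - starts + 1L)[ex_order]
      gcursor <- 0L  # offset within gseq
      for (k in seq_len(n_ex)) {
        len <- glens[k]
        seq_parts <- c(seq_parts, substring(gseq, gcursor + 1L, gcursor + len))
        iv[k, ] <- c(pos + 1L, pos + len)
        pos <- pos + len
        gcursor <- gcursor + len
        if (k < n_ex) {
          intron <- resample(30:80, 1L)
          seq_parts <- c(seq_parts, rand_dna(intron))
          pos <- pos + intron
        }
      }
      models[[tid]] <- gene_model(gid, tid, chrom, strand, iv, 0L)
      # domain intervals: per-gene coverage jittered around the target
      if (config$domain_fraction > 0) {
        f <- max(0, min(0.9, config$domain_fraction + runif(1, -0.15, 0.15)))
        dlen <- round(f * aa)
        if (dlen >= 5) {
          n_dom <- if (dlen >= 60 && runif(1) < 0.5) 2L else 1L
          lens <- if (n_dom == 2L) {
            l1 <- round(dlen / 2); c(l1, dlen - l1)
          } else dlen
          # place disjoint intervals left to right with random gaps
          free <- aa - sum(lens)
          gaps <- sort(resample(0:free, n_dom, replace = TRUE))
          s <- integer(n_dom); cur <- 0L
          for (k in seq_len(n_dom)) {
            s[k] <- gaps[k] + cur + 1L
            cur <- cur + lens[k]
          }
          hits[[length(hits) + 1L]] <- data.frame(
            protein_id = gid,
            ali_start = s, ali_end = s + lens - 1L,
            accession = sprintf("PF%05d", sample(1:400, n_dom, replace = TRUE)),
            e_value = 10^-runif(n_dom, 4, 12),
            stringsAsFactors = FALSE)
        }
      }
    }
    seq_parts <- c(seq_parts, rand_dna(resample(50:200, 1L)))
    genome <- stats::setNames(paste(seq_parts, collapse = ""), chrom)
    hits <- if (length(hits)) do.call(rbind, hits)
            else data.frame(protein_id = character(0), ali_start = integer(0),
                            ali_end = integer(0), accession = character(0),
                            e_value = numeric(0))
    cds <- lapply(models, function(m) extract_cds(genome, m))
    names(cds) <- vapply(cds, `[[`, "", "gene_id")
    partitions <- lapply(cds, function(cs)
      build_partition(hits[hits$protein_id == cs$gene_id, , drop = FALSE],
                      cs$aa_len, cs$gene_id))
    out <- list(genome = genome, models = models, hits = hits, cds = cds,
                partitions = partitions, config = config)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(genome = file.path(dir, "genome.fa"),
                    gff = file.path(dir, "genes.gff3"),
                    domains = file.path(dir, "domains.tsv"))
      write_fasta(genome, paths$genome)
      write_gene_models(models, paths$gff)
      write_domain_hits(hits, paths$domains)
      out$paths <- paths
    }
    out
  })
}

# 1/i-weighted allele-count draw over 1..n-1 (standard neutral SFS shape);
# populates rare/low/common MAF classes without a coalescent.
draw_allele_counts <- function(k, n_chrom) {
  i <- seq_len(n_chrom - 1L)
  sample(i, k, replace = TRUE, prob = 1 / i)
}

#' Simulate population variants over a synthetic proteome
#'
#' Candidate mutations are placed uniformly over coding positions
#' (terminal stop excluded); each candidate's effect is computed from its
#' codon; non-synonymous candidates are retained with the region-specific
#' acceptance probability; retained variants receive allele counts from a
#' 1/i-weighted distribution over `1..n_chrom-1`.  Emits a ground-truth
#' row per variant.
#'
#' @param proteome Result of [generate_proteome()].
#' @param config The same [sim_config()].
#' @param vcf Optional path; when given, a VCF is written.
#' @return List with `variants` (VCF-style data.frame in genomic
#'   coordinates) and `truth` (per-variant true effect, region, MAF class
#'   and CDS bookkeeping).
#' @export
simulate_variants <- function(proteome, config, vcf = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    rows <- list()
    for (cs in proteome$cds) {
      part <- proteome$partitions[[cs$gene_id]]
      L <- 3L * cs$aa_len
      if (L == 0L) next
      k <- rpois(1, config$theta * L)
      if (k == 0L) next
      cpos <- sample.int(L, k, replace = TRUE)
      keep <- !logical(k)
      eff <- character(k); reg <- character(k)
      ref_cds <- character(k); alt_cds <- character(k)
      seq_up <- toupper(cs$nt_seq)
      for (j in seq_len(k)) {
        p <- cpos[j]
        cod_i <- (p - 1L) %/% 3L + 1L
        off <- (p - 1L) %% 3L + 1L
        cod <- substring(seq_up, 3L * cod_i - 2L, 3L * cod_i)
        refb <- substring(cod, off, off)
        altb <- resample(setdiff(BASES, refb), 1L)
        e <- classify_effect(cod, off, altb)
        r <- assign_region(cod_i, part)
        if (e == "nonsynonymous") {
          acc <- if (r == "domain") config$accept_dom else config$accept_un
          if (runif(1) > acc) keep[j] <- FALSE
        }
        eff[j] <- e; reg[j] <- r
        ref_cds[j] <- refb; alt_cds[j] <- altb
      }
      if (!any(keep)) next
      idx <- which(keep)
      ac <- draw_allele_counts(length(idx), config$n_chrom)
      gpos <- cs$genomic_map[cpos[idx]]
      flip <- cs$strand == "-"
      rows[[cs$gene_id]] <- data.frame(
        chrom = cs$chrom, pos = gpos,
        ref = if (flip) complement_chr(ref_cds[idx]) else ref_cds[idx],
        alt = if (flip) complement_chr(alt_cds[idx]) else alt_cds[idx],
        allele_number = config$n_chrom, alt_count = ac,
        gene_id = cs$gene_id, cds_pos = cpos[idx],
        aa_pos = (cpos[idx] - 1L) %/% 3L + 1L,
        effect = eff[idx], region = reg[idx],
        stringsAsFactors = FALSE)
    }
    truth <- if (length(rows)) do.call(rbind, rows)
             else data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0),
                             allele_number = integer(0), alt_count = integer(0),
                             gene_id = character(0), cds_pos = integer(0),
                             aa_pos = integer(0), effect = character(0),
                             region = character(0))
    rownames(truth) <- NULL
    # drop exact duplicates (same site, same alt drawn twice)
    truth <- truth[!duplicated(truth[, c("chrom", "pos", "alt")]), ,
                   drop = FALSE]
    truth$aaf <- truth$alt_count / truth$allele_number
    truth$maf <- pmin(truth$aaf, 1 - truth$aaf)
    truth$maf_class <- if (nrow(truth)) maf_class(truth$maf) else character(0)
    variants <- truth[, c("chrom", "pos", "ref", "alt", "allele_number",
                          "alt_count", "aaf", "maf")]
    if (!is.null(vcf)) write_variants(variants, vcf)
    list(variants = variants, truth = truth)
  })
}

#' Simulate an ancestral genome with a confidence mask
#'
#' Introduces Poisson(`divergence_rate` x coding length) substitutions per
#' gene into the ancestral copy of the genome, never at polymorphic sites,
#' never creating an ancestral internal stop, and with non-synonymous
#' changes accepted at the region-specific fixed-difference probabilities.
#' A `mask_fraction` of all positions is lower-cased (low confidence),
#' mirroring the 1000 Genomes ancestral-FASTA convention.
#'
#' @param proteome Result of [generate_proteome()].
#' @param config The [sim_config()].
#' @param polymorphic Optional data.frame with `chrom`, `pos` of
#'   polymorphic sites (typically `simulate_variants()$variants`).
#' @param fasta Optional path to write the ancestral FASTA.
#' @return List with `ancestral` (named character genome), `truth`
#'   (data.frame of true fixed differences: gene, CDS position, bases,
#'   effect, region, masked flag).
#' @export
simulate_ancestor <- function(proteome, config, polymorphic = NULL,
                              fasta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    genome <- proteome$genome
    anc <- strsplit(genome[[1]], "", fixed = TRUE)[[1]]
    chrom <- names(genome)[1]
    poly_pos <- if (is.null(polymorphic)) integer(0)
                else polymorphic$pos[polymorphic$chrom == chrom]
    rows <- list()
    for (cs in proteome$cds) {
      part <- proteome$partitions[[cs$gene_id]]
      L <- 3L * cs$aa_len
      if (L == 0L) next
      k <- rpois(1, config$divergence_rate * L)
      if (k == 0L) next
      cand <- sample.int(L, min(k, L))  # distinct sites
      seq_up <- toupper(cs$nt_seq)
      anc_cds <- strsplit(seq_up, "")[[1]]  # ancestral CDS under edit
      for (p in cand) {
        if (cs$genomic_map[p] %in% poly_pos) next
        cod_i <- (p - 1L) %/% 3L + 1L
        off <- (p - 1L) %% 3L + 1L
        human_cod <- substring(seq_up, 3L * cod_i - 2L, 3L * cod_i)
        humanb <- substring(human_cod, off, off)
        ancb <- resample(setdiff(BASES, humanb), 1L)
        anc_cod <- paste0(anc_cds[(3L * cod_i - 2L):(3L * cod_i)],
                          collapse = "")
        substr(anc_cod, off, off) <- ancb
        if (is_stop_codon(anc_cod)) next  # ancestor stays stop-free
        # derived effect: human base substituted into the ancestral context
        e <- classify_effect(anc_cod, off, humanb)
        r <- assign_region(cod_i, part)
        acc <- if (e == "nonsynonymous") {
          if (r == "domain") config$accept_fixed_dom else config$accept_fixed_un
        } else 1
        if (runif(1) > acc) next
        anc_cds[p] <- ancb
        gpos <- cs$genomic_map[p]
        gb <- if (cs$strand == "-") complement_chr(ancb) else ancb
        anc[gpos] <- gb
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = cs$gene_id, cds_pos = p, aa_pos = cod_i,
          ancestral_base = ancb, derived_base = humanb,
          effect = e, region = r, chrom = chrom, pos = gpos,
          stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows)
             else data.frame(gene_id = character(0), cds_pos = integer(0),
                             aa_pos = integer(0), ancestral_base = character(0),
                             derived_base = character(0), effect = character(0),
                             region = character(0), chrom = character(0),
                             pos = integer(0))
    # low-confidence mask over all positions
    n_mask <- round(config$mask_fraction * length(anc))
    masked <- if (n_mask > 0) sample.int(length(anc), n_mask) else integer(0)
    if (length(masked)) anc[masked] <- tolower(anc[masked])
    truth$masked <- truth$pos %in% masked
    ancestral <- stats::setNames(paste(anc, collapse = ""), chrom)
    if (!is.null(fasta)) write_fasta(ancestral, fasta)
    list(ancestral = ancestral, truth = truth)
  })
}

#' Simulate a paired neutral/selected site-frequency spectrum
#'
#' Class counts are Poisson with means equal to the model expectations:
#' neutral class i has mean `theta_neu * L_sites * r[i] / i`; selected
#' class i has mean `theta_sel * L_sites * r[i] * E_i` where `E_i` is the
#' gamma-mixed diffusion sojourn expectation of [expected_sfs()]
#' (`E_i = 1/i` when `S_mean = 0`).
#'
#' @param beta Gamma shape of the DFE (>0).
#' @param S_mean Mean scaled selection strength E\[4Ns\] (>= 0).
#' @param theta_sel,theta_neu Mutation intensities (per site when
#'   `L_sites` is used as a multiplier; the mean count scale is
#'   `theta * L_sites`).
#' @param r Per-class distortion multipliers (length `n - 1`, `r[1]`
#'   conventionally 1); default all 1.
#' @param n Sample size in chromosomes (>= 4).
#' @param L_sites Number of sites; scales both spectra (default 1).
#' @param folded Fold the spectra onto minor-allele classes.
#' @param seed Integer seed.
#' @return Object of class `sfs_pair`: list with `n`, `folded`,
#'   `neutral`, `selected` count vectors, and attribute `means` holding
#'   the (unfolded) expected counts.
#' @export
simulate_sfs_pair <- function(beta, S_mean, theta_sel, theta_neu, r = NULL,
                              n, L_sites = 1, folded = FALSE, seed = 1L) {
  stopifnot(beta > 0, S_mean >= 0, n >= 4)
  i <- seq_len(n - 1L)
  if (is.null(r)) r <- rep(1, n - 1L)
  stopifnot(length(r) == n - 1L, all(r > 0))
  E <- if (S_mean == 0) 1 / i else gamma_mixed_sfs(beta, S_mean, n)
  mu_neu <- theta_neu * L_sites * r / i
  mu_sel <- theta_sel * L_sites * r * E
  with_seed(seed, {
    neu <- rpois(n - 1L, mu_neu)
    sel <- rpois(n - 1L, mu_sel)
    pair <- sfs_pair(n, neu, sel, folded = FALSE)
    if (folded) pair <- fold_sfs(pair)
    attr(pair, "means") <- list(neutral = mu_neu, selected = mu_sel)
    pair
  })
}

#' Construct a paired site-frequency spectrum
#' @param n Sample size (chromosomes).
#' @param neutral,selected Count vectors (length `n - 1` unfolded,
#'   `floor(n/2)` folded).
#' @param folded Logical.
#' @return Object of class `sfs_pair`.
#' @export
sfs_pair <- function(n, neutral, selected, folded = FALSE) {
  n <- as.integer(n)
  want <- if (folded) n %/% 2L else n - 1L
  if (length(neutral) != want || length(selected) != want)
    stop("sfs_pair: count vectors must have length ", want)
  if (any(neutral < 0) || any(selected < 0)) stop("sfs_pair: negative counts")
  structure(list(n = n, folded = folded, neutral = as.numeric(neutral),
                 selected = as.numeric(selected)), class = "sfs_pair")
}

#' Fold a site-frequency spectrum pair onto minor-allele classes
#' @param pair An unfolded [sfs_pair()].
#' @return Folded `sfs_pair` (classes `i` and `n - i` summed; the middle
#'   class of an even `n` is not doubled).
#' @export
fold_sfs <- function(pair) {
  stopifnot(inherits(pair, "sfs_pair"))
  if (pair$folded) return(pair)
  sfs_pair(pair$n, fold_vector(pair$neutral, pair$n),
           fold_vector(pair$selected, pair$n), folded = TRUE)
}

fold_vector <- function(x, n) {
  m <- n %/% 2L
  out <- numeric(m)
  for (j in seq_len(m)) {
    out[j] <- if (j == n - j) x[j] else x[j] + x[n - j]
  }
  out
}
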