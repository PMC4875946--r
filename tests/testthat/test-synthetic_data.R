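# Generators: proteome, variants, ancestor, SFS pairs.

test_that("generate_proteome produces valid ORFs and honours trivial configs", {
  cfg <- sim_config(n_genes = 1L, aa_len_range = c(10L, 10L),
                    domain_fraction = 0, seed = 1)
  prot <- generate_proteome(cfg)
  cs <- prot$cds[[1]]
  expect_equal(nchar(cs$nt_seq), 33L)  # 10 aa + terminal stop
  expect_equal(cs$aa_len, 10L)
  expect_equal(substr(toupper(cs$nt_seq), 1, 3), "ATG")
  expect_equal(nrow(prot$hits), 0L)
})

test_that("generated ORFs are internal-stop-free on all strands/exon counts", {
  sim <- small_sim(seed = 33, n_genes = 25)
  for (cs in sim$prot$cds) {
    idx <- seq_len(cs$aa_len)
    cods <- substring(toupper(cs$nt_seq), 3 * idx - 2, 3 * idx)
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
    last <- substring(toupper(cs$nt_seq), 3 * cs$aa_len + 1, 3 * cs$aa_len + 3)
    expect_true(last %in% c("TAA", "TAG", "TGA"))
  }
  expect_true(any(vapply(sim$prot$models, `[[`, "", "strand") == "-"))
  expect_true(any(vapply(sim$prot$models,
                         function(m) nrow(m$cds_intervals), 0L) > 1))
})

test_that("realized domain coverage tracks the configured fraction", {
  cfg <- sim_config(n_genes = 120L, aa_len_range = c(100L, 400L),
                    domain_fraction = 0.44, seed = 8)
  prot <- generate_proteome(cfg)
  labs <- unlist(lapply(prot$partitions, function(p)
    rep(p$label, p$aa_end - p$aa_start + 1)))
  expect_equal(mean(labs == "domain"), 0.44, tolerance = 0.05 / 0.44)
})

test_that("generators are deterministic given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 8L, seed = 99)
  generate_proteome(cfg, dir = d1)
  generate_proteome(cfg, dir = d2)
  for (f in c("genome.fa", "genes.gff3", "domains.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  p <- generate_proteome(cfg)
  v1 <- simulate_variants(p, cfg)$truth
  v2 <- simulate_variants(p, cfg)$truth
  expect_identical(v1, v2)
  a1 <- simulate_ancestor(p, cfg)$ancestral
  a2 <- simulate_ancestor(p, cfg)$ancestral
  expect_identical(a1, a2)
})

test_that("simulate_variants: theta = 0 gives an empty VCF", {
  cfg <- sim_config(n_genes = 4L, theta = 0, seed = 2)
  prot <- generate_proteome(cfg)
  sim <- simulate_variants(prot, cfg)
  expect_equal(nrow(sim$variants), 0L)
})

test_that("neutral acceptance reproduces the site-count ratio; truth labels
          agree with re-classification", {
  cfg <- sim_config(n_genes = 50L, aa_len_range = c(100L, 200L),
                    theta = 0.05, accept_dom = 1, accept_un = 1, seed = 12)
  prot <- generate_proteome(cfg)
  sim <- simulate_variants(prot, cfg)
  st <- do.call(rbind, lapply(prot$cds, function(cs)
    region_site_counts(cs, prot$partitions[[cs$gene_id]])))
  ratio_sites <- sum(st$nonsyn_sites) / sum(st$syn_sites)
  ratio_snps <- sum(sim$truth$effect == "nonsynonymous") /
    sum(sim$truth$effect == "synonymous")
  expect_equal(ratio_snps, ratio_sites, tolerance = 0.1)

  # truth labels vs the classifier re-applied to the emitted variants
  cl <- classify_variants(sim$variants, prot$cds, prot$partitions)
  key <- function(d) paste(d$chrom, d$pos, d$alt)
  m <- match(key(cl), key(sim$truth))
  expect_false(anyNA(m))
  expect_equal(cl$effect, sim$truth$effect[m])
  expect_equal(cl$region, sim$truth$region[m])
  expect_equal(cl$maf_class, sim$truth$maf_class[m])
  # all three MAF classes populated
  expect_setequal(unique(sim$truth$maf_class), c("rare", "low", "common"))
})

test_that("domain thinning drives the non-synonymous deficit it claims", {
  cfg <- sim_config(n_genes = 60L, aa_len_range = c(100L, 200L),
                    theta = 0.08, accept_dom = 0.5, accept_un = 1, seed = 13)
  prot <- generate_proteome(cfg)
  tr <- simulate_variants(prot, cfg)$truth
  st <- do.call(rbind, lapply(prot$cds, function(cs)
    region_site_counts(cs, prot$partitions[[cs$gene_id]])))
  ns <- tr[tr$effect == "nonsynonymous", ]
  or <- (sum(ns$region == "domain") / sum(st$nonsyn_sites[st$region == "domain"])) /
    (sum(ns$region == "unassigned") / sum(st$nonsyn_sites[st$region == "unassigned"]))
  expect_equal(or, 0.5, tolerance = 0.15)
})

test_that("simulate_ancestor: divergence count, exclusions and masking", {
  cfg0 <- sim_config(n_genes = 6L, divergence_rate = 0, mask_fraction = 0,
                     seed = 3)
  prot0 <- generate_proteome(cfg0)
  anc0 <- simulate_ancestor(prot0, cfg0)
  expect_identical(anc0$ancestral, prot0$genome)
  expect_equal(nrow(anc0$truth), 0L)

  cfg <- sim_config(n_genes = 40L, aa_len_range = c(100L, 200L),
                    divergence_rate = 0.01, mask_fraction = 0,
                    accept_fixed_dom = 1, accept_fixed_un = 1, seed = 4)
  prot <- generate_proteome(cfg)
  anc <- simulate_ancestor(prot, cfg)
  L <- sum(vapply(prot$cds, function(cs) 3 * cs$aa_len, 0))
  rL <- 0.01 * L
  expect_lt(abs(nrow(anc$truth) - rL), 3 * sqrt(rL))

  # divergences never coincide with declared polymorphic sites
  sim <- simulate_variants(prot, cfg)
  anc2 <- simulate_ancestor(prot, cfg, polymorphic = sim$variants)
  expect_false(any(anc2$truth$pos %in% sim$variants$pos))

  # full masking suppresses every divergence call downstream
  cfgm <- sim_config(n_genes = 10L, divergence_rate = 0.01,
                     mask_fraction = 1, seed = 6)
  protm <- generate_proteome(cfgm)
  ancm <- simulate_ancestor(protm, cfgm)
  for (cs in protm$cds) {
    anc_cds <- extract_cds(ancm$ancestral, protm$models[[cs$transcript_id]],
                           check_stops = FALSE)
    expect_equal(nrow(call_fixed_divergence(cs, anc_cds$nt_seq)), 0L)
  }
})

test_that("simulate_sfs_pair matches its stated expectations", {
  # neutral limit: selected and neutral means share the 1/i shape
  p0 <- simulate_sfs_pair(beta = 0.5, S_mean = 0, theta_sel = 700,
                          theta_neu = 1000, n = 10, seed = 1)
  mu <- attr(p0, "means")
  expect_equal(mu$neutral, 1000 / (1:9))
  expect_equal(mu$selected, 700 / (1:9))
  expect_equal(mu$neutral[1], 1000)   # singleton mean
  expect_equal(mu$neutral[2], 500)    # doubleton mean

  # determinism and folding
  p1 <- simulate_sfs_pair(0.3, 50, 0.001, 0.001, n = 20, L_sites = 1e6,
                          folded = TRUE, seed = 42)
  p2 <- simulate_sfs_pair(0.3, 50, 0.001, 0.001, n = 20, L_sites = 1e6,
                          folded = TRUE, seed = 42)
  expect_identical(p1$neutral, p2$neutral)
  expect_identical(p1$selected, p2$selected)
  expect_length(p1$neutral, 10L)

  # selection depletes the selected spectrum relative to neutral
  expect_lt(sum(p1$selected), sum(p1$neutral))
})

test_that("fold_sfs sums complementary classes once", {
  pair <- sfs_pair(6, c(10, 5, 3, 2, 1), c(7, 4, 2, 1, 1))
  f <- fold_sfs(pair)
  expect_equal(f$neutral, c(10 + 1, 5 + 2, 3))
  expect_equal(f$selected, c(7 + 1, 4 + 1, 2))
  expect_identical(fold_sfs(f), f)
})

test_that("sim_config validates its ranges", {
  expect_error(sim_config(domain_fraction = 1.2), "domain_fraction")
  expect_error(sim_config(accept_dom = 0), "accept_dom")
  expect_error(sim_config(n_chrom = 1))
})
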