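# Effect / region / MAF classification, divergence calling, tabulation.

test_that("classify_effect matches the documented single cases", {
  # the two disease-linked substitutions in the neurohypophyseal hormone
  # domain: Pro26Leu (CCG->CTG) and Tyr21His (TAC->CAC)
  expect_equal(classify_effect("CCG", 2, "T"), "nonsynonymous")
  expect_equal(classify_effect("TAC", 1, "C"), "nonsynonymous")
  expect_equal(classify_effect("CTG", 3, "A"), "synonymous")  # 4-fold site
  # Met: all nine changes are non-synonymous
  for (off in 1:3)
    for (alt in setdiff(c("A", "C", "G", "T"), substr("ATG", off, off)))
      expect_equal(classify_effect("ATG", off, alt), "nonsynonymous")
  expect_error(classify_effect("TAA", 1, "C"), "stop")
  expect_error(classify_effect("AAA", 1, "A"), "equals")
})

test_that("classify_effect agrees with the translate-and-compare oracle on
          all 549 sense-codon changes; nonsense pools as non-synonymous", {
  for (cod in sense_codons()) {
    for (off in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), substr(cod, off, off))) {
        expect_equal(classify_effect(cod, off, alt),
                     oracle_effect(cod, off, alt),
                     label = paste(cod, off, alt))
      }
    }
  }
  expect_equal(classify_effect("TAC", 3, "A"), "nonsynonymous")  # TAC->TAA
})

test_that("maf_class applies the rare/low/common thresholds inclusively", {
  expect_equal(maf_class(0.003), "rare")
  expect_equal(maf_class(0.005), "low")     # lower boundary inclusive
  expect_equal(maf_class(0.05), "low")      # upper boundary inclusive
  expect_equal(maf_class(0.0500001), "common")
  expect_equal(maf_class(c(0.001, 0.02, 0.3)), c("rare", "low", "common"))
  expect_error(maf_class(0), "monomorphic")
  expect_error(maf_class(0.6), "0.5")
})

test_that("assign_region respects segment boundaries", {
  part <- build_partition(data.frame(protein_id = "p", ali_start = 10L,
                                     ali_end = 60L, accession = "PF1",
                                     e_value = 0), 100L)
  expect_equal(assign_region(10, part), "domain")
  expect_equal(assign_region(60, part), "domain")
  expect_equal(assign_region(61, part), "unassigned")
  expect_equal(assign_region(9, part), "unassigned")
  expect_error(assign_region(101, part), "outside")
})

test_that("call_fixed_divergence applies all exclusion rules", {
  cs <- make_cds("ATGAAATAG")
  expect_equal(nrow(call_fixed_divergence(cs, "ATGAAATAG")), 0L)
  # one synonymous difference (Lys AAA vs AAG at CDS pos 6)
  d <- call_fixed_divergence(cs, "ATGAAGTAG")
  expect_equal(nrow(d), 1L)
  expect_equal(d$cds_pos, 6L)
  expect_equal(d$ancestral_base, "G")
  expect_equal(d$derived_base, "A")
  expect_equal(d$effect, "synonymous")
  # low-confidence (lower case) ancestral call: excluded
  expect_equal(nrow(call_fixed_divergence(cs, "ATGAAgTAG")), 0L)
  # polymorphic in the sample: excluded
  expect_equal(nrow(call_fixed_divergence(cs, "ATGAAGTAG",
                                          polymorphic_positions = 6L)), 0L)
  # missing outgroup information (N): excluded
  expect_equal(nrow(call_fixed_divergence(cs, "ATGAANTAG")), 0L)
  # difference in the terminal stop codon: outside the counting window
  expect_equal(nrow(call_fixed_divergence(cs, "ATGAAATAA")), 0L)
  expect_error(call_fixed_divergence(cs, "ATG"), "length mismatch")
})

test_that("divergence effect uses the ancestral codon as context", {
  # human ATG|CTG, ancestor ATG|TTG: derived C at pos 4; TTG->CTG Leu->Leu
  cs <- make_cds("ATGCTGTAG")
  d <- call_fixed_divergence(cs, "ATGTTGTAG")
  expect_equal(d$effect, "synonymous")
  # two differences in one codon, classified one at a time left to right
  # human AAA, ancestor AGG: pos5 (AGG+A@2 -> AAG Lys vs Arg: nonsyn),
  # pos6 (AGG+A@3 -> AGA Arg=Arg: syn)
  cs2 <- make_cds("ATGAAATAG")
  d2 <- call_fixed_divergence(cs2, "ATGAGGTAG")
  expect_equal(d2$cds_pos, c(5L, 6L))
  expect_equal(d2$effect, c("nonsynonymous", "synonymous"))
})

test_that("classify_variants maps strands, QCs mismatches, skips monomorphic", {
  sim <- small_sim(seed = 17, n_genes = 12)
  vs <- simulate_variants(sim$prot, sim$cfg)
  v <- vs$variants
  # corrupt one record's ref, add a non-coding and a monomorphic record
  v2 <- rbind(v,
              data.frame(chrom = "chr1", pos = v$pos[1], ref = v$ref[1],
                         alt = v$alt[1], allele_number = 2184L,
                         alt_count = 0L, aaf = 0, maf = 0),
              data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "C",
                         allele_number = 2184L, alt_count = 5L,
                         aaf = 5 / 2184, maf = 5 / 2184))
  bad <- v$ref[2]
  v2$ref[2] <- setdiff(c("A", "C", "G", "T"), bad)[1]
  cl <- classify_variants(v2, sim$prot$cds, sim$prot$partitions)
  qc <- attr(cl, "qc")
  expect_equal(unname(qc["ref_mismatch"]), 1L)
  expect_equal(unname(qc["monomorphic"]), 1L)
  expect_gte(unname(qc["noncoding"]), 1L)
  expect_equal(nrow(cl) + sum(qc) - unname(qc["noncoding"]),
               nrow(v2) - unname(qc["noncoding"]))
  # alt codon differs from ref codon exactly at the offset
  same <- substr(cl$ref_codon, cl$offset_in_codon, cl$offset_in_codon) !=
    substr(cl$alt_codon, cl$offset_in_codon, cl$offset_in_codon)
  expect_true(all(same))
  expect_true(all(cl$effect %in% c("synonymous", "nonsynonymous")))
  expect_true(all(cl$region %in% c("domain", "unassigned")))
  expect_true(all(cl$maf_class %in% c("rare", "low", "common")))
})

test_that("tabulate_counts reproduces the synthetic ground truth exactly", {
  cfg <- sim_config(n_genes = 30L, theta = 0.03, divergence_rate = 0.008,
                    seed = 19)
  prot <- generate_proteome(cfg)
  sim <- simulate_variants(prot, cfg)
  anc <- simulate_ancestor(prot, cfg, polymorphic = sim$variants)
  cl <- classify_variants(sim$variants, prot$cds, prot$partitions)
  poly <- split(cl$cds_pos, cl$gene_id)
  divs <- do.call(rbind, lapply(prot$cds, function(cs) {
    am <- extract_cds(anc$ancestral, prot$models[[cs$transcript_id]],
                      check_stops = FALSE)
    d <- call_fixed_divergence(cs, am$nt_seq,
                               polymorphic_positions =
                                 if (is.null(poly[[cs$gene_id]])) integer(0)
                                 else poly[[cs$gene_id]])
    if (nrow(d)) d$region <- assign_region(d$aa_pos,
                                           prot$partitions[[cs$gene_id]])
    d
  }))
  ct <- tabulate_counts(cl, divs)
  truth_ct <- tabulate_counts(sim$truth, anc$truth[!anc$truth$masked, ])
  expect_equal(as.data.frame(ct), as.data.frame(truth_ct))
  # marginals recompose
  m <- counts_marginals(ct, "all")
  expect_equal(unname(m["Pn"] + m["Ps"]), nrow(cl))
  expect_equal(unname(m["Dn"] + m["Ds"]), nrow(divs))
})

test_that("tabulate_counts of empty inputs is the all-zero table", {
  ct <- tabulate_counts(NULL, NULL)
  expect_equal(nrow(ct), 16L)
  expect_true(all(ct$count == 0L))
  expect_equal(unname(counts_marginals(ct)), c(0, 0, 0, 0))
})
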