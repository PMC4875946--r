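# I/O layer: gene models, CDS extraction, partitions, variants.

gff_text <- function(rows, path) {
  writeLines(c("##gff-version 3", rows), path)
  path
}

test_that("read_gene_models parses, sorts and validates CDS features", {
  p <- withr::local_tempfile(fileext = ".gff3")
  gff_text(c(
    "chr1\tx\tCDS\t101\t109\t.\t+\t0\tID=c1;Parent=tA;transcript_id=tA;gene_id=gA",
    # minus-strand two-exon model, features deliberately unsorted
    "chr1\tx\tCDS\t301\t306\t.\t-\t0\tID=c2;Parent=tB;transcript_id=tB;gene_id=gB",
    "chr1\tx\tCDS\t201\t206\t.\t-\t0\tID=c3;Parent=tB;transcript_id=tB;gene_id=gB",
    # total length 10: invalid, must be skipped with a logged reason
    "chr1\tx\tCDS\t401\t410\t.\t+\t0\tID=c4;Parent=tC;transcript_id=tC;gene_id=gC"),
    p)
  models <- suppressMessages(read_gene_models(p))
  expect_named(models, c("tA", "tB"))
  expect_equal(nrow(models$tA$cds_intervals), 1L)
  expect_equal(unname(models$tA$cds_intervals[1, ]), c(101L, 109L))
  expect_equal(unname(models$tB$cds_intervals[, 1]), c(201L, 301L))
  skipped <- attr(models, "skipped")
  expect_equal(skipped$transcript_id, "tC")
  expect_match(skipped$reason, "multiple of 3")
})

test_that("minus-strand extraction splices then reverse-complements", {
  contig <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  genome <- c(chr1 = contig)
  m <- gene_model("gB", "tB", "chr1", "-", rbind(c(201L, 206L), c(301L, 306L)))
  cs <- extract_cds(genome, m, check_stops = FALSE)
  by_hand <- chartr("ACGT", "TGCA", paste(rev(strsplit(
    paste0(substr(contig, 201, 206), substr(contig, 301, 306)),
    "")[[1]]), collapse = ""))
  expect_equal(cs$nt_seq, by_hand)
  # the genomic map walks 306..301 then 206..201
  expect_equal(cs$genomic_map, c(306:301, 206:201))
  # and equals the reverse complement of the + strand extraction
  m_plus <- gene_model("gB", "tBp", "chr1", "+",
                       rbind(c(201L, 206L), c(301L, 306L)))
  cs_plus <- extract_cds(genome, m_plus, check_stops = FALSE)
  expect_equal(cs$nt_seq, chartr("ACGT", "TGCA", paste(rev(strsplit(
    cs_plus$nt_seq, "")[[1]]), collapse = "")))
})

test_that("extract_cds handles ORFs, stops and bounds", {
  genome <- c(chr1 = "ATGAAATAG")
  cs <- extract_cds(genome, gene_model("g", "t", "chr1", "+", c(1L, 9L)))
  expect_equal(cs$nt_seq, "ATGAAATAG")
  expect_equal(cs$aa_len, 2L)  # Met-Lys, terminal stop retained but excluded
  csm <- extract_cds(genome, gene_model("g", "t", "chr1", "-", c(1L, 9L)),
                     check_stops = FALSE)
  expect_equal(csm$nt_seq, "CTATTTCAT")
  expect_error(
    extract_cds(c(chr1 = "ATGTAAAAATAG"),
                gene_model("g", "t", "chr1", "+", c(1L, 12L))),
    "internal stop")
  expect_error(
    extract_cds(genome, gene_model("g", "t", "chr1", "+", c(4L, 15L))),
    "bounds")
})

test_that("build_partition tiles the protein with alternating labels", {
  p0 <- build_partition(data.frame(), 100L, "p")
  expect_equal(nrow(p0), 1L)
  expect_equal(p0$label, "unassigned")
  expect_equal(c(p0$aa_start, p0$aa_end), c(1L, 100L))

  hits <- data.frame(protein_id = "p", ali_start = c(10L, 30L),
                     ali_end = c(40L, 60L), accession = c("PF1", "PF2"),
                     e_value = c(1e-5, 1e-6))
  pp <- build_partition(hits, 100L)
  expect_equal(pp$aa_start, c(1L, 10L, 61L))
  expect_equal(pp$aa_end, c(9L, 60L, 100L))
  expect_equal(pp$label, c("unassigned", "domain", "unassigned"))
  # full-length hit
  pfull <- build_partition(data.frame(protein_id = "p", ali_start = 1L,
                                      ali_end = 100L, accession = "PF1",
                                      e_value = 0), 100L)
  expect_equal(pfull$label, "domain")
  expect_error(build_partition(data.frame(protein_id = "p", ali_start = 90L,
                                          ali_end = 120L, accession = "PFX",
                                          e_value = 0), 100L),
               "PFX")
})

test_that("partitions tile and alternate over random hit sets", {
  set.seed(42)
  for (rep in 1:25) {
    aa_len <- sample(20:200, 1)
    k <- sample(0:4, 1)
    if (k > 0) {
      s <- sample(seq_len(aa_len), k, replace = TRUE)
      e <- pmin(aa_len, s + sample(0:30, k, replace = TRUE))
      hits <- data.frame(protein_id = "p", ali_start = s, ali_end = e,
                         accession = paste0("PF", seq_len(k)), e_value = 0)
    } else hits <- data.frame()
    part <- build_partition(hits, aa_len, "p")
    expect_equal(sum(part$aa_end - part$aa_start + 1L), aa_len)
    expect_true(all(part$aa_start[-1] == part$aa_end[-nrow(part)] + 1L))
    if (nrow(part) > 1)
      expect_true(all(part$label[-1] != part$label[-nrow(part)]))
  }
})

test_that("read_variants computes frequencies and splits/skips records", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\tAC=3;AN=2184",
    "chr1\t200\t.\tC\tT\t.\tPASS\tAC=2000;AN=2184",
    "chr1\t300\t.\tG\tGA\t.\tPASS\tAC=5;AN=2184",        # indel: skipped
    "chr1\t400\t.\tT\tA,C\t.\tPASS\tAC=5,10;AN=2184"),   # multiallelic: split
    p)
  v <- read_variants(p)
  expect_equal(nrow(v), 4L)
  expect_equal(v$aaf[v$pos == 100], 3 / 2184, tolerance = 1e-12)
  expect_equal(v$maf[v$pos == 100], 3 / 2184, tolerance = 1e-12)
  expect_equal(v$maf[v$pos == 200], 1 - 2000 / 2184, tolerance = 1e-12)
  expect_false(300 %in% v$pos)
  expect_equal(sort(v$alt[v$pos == 400]), c("A", "C"))
  expect_equal(sort(v$alt_count[v$pos == 400]), c(5L, 10L))
  expect_equal(attr(v, "n_skipped"), 1L)
})

test_that("read_variants falls back to genotypes when AC/AN are absent", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
               "chr1\t50\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0"), p)
  v <- read_variants(p)
  expect_equal(v$allele_number, 6L)
  expect_equal(v$alt_count, 3L)
  expect_equal(v$maf, 0.5)
})

test_that("write/read round-trips preserve records", {
  sim <- small_sim(seed = 21, n_genes = 6)
  dir <- withr::local_tempdir()
  write_gene_models(sim$prot$models, file.path(dir, "g.gff3"))
  back <- read_gene_models(file.path(dir, "g.gff3"))
  expect_setequal(names(back), names(sim$prot$models))
  for (t in names(back)) {
    expect_equal(back[[t]]$cds_intervals, sim$prot$models[[t]]$cds_intervals)
    expect_equal(back[[t]]$strand, sim$prot$models[[t]]$strand)
    expect_equal(back[[t]]$phase, sim$prot$models[[t]]$phase)
  }
  write_fasta(sim$prot$genome, file.path(dir, "g.fa"))
  expect_equal(read_fasta(file.path(dir, "g.fa")), sim$prot$genome)

  hits <- sim$prot$hits
  write_domain_hits(hits, file.path(dir, "d.tsv"))
  hits2 <- read_domain_hits(file.path(dir, "d.tsv"), e_max = 1)
  expect_equal(hits2, hits, tolerance = 1e-10, ignore_attr = TRUE)

  vs <- simulate_variants(sim$prot, sim$cfg)$variants
  write_variants(vs, file.path(dir, "v.vcf"))
  vs2 <- read_variants(file.path(dir, "v.vcf"))
  vs_sorted <- vs[order(vs$chrom, vs$pos, vs$alt), ]
  vs2_sorted <- vs2[order(vs2$chrom, vs2$pos, vs2$alt), ]
  rownames(vs_sorted) <- rownames(vs2_sorted) <- NULL
  expect_equal(vs2_sorted, vs_sorted, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("read_domain_hits applies the E-value threshold at read time", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tali_start\tali_end\taccession\te_value",
               "p1\t5\t50\tPF00001\t1e-08",
               "p1\t60\t80\tPF00002\t0.01"), p)
  h <- read_domain_hits(p)  # default 1e-3
  expect_equal(h$accession, "PF00001")
  h2 <- read_domain_hits(p, e_max = 0.1)
  expect_equal(nrow(h2), 2L)
})

test_that("aa_to_nt projects residue intervals onto CDS nucleotides", {
  expect_equal(aa_to_nt(1, 1), 1:3)
  expect_equal(aa_to_nt(10, 12), 28:36)
})
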