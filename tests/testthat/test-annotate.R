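test_that("introns are derived as gaps between exons, honoring strand", {
  idx <- toy_index()
  expect_equal(length(idx$genes), 2L)
  expect_equal(length(idx$exons), 5L)
  # gplus: exons [100,200) [300,400) [500,620) -> introns [200,300) [400,500)
  ip <- idx$introns[idx$introns$gene_id == "gplus"]
  expect_equal(BiocGenerics::start(ip), c(201L, 401L))
  expect_equal(BiocGenerics::end(ip), c(300L, 500L))
  # minus-strand gene: rank 1 from the 5' end is the genomically last exon
  em <- idx$exons[idx$exons$gene_id == "gminus"]
  expect_equal(em$rank5[BiocGenerics::start(em) == 1301L], 1L)
  expect_equal(em$rank5[BiocGenerics::start(em) == 1001L], 2L)
  # rank arithmetic holds for every feature
  for (gid in unique(idx$exons$gene_id)) {
    ex <- idx$exons[idx$exons$gene_id == gid]
    expect_true(all(ex$rank5 + ex$rank3 == length(ex) + 1L))
  }
  # single-exon gene has no introns
  p <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(gene_spec("c", "+",
                                        rbind(c(10L, 400L)))), p)
  expect_equal(length(build_annotation_index(p)$introns), 0L)
})

test_that("intron derivation conserves gene span length", {
  idx <- toy_index()
  for (gid in c("gplus", "gminus")) {
    ex <- idx$exons[idx$exons$gene_id == gid]
    intr <- idx$introns[idx$introns$gene_id == gid]
    g <- idx$genes[as.character(idx$genes$ID) == gid]
    expect_equal(sum(BiocGenerics::width(ex)) +
                   sum(BiocGenerics::width(intr)),
                 BiocGenerics::width(g))
  }
})

test_that("region assignment follows midpoint precedence", {
  idx <- toy_index()
  mk_locus <- function(start, end) {
    data.frame(seq_id = "chr1", start = start, end = end,
               ssr_type = "perfect", motif = "A", canonical_motif = "A",
               motif_len = 1L, repeats = end - start,
               length_bp = end - start, score = 0L, n_edits = 0L)
  }
  lab <- function(start, end) {
    as.character(assign_region(mk_locus(start, end), idx)$region)
  }
  expect_equal(lab(330L, 350L), "CDS")
  expect_equal(lab(110L, 130L), "exon_noncoding")   # exon outside CDS
  expect_equal(lab(210L, 260L), "intron")
  expect_equal(lab(700L, 730L), "intergenic")
  expect_equal(lab(5000L, 5020L), "intergenic")
  # region labels partition the loci
  g <- study_fixture()
  counts <- table(g$loci$region)
  expect_equal(sum(counts), nrow(g$loci))
})

test_that("midpoint labels agree with a per-base majority oracle", {
  genes <- toy_genes()
  p <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(genes, p)
  idx <- build_annotation_index(p)
  set.seed(31)
  starts <- sample(0:1950, 2000, replace = TRUE)
  lens <- sample(12:40, 2000, replace = TRUE)
  loci <- data.frame(seq_id = "chr1", start = starts, end = starts + lens,
                     ssr_type = "perfect", motif = "A",
                     canonical_motif = "A", motif_len = 1L,
                     repeats = lens, length_bp = lens, score = 0L,
                     n_edits = 0L)
  got <- as.character(assign_region(loci, idx)$region)
  want <- vapply(seq_len(nrow(loci)), function(i) {
    majority_region_oracle(loci$start[i], loci$end[i], genes)
  }, character(1))
  agree <- got == want
  expect_gte(mean(agree), 0.99)
  # every disagreement must straddle a compartment boundary
  for (i in which(!agree)) {
    per_base <- vapply(loci$start[i]:(loci$end[i] - 1L), function(b) {
      majority_region_oracle(b, b + 1L, genes)
    }, character(1))
    expect_gt(length(unique(per_base)), 1L)
  }
})

test_that("positional profiles do rank arithmetic from both gene ends", {
  # plus-strand gene with 5 exons of 100 bp separated by 100 bp introns
  exons <- cbind(seq(0L, 1600L, by = 400L),
                 seq(100L, 1700L, by = 400L))
  p <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(gene_spec("c", "+", exons,
                                        gene_id = "g5")), p)
  idx <- build_annotation_index(p)
  locus_at <- function(start) {
    data.frame(seq_id = "c", start = start, end = start + 20L,
               ssr_type = "perfect", motif = "A", canonical_motif = "A",
               motif_len = 1L, repeats = 20L, length_bp = 20L,
               score = 0L, n_edits = 0L)
  }
  # an SSR in exon 2 counts at rank 2 from 5' and rank 4 from 3'
  prof <- positional_profile(locus_at(410L), idx, top_n = 30L)
  expect_equal(prof$exon_5p[2], 1L)
  expect_equal(prof$exon_3p[4], 1L)
  expect_equal(sum(prof$exon_5p), 1L)
  # truncation: rank above top_n contributes nothing from that end
  prof2 <- positional_profile(locus_at(810L), idx, top_n = 2L)  # exon 3
  expect_equal(sum(prof2$exon_5p) + sum(prof2$exon_3p), 0L)
  # intron hit mirrors the same arithmetic
  prof3 <- positional_profile(locus_at(150L), idx, top_n = 30L)  # intron 1
  expect_equal(prof3$intron_5p[1], 1L)
  expect_equal(prof3$intron_3p[4], 1L)
})

test_that("flipping every gene strand swaps the 5' and 3' profiles exactly", {
  g <- study_fixture()
  flipped <- lapply(g$gene_models, function(gs) {
    gs$strand <- if (gs$strand == "+") "-" else "+"
    gs
  })
  p <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(flipped, p)
  idx_flipped <- build_annotation_index(p)
  perf <- g$loci[g$loci$ssr_type == "perfect", ]
  prof <- positional_profile(perf, g$index)
  prof_f <- positional_profile(perf, idx_flipped)
  expect_identical(prof$exon_5p, prof_f$exon_3p)
  expect_identical(prof$exon_3p, prof_f$exon_5p)
  expect_identical(prof$intron_5p, prof_f$intron_3p)
  expect_identical(prof$intron_3p, prof_f$intron_5p)
})

test_that("multi-transcript genes use the longest transcript", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c\t.\tgene\t101\t1000\t.\t+\t.\tID=gA",
    "c\t.\tmRNA\t101\t1000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "c\t.\texon\t101\t200\t.\t+\t.\tID=e1;Parent=gA.t1",
    "c\t.\tmRNA\t101\t1000\t.\t+\t.\tID=gA.t2;Parent=gA",
    "c\t.\texon\t101\t300\t.\t+\t.\tID=e2;Parent=gA.t2",
    "c\t.\texon\t501\t1000\t.\t+\t.\tID=e3;Parent=gA.t2"), gff)
  idx <- build_annotation_index(gff)
  # t2 has 800 exonic bases vs 100 for t1
  expect_equal(length(idx$exons), 2L)
  expect_equal(length(idx$introns), 1L)
  expect_equal(BiocGenerics::start(idx$introns), 301L)
})
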