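mk_loci <- function(types = "perfect", motif = "A", repeats = 12L,
                    seq_id = "chr1", start = 0L) {
  n <- max(length(types), length(motif), length(repeats))
  types <- rep_len(types, n); motif <- rep_len(motif, n)
  repeats <- rep_len(repeats, n)
  len <- nchar(motif) * repeats
  start <- if (length(start) == n) start else
    cumsum(c(start, len[-n] + 50L))
  data.frame(seq_id = rep_len(seq_id, n), start = start,
             end = start + len, ssr_type = types, motif = motif,
             canonical_motif = vapply(motif, canonical_motif, ""),
             motif_len = nchar(motif), repeats = repeats,
             length_bp = len, score = 0L, n_edits = 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

test_that("type proportions sum to 100 and count loci once", {
  loci <- mk_loci(c(rep("imperfect", 70), rep("perfect", 28),
                    rep("compound", 2)))
  p <- type_proportions(loci)
  expect_equal(unname(p), c(28, 70, 2))
  expect_equal(sum(p), 100)
  expect_equal(unname(type_proportions(mk_loci(rep("perfect", 5)))),
               c(100, 0, 0))
  expect_error(type_proportions(mk_loci()[0, ]), "no loci")
  # compound members are not double-counted unless asked
  loci2 <- mk_loci(c("perfect", "perfect", "compound"))
  loci2$in_compound <- c(TRUE, TRUE, FALSE)
  expect_equal(unname(type_proportions(loci2)), c(0, 0, 100))
  expect_equal(unname(type_proportions(loci2,
                                       count_compound_members = TRUE)),
               c(200 / 3, 0, 100 / 3))
})

test_that("abundance and density are per-megabase ratios", {
  loci <- mk_loci(rep("perfect", 500))
  ad <- abundance_density(loci, 2e6)
  expect_equal(ad$loci_per_mb, 250)
  one <- abundance_density(mk_loci(repeats = 24L), 1e6)
  expect_equal(one$bp_per_mb, 24)
  expect_error(abundance_density(loci, 0), "positive")
  # stratified results sum to the total
  g <- study_fixture()
  perf <- g$loci[g$loci$ssr_type == "perfect", ]
  tot <- abundance_density(perf, sum(nchar(g$sequences)))
  strat <- abundance_density(perf, sum(nchar(g$sequences)),
                             by = "motif_len")
  expect_equal(sum(strat$loci_per_mb), tot$loci_per_mb)
  expect_equal(sum(strat$bp_per_mb), tot$bp_per_mb)
})

test_that("RCN histograms count integer repeat classes", {
  h <- rcn_histogram(mk_loci(repeats = c(12L, 12L, 13L)))
  expect_equal(h$count[h$repeats == 12], 2L)
  expect_equal(h$count[h$repeats == 13], 1L)
  expect_equal(sum(h$count), 3L)
  expect_equal(nrow(rcn_histogram(mk_loci()[0, ])), 0L)
})

test_that("CV of RCN matches the closed form and is scale invariant", {
  cv0 <- cv_rcn(mk_loci(repeats = c(4L, 4L, 4L)))
  expect_equal(cv0$cv, 0)
  cv <- cv_rcn(mk_loci(repeats = c(2L, 4L, 6L)))
  expect_equal(cv$mean_rcn, 4)
  expect_equal(cv$cv, 50)
  cv3 <- cv_rcn(mk_loci(repeats = 3L * c(2L, 4L, 6L)))
  expect_equal(cv3$cv, 50)
  # fewer than two loci: missing, not a number
  expect_true(is.na(cv_rcn(mk_loci(repeats = 12L))$cv))
})

test_that("GC content is computed from the actual locus spans", {
  seqs <- c(chr1 = paste0(strrep("AT", 10), strrep("CG", 7),
                          strrep("AACG", 4)))
  loci <- mk_loci(motif = c("AT", "CG", "AACG"),
                  repeats = c(10L, 7L, 4L),
                  start = c(0L, 20L, 34L))
  gc <- gc_content(loci, seqs, by = "motif")
  expect_equal(gc$gc[gc$motif == "AT"], 0)
  expect_equal(gc$gc[gc$motif == "CG"], 1)
  expect_equal(gc$gc[gc$motif == "AACG"], 0.5)
})

test_that("motif preference matrices cover classes and apply top-n", {
  # one species, one (AG)x9 locus in 1 Mb
  lone <- list(sp1 = mk_loci(motif = "AG", repeats = 9L))
  mp <- motif_preference(lone, c(sp1 = 1e6), classes = 2L)
  expect_equal(mp[["2"]]$abundance["sp1", "AG"], 1)
  expect_equal(mp[["2"]]$density["sp1", "AG"], 18)

  # all four dinucleotide classes present -> exactly four columns
  di <- unique(canonical_motif(primitive_motifs(2)))
  both <- list(a = mk_loci(motif = di, repeats = 8L),
               b = mk_loci(motif = di[1:2], repeats = 8L))
  mp2 <- motif_preference(both, c(a = 1e6, b = 1e6), classes = 2L)
  expect_equal(sort(colnames(mp2[["2"]]$abundance)), sort(di))
  expect_equal(ncol(mp2[["2"]]$abundance), motif_class_count(2))

  # hexa class: columns capped at top_n, ranked by mean abundance with
  # lexicographic tie-break
  hexa <- unique(canonical_motif(primitive_motifs(6)))[1:30]
  lots <- list(s = mk_loci(motif = hexa, repeats = 4L))
  mp3 <- motif_preference(lots, c(s = 1e6), top_n = 25L, classes = 6L)
  expect_equal(ncol(mp3[["6"]]$abundance), 25L)
  expect_equal(colnames(mp3[["6"]]$abundance), sort(hexa)[1:25])

  # per-motif abundance sums to the class-level abundance
  g <- study_fixture()
  perf <- g$loci[g$loci$ssr_type == "perfect", ]
  glen <- sum(nchar(g$sequences))
  mp4 <- motif_preference(list(spA = perf), setNames(glen, "spA"),
                          classes = 1:3)
  for (k in 1:3) {
    cls <- abundance_density(perf[perf$motif_len == k, ], glen)
    expect_equal(sum(mp4[[as.character(k)]]$abundance),
                 cls$loci_per_mb)
    expect_equal(sum(mp4[[as.character(k)]]$density), cls$bp_per_mb)
  }
  # density is never below abundance times the minimum locus length
  thr <- detector_params()$min_repeats
  for (k in 1:3) {
    ab <- mp4[[as.character(k)]]$abundance
    de <- mp4[[as.character(k)]]$density
    expect_true(all(de >= ab * k * thr[k] - 1e-9))
  }
})
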