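test_that("minimum repeat thresholds are exact per motif-length class", {
  thr <- detector_params()$min_repeats
  for (k in 1:6) {
    m <- boundary_motifs[k]
    at <- find_perfect_ssrs(paste0("GG", strrep(m, thr[k]), "GG"))
    expect_equal(nrow(at), 1L)
    expect_equal(at$motif_len, k)
    expect_equal(at$repeats, thr[k])
    expect_equal(at$length_bp, thr[k] * k)
    below <- find_perfect_ssrs(paste0("GG", strrep(m, thr[k] - 1L), "GG"))
    expect_equal(nrow(below), 0L)
  }
})

test_that("runs are reported at their shortest primitive period", {
  # (ACAC)x4 is (AC)x8, a dinucleotide locus
  hit <- find_perfect_ssrs(strrep("ACAC", 4))
  expect_equal(hit$motif_len, 2L)
  expect_equal(hit$repeats, 8L)
  # a pure mononucleotide run is never reported as "AA"
  hit <- find_perfect_ssrs(paste0("G", strrep("A", 14), "G"))
  expect_equal(hit$motif, "A")
})

test_that("N breaks runs and invalid characters are rejected with position", {
  two <- find_perfect_ssrs(paste0(strrep("A", 20), "N", strrep("A", 20)))
  expect_equal(nrow(two), 2L)
  expect_equal(two$start, c(0L, 21L))
  expect_error(find_perfect_ssrs("ACGTXACGT"), "position 5")
  expect_equal(nrow(find_perfect_ssrs("")), 0L)
})

test_that("perfect calls equal the regex brute-force oracle on random sequences", {
  set.seed(42)
  params <- detector_params()
  n_identical <- 0L
  for (i in 1:150) {
    gc <- sample(c(0.3, 0.5, 0.7, 0.85), 1)
    s <- random_dna(10000, gc)
    # spike half the sequences with near-threshold arrays so the
    # comparison exercises accepts, rejects and overlap resolution
    if (i %% 2 == 0) {
      for (j in 1:3) {
        k <- sample(1:6, 1)
        m <- sample(primitive_motifs(k), 1)
        r <- params$min_repeats[k] + sample(-1:3, 1)
        pos <- sample(9000, 1)
        s <- paste0(substr(s, 1, pos), strrep(m, r),
                    substr(s, pos + 1, nchar(s)))
      }
    }
    mine <- find_perfect_ssrs(s, params)
    oracle <- regex_perfect_oracle(s, params$min_repeats)
    same <- identical(mine$start, oracle$start) &&
      identical(mine$end, oracle$end) &&
      identical(mine$motif, oracle$motif) &&
      identical(mine$repeats, oracle$repeats)
    if (!same) {
      fail(sprintf("oracle mismatch on sequence %d", i))
    }
    n_identical <- n_identical + 1L
  }
  expect_equal(n_identical, 150L)
})

test_that("detection is strand symmetric up to coordinate mirroring", {
  set.seed(9)
  thr <- detector_params()$min_repeats
  for (i in 1:20) {
    # plant whole-copy arrays in clean background: maximal runs then carry
    # no partial copy, so mirrored coordinates are exact
    chunks <- character(0)
    for (j in 1:3) {
      k <- sample(1:6, 1)
      m <- boundary_motifs[k]
      chunks <- c(chunks, random_dna(400, 0.5), "G",
                  strrep(m, thr[k] + sample(0:2, 1)), "G")
    }
    s <- paste0(paste(chunks, collapse = ""), random_dna(400, 0.5))
    fwd <- find_perfect_ssrs(s)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    bwd <- find_perfect_ssrs(rc)
    expect_equal(nrow(fwd), nrow(bwd))
    if (nrow(fwd) > 0L) {
      n <- nchar(s)
      mirrored <- data.frame(start = n - rev(bwd$end),
                             end = n - rev(bwd$start),
                             canonical = rev(bwd$canonical_motif))
      expect_equal(fwd$start, mirrored$start)
      expect_equal(fwd$end, mirrored$end)
      expect_equal(fwd$canonical_motif, mirrored$canonical)
    }
  }
})

test_that("no base belongs to two perfect loci", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_dna(5000, gc = 0.85)
    loci <- find_perfect_ssrs(s)
    if (nrow(loci) > 1L) {
      expect_true(all(loci$start[-1] >= loci$end[-nrow(loci)]))
    }
    # for perfect loci the span is an exact tiling of the motif
    for (r in seq_len(nrow(loci))) {
      span <- substr(s, loci$start[r] + 1, loci$end[r])
      expect_equal(span, strrep(loci$motif[r], loci$repeats[r]))
    }
  }
})

test_that("imperfect detection follows the seed-and-extend scoring", {
  # one substitution bridging two 8 bp seeds: 17 bp, score 8+8-1
  imp <- find_imperfect_ssrs(paste0(strrep("A", 8), "C", strrep("A", 8)))
  expect_equal(nrow(imp), 1L)
  expect_equal(c(imp$start, imp$end), c(0L, 17L))
  expect_equal(imp$n_edits, 1L)
  expect_equal(imp$score, 15L)

  # a pure run carries no edits and is left to the perfect detector
  expect_equal(nrow(find_imperfect_ssrs(strrep("A", 12))), 0L)

  # too-short seed: (AC)x3 is only 6 bp
  expect_equal(nrow(find_imperfect_ssrs(paste0(strrep("AC", 3), "TT",
                                               "GATGGTCAGT"))), 0L)

  # an interruption only counts when the array continues beyond it
  expect_equal(nrow(find_imperfect_ssrs(paste0(strrep("A", 8), "C",
                                               strrep("A", 7)))), 0L)
})

test_that("imperfect extension classifies substitutions and indels", {
  # deletion: (AC)x5 then (CA)x6+C after deleting one A
  del <- find_imperfect_ssrs(paste0(strrep("AC", 5), substr(strrep("CA", 7), 1, 13)))
  expect_equal(nrow(del), 1L)
  expect_equal(del$n_edits, 1L)
  expect_equal(del$score, 10L + 13L - 2L)

  # insertion of a foreign base between two (AC)x5 arrays
  ins <- find_imperfect_ssrs(paste0(strrep("AC", 5), "G", strrep("AC", 5)))
  expect_equal(nrow(ins), 1L)
  expect_equal(c(ins$start, ins$end), c(0L, 21L))
  expect_equal(ins$n_edits, 1L)
  expect_equal(ins$score, 10L + 10L - 2L)
})

test_that("compound loci chain perfect loci by gap threshold", {
  params <- detector_params()
  mk <- function(gaps, motifs = NULL, reps = NULL) {
    # lay consecutive perfect arrays separated by the given gaps
    n <- length(gaps) + 1L
    if (is.null(motifs)) motifs <- rep(c("AC", "AAG"), length.out = n)
    if (is.null(reps)) reps <- ifelse(nchar(motifs) == 2, 8L, 6L)
    s <- ""
    rows <- list()
    for (i in seq_len(n)) {
      start <- nchar(s)
      s <- paste0(s, strrep(motifs[i], reps[i]))
      rows[[i]] <- data.frame(seq_id = "seq", start = start,
                              end = nchar(s), ssr_type = "perfect",
                              motif = motifs[i],
                              canonical_motif = canonical_motif(motifs[i]),
                              motif_len = nchar(motifs[i]),
                              repeats = reps[i],
                              length_bp = nchar(motifs[i]) * reps[i],
                              score = 0L, n_edits = 0L)
      if (i < n) s <- paste0(s, strrep("G", gaps[i]))
    }
    do.call(rbind, rows)
  }
  one <- find_compound_ssrs(mk(5L), params)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_members, 2L)
  expect_equal(nrow(find_compound_ssrs(mk(11L), params)), 0L)
  chain <- find_compound_ssrs(mk(c(3L, 8L)), params)
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$n_members, 3L)
  expect_equal(chain$start, 0L)
  # the compound spans first member start to last member end
  mem <- chain$members[[1]]
  expect_equal(chain$end, mem$end[3])
})

test_that("detect_ssrs flags compound members and keeps coordinates consistent", {
  s <- paste0(random_dna(200, 0.5), strrep("AC", 8), "GGTGG",
              strrep("AAG", 6), random_dna(200, 0.5))
  set.seed(2)
  loci <- detect_ssrs(c(chrZ = s))
  perf <- loci[loci$ssr_type == "perfect", ]
  comp <- loci[loci$ssr_type == "compound", ]
  expect_gte(nrow(perf), 2L)
  expect_equal(nrow(comp), 1L)
  expect_equal(sum(perf$in_compound), 2L)
  expect_equal(comp$n_members, 2L)
})
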