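# Independent oracles used by the tests. These deliberately take different
# computational routes from the package implementation.

# Brute-force perfect-SSR finder built on PCRE backreferences: for each
# period p, a greedy regex '([ACGT]{p})\1{k-1,}' proposes maximal tandem
# candidates; candidates are resolved leftmost-first with the shortest
# primitive period winning, and the suffix after each accepted locus is
# rescanned so runs straddling an accepted boundary are re-evaluated.
regex_perfect_oracle <- function(seq, min_repeats = c(12L, 7L, 5L, 4L, 4L, 4L)) {
  out <- list()
  offset <- 0L                       # 0-based start of the current suffix
  while (nchar(seq) > 0L) {
    best <- NULL
    for (p in 1:6) {
      k <- min_repeats[p]
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, k - 1L)
      m <- gregexpr(pat, seq, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (j in seq_along(m)) {
        st <- m[j]
        motif <- substr(seq, st, st + p - 1L)
        if (!avissr::is_primitive_motif(motif)) next
        reps <- attr(m, "match.length")[j] %/% p
        cand <- list(start = st - 1L, p = p, repeats = reps, motif = motif)
        if (is.null(best) || cand$start < best$start ||
            (cand$start == best$start && cand$p < best$p)) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    out[[length(out) + 1L]] <- data.frame(
      start = offset + best$start,
      end = offset + best$start + best$repeats * best$p,
      motif = best$motif, motif_len = best$p, repeats = best$repeats,
      stringsAsFactors = FALSE)
    consumed <- best$start + best$repeats * best$p
    seq <- substr(seq, consumed + 1L, nchar(seq))
    offset <- offset + consumed
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), motif_len = integer(),
                      repeats = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Canonical-class count by a route independent of lexicographic-minimum
# canonicalization: union-find over the rotation and reverse-complement
# graph of all primitive k-mers.
union_find_class_count <- function(k) {
  mot <- avissr::primitive_motifs(k)
  idx <- seq_along(mot)
  names(idx) <- mot
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  rot1 <- function(m) paste0(substr(m, 2, k), substr(m, 1, 1))
  for (m in mot) {
    union(idx[[m]], idx[[rot1(m)]])
    union(idx[[m]], idx[[avissr::revcomp(m)]])
  }
  length(unique(vapply(idx, find, numeric(1))))
}

# Per-base majority compartment of a locus, straight from the gene models
# (not from the annotation index): every base is labeled with precedence
# CDS > exon_noncoding > intron > intergenic and the locus takes the
# plurality label, ties resolved by the same precedence.
majority_region_oracle <- function(start0, end0, genes) {
  labs <- vapply(start0:(end0 - 1L), function(b) {
    lab <- "intergenic"
    for (g in genes) {
      span <- range(g$exons)
      if (b < span[1] || b >= span[2]) next
      if (!is.null(g$cds) && any(b >= g$cds[, 1] & b < g$cds[, 2])) {
        return("CDS")
      }
      if (any(b >= g$exons[, 1] & b < g$exons[, 2])) {
        return("exon_noncoding")
      }
      lab <- "intron"
    }
    lab
  }, character(1))
  counts <- table(factor(labs, levels = c("CDS", "exon_noncoding",
                                          "intron", "intergenic")))
  names(counts)[which.max(counts)]
}
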