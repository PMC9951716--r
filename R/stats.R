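# Summary statistics over detected SSR loci: type proportions, abundance
# and density, RCN histograms, CV of RCN, GC content and motif-preference
# matrices.

# each genomic locus counted once: perfect loci absorbed into a compound
# are dropped when the flag is present
count_once <- function(loci, count_compound_members = FALSE) {
  if (!count_compound_members && "in_compound" %in% names(loci)) {
    loci <- loci[!(loci$ssr_type == "perfect" & loci$in_compound), ,
                 drop = FALSE]
  }
  loci
}

#' Proportions of perfect, imperfect and compound SSRs
#'
#' @param loci Locus data.frame from \code{\link{detect_ssrs}}.
#' @param count_compound_members If \code{FALSE} (default), perfect loci
#'   absorbed into a compound locus are not counted again as perfect.
#' @return Named numeric vector \code{c(perfect=, imperfect=, compound=)}
#'   of percentages summing to 100.
#' @export
type_proportions <- function(loci, count_compound_members = FALSE) {
  loci <- count_once(loci, count_compound_members)
  if (nrow(loci) == 0L) stop("no loci")
  n <- table(factor(loci$ssr_type,
                    levels = c("perfect", "imperfect", "compound")))
  setNames(100 * as.vector(n) / sum(n),
           c("perfect", "imperfect", "compound"))
}

#' SSR abundance (loci/Mb) and density (bp/Mb)
#'
#' @param loci Locus data.frame.
#' @param genome_length Total genome length in bases.
#' @param by Optional column name(s) of \code{loci} to stratify by (e.g.
#'   \code{"motif_len"} or \code{c("motif_len", "region")}).
#' @return A data.frame with \code{n_loci}, \code{loci_per_mb} and
#'   \code{bp_per_mb} per stratum (one row when \code{by} is NULL).
#' @export
abundance_density <- function(loci, genome_length, by = NULL) {
  if (length(genome_length) != 1L || genome_length <= 0) {
    stop("genome_length must be a single positive number")
  }
  f <- 1e6 / genome_length
  if (is.null(by)) {
    return(data.frame(n_loci = nrow(loci),
                      loci_per_mb = nrow(loci) * f,
                      bp_per_mb = sum(loci$length_bp) * f))
  }
  groups <- interaction(loci[by], drop = TRUE, sep = "|")
  rows <- lapply(levels(groups), function(g) {
    sub <- loci[groups == g, , drop = FALSE]
    cbind(sub[1L, by, drop = FALSE],
          data.frame(n_loci = nrow(sub),
                     loci_per_mb = nrow(sub) * f,
                     bp_per_mb = sum(sub$length_bp) * f))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram of repeat copy number per motif-length class
#'
#' @param loci Perfect loci only.
#' @return Data.frame with \code{motif_len}, \code{repeats}, \code{count};
#'   counts sum to the number of loci.
#' @export
rcn_histogram <- function(loci) {
  loci <- loci[loci$ssr_type == "perfect", , drop = FALSE]
  if (nrow(loci) == 0L) {
    return(data.frame(motif_len = integer(), repeats = integer(),
                      count = integer()))
  }
  tab <- as.data.frame(table(motif_len = loci$motif_len,
                             repeats = loci$repeats),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  out <- data.frame(motif_len = as.integer(tab$motif_len),
                    repeats = as.integer(tab$repeats),
                    count = as.integer(tab$Freq))
  out[order(out$motif_len, out$repeats), , drop = FALSE]
}

#' Coefficient of variability of repeat copy number
#'
#' CV = 100 * sd/mean of the repeat copy numbers in each group, with the
#' sample (n-1) standard deviation. Groups with fewer than two loci give
#' \code{NA} (a CV needs at least two observations) and are reported as
#' missing.
#'
#' @param loci Perfect loci (data.frame with \code{repeats}).
#' @param by Column name(s) to group by, default
#'   \code{c("motif_len", "region")} when present.
#' @return Data.frame of groups with \code{n}, \code{mean_rcn}, \code{cv}
#'   (percent).
#' @export
cv_rcn <- function(loci, by = intersect(c("motif_len", "region"),
                                        names(loci))) {
  loci <- loci[loci$ssr_type == "perfect", , drop = FALSE]
  if (length(by) == 0L) {
    loci$all <- "all"
    by <- "all"
  }
  groups <- interaction(loci[by], drop = TRUE, sep = "|")
  rows <- lapply(levels(groups), function(g) {
    sub <- loci[groups == g, , drop = FALSE]
    rcn <- sub$repeats
    cv <- if (length(rcn) < 2L) NA_real_ else 100 * sd(rcn) / mean(rcn)
    cbind(sub[1L, by, drop = FALSE],
          data.frame(n = length(rcn), mean_rcn = mean(rcn), cv = cv))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' GC content of SSR loci per group
#'
#' Fraction of G+C bases over the concatenated spans of the loci in each
#' group, computed from the genome sequence.
#'
#' @param loci Locus data.frame (0-based half-open coordinates).
#' @param sequences Named character vector or \code{DNAStringSet} holding
#'   the sequences the loci were called on.
#' @param by Column name(s) to group by, default \code{"motif_len"}.
#' @return Data.frame of groups with \code{n}, \code{total_bp}, \code{gc}
#'   in [0,1].
#' @export
gc_content <- function(loci, sequences,
                       by = intersect(c("motif_len", "region"),
                                      names(loci))) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (length(by) == 0L) {
    loci$all <- "all"
    by <- "all"
  }
  spans <- substring(sequences[loci$seq_id], loci$start + 1L, loci$end)
  groups <- interaction(loci[by], drop = TRUE, sep = "|")
  rows <- lapply(levels(groups), function(g) {
    s <- paste(spans[groups == g], collapse = "")
    freq <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
    acgt <- sum(freq[c("A", "C", "G", "T")])
    cbind(loci[groups == g, , drop = FALSE][1L, by, drop = FALSE],
          data.frame(n = sum(groups == g), total_bp = nchar(s),
                     gc = if (acgt == 0L) NA_real_ else
                       sum(freq[c("G", "C")]) / acgt))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species-by-motif preference matrices (loci/Mb and bp/Mb)
#'
#' Builds, per motif-length class, matrices of abundance (loci/Mb) and
#' density (bp/Mb) with one row per species and one column per canonical
#' motif. Di- and trinucleotide classes keep all canonical classes; for
#' tetra-, penta- and hexanucleotide classes the columns are restricted to
#' the \code{top_n} motifs ranked by mean abundance across species (ties
#' broken lexicographically).
#'
#' @param loci_by_species Named list of perfect-locus data.frames, one per
#'   species.
#' @param genome_lengths Named numeric vector of genome lengths (bases)
#'   per species.
#' @param top_n Number of motif columns retained for classes of length
#'   >= 4 (default 25).
#' @param classes Motif lengths to tabulate (default 1:6).
#' @return A list per class: \code{list(abundance = matrix,
#'   density = matrix)} with species rows and canonical-motif columns.
#' @export
motif_preference <- function(loci_by_species, genome_lengths, top_n = 25L,
                             classes = 1:6) {
  stopifnot(is.list(loci_by_species), !is.null(names(loci_by_species)),
            all(names(loci_by_species) %in% names(genome_lengths)))
  species <- names(loci_by_species)
  out <- list()
  for (k in classes) {
    motifs <- sort(unique(unlist(lapply(loci_by_species, function(l) {
      l$canonical_motif[l$ssr_type == "perfect" & l$motif_len == k]
    }))))
    ab <- matrix(0, nrow = length(species), ncol = length(motifs),
                 dimnames = list(species, motifs))
    de <- ab
    for (sp in species) {
      l <- loci_by_species[[sp]]
      l <- l[l$ssr_type == "perfect" & l$motif_len == k, , drop = FALSE]
      f <- 1e6 / genome_lengths[[sp]]
      if (nrow(l) > 0L) {
        cnt <- tapply(rep(1L, nrow(l)), l$canonical_motif, sum)
        bp <- tapply(l$length_bp, l$canonical_motif, sum)
        ab[sp, names(cnt)] <- cnt * f
        de[sp, names(bp)] <- bp * f
      }
    }
    if (k >= 4L && ncol(ab) > top_n) {
      rank_key <- order(-colMeans(ab), colnames(ab))
      keep <- sort(rank_key[seq_len(top_n)])
      ab <- ab[, keep, drop = FALSE]
      de <- de[, keep, drop = FALSE]
    }
    out[[as.character(k)]] <- list(abundance = ab, density = de)
  }
  out
}
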