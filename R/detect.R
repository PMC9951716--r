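# Detection of perfect, imperfect and compound microsatellites.
# Coordinates are 0-based half-open throughout the in-memory tables;
# TSV export converts to 1-based inclusive (see write_loci_tsv).

#' Detector parameters
#'
#' Thresholds controlling SSR detection. \code{min_repeats} gives the
#' minimum repeat copy number for a perfect SSR per motif length
#' (mono- to hexanucleotide); the defaults 12, 7, 5, 4, 4, 4 are the
#' detection standard for avian and other vertebrate genome surveys.
#' Imperfect detection is seed-and-extend: a perfect tandem run with at
#' least \code{seed_min_repeats} copies and \code{seed_min_length} bases is
#' extended outward scoring +1 per matching base, -\code{mismatch_penalty}
#' per substitution and -\code{gap_penalty} per inserted or deleted base,
#' stopping once more than \code{max_consecutive_edits} consecutive edited
#' positions accumulate; a locus is reported when its total score reaches
#' \code{min_score} and it contains at least one edit. Two or more perfect
#' loci separated by gaps of at most \code{compound_max_gap} bases form a
#' compound SSR.
#'
#' @param min_repeats Integer vector of length 6, minimum copies per motif
#'   length class.
#' @param compound_max_gap Maximum gap (bases) joining perfect loci into a
#'   compound SSR.
#' @param seed_min_repeats,seed_min_length Seed thresholds for imperfect
#'   detection (copies, bases).
#' @param max_consecutive_edits Extension stops after this many consecutive
#'   edited positions.
#' @param mismatch_penalty,gap_penalty Score penalties per substitution and
#'   per indel base.
#' @param min_score Minimum alignment score of a reported imperfect locus.
#' @param xdrop Extension stops when the running score falls this far below
#'   the best committed score (X-drop termination), so an extension cannot
#'   wander indefinitely through unrelated sequence on occasional chance
#'   matches.
#' @return A list of class \code{"detector_params"}.
#' @export
detector_params <- function(min_repeats = c(12L, 7L, 5L, 4L, 4L, 4L),
                            compound_max_gap = 10L,
                            seed_min_repeats = 3L,
                            seed_min_length = 8L,
                            max_consecutive_edits = 3L,
                            mismatch_penalty = 1L,
                            gap_penalty = 2L,
                            min_score = 10L,
                            xdrop = 10L) {
  min_repeats <- as.integer(min_repeats)
  if (length(min_repeats) != 6L || any(min_repeats < 1L)) {
    stop("min_repeats must be six positive integers (mono..hexa)")
  }
  scalars <- c(compound_max_gap = compound_max_gap,
               seed_min_repeats = seed_min_repeats,
               seed_min_length = seed_min_length,
               max_consecutive_edits = max_consecutive_edits,
               mismatch_penalty = mismatch_penalty,
               gap_penalty = gap_penalty, min_score = min_score,
               xdrop = xdrop)
  if (any(scalars < 1)) stop("all detector thresholds must be positive")
  structure(list(min_repeats = min_repeats,
                 compound_max_gap = as.integer(compound_max_gap),
                 seed_min_repeats = as.integer(seed_min_repeats),
                 seed_min_length = as.integer(seed_min_length),
                 max_consecutive_edits = as.integer(max_consecutive_edits),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_penalty = as.integer(gap_penalty),
                 min_score = as.integer(min_score),
                 xdrop = as.integer(xdrop)),
            class = "detector_params")
}

empty_loci <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             ssr_type = character(), motif = character(),
             canonical_motif = character(), motif_len = integer(),
             repeats = integer(), length_bp = integer(),
             score = integer(), n_edits = integer(),
             stringsAsFactors = FALSE)
}

as_seq_string <- function(sequence) {
  if (methods::is(sequence, "DNAString") ||
      methods::is(sequence, "DNAStringSet")) {
    sequence <- as.character(sequence)
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  toupper(sequence)
}

check_alphabet <- function(seq) {
  pos <- first_invalid_base_cpp(seq)
  if (pos > 0L) {
    stop("invalid character '", substr(seq, pos, pos),
         "' at position ", pos, " (expected A/C/G/T/N)")
  }
  invisible(seq)
}

#' Find perfect microsatellites in one sequence
#'
#' Scans for maximal tandem runs of primitive 1-6 bp motifs with repeat
#' copy number at or above the class threshold. A run reportable under two
#' motif lengths is reported only at its shortest primitive period (a run
#' of "ACACAC..." is a dinucleotide locus, never a tetranucleotide one).
#' Overlapping candidate runs are resolved leftmost-first: once a locus is
#' accepted, scanning resumes at its end, so no base belongs to two loci.
#' Runs containing N are broken at the N.
#'
#' @param sequence A character string or \code{DNAString} over
#'   \code{A,C,G,T,N}.
#' @param params A \code{\link{detector_params}} object.
#' @param seq_id Sequence name recorded in the output.
#' @return A data.frame of loci (0-based half-open \code{start}/\code{end})
#'   with motif, canonical motif, repeat copy number (RCN) and length;
#'   sorted by start. For perfect loci \code{length_bp == repeats * motif_len}
#'   exactly.
#' @export
find_perfect_ssrs <- function(sequence, params = detector_params(),
                              seq_id = "seq") {
  seq <- check_alphabet(as_seq_string(sequence))
  if (nchar(seq) == 0L) return(empty_loci())
  hits <- scan_perfect_cpp(seq, params$min_repeats, 6L)
  if (nrow(hits) == 0L) return(empty_loci())
  motif <- substring(seq, hits$start + 1L, hits$start + hits$period)
  data.frame(seq_id = seq_id,
             start = hits$start,
             end = hits$start + hits$repeats * hits$period,
             ssr_type = "perfect",
             motif = motif,
             canonical_motif = canonical_motif(motif),
             motif_len = hits$period,
             repeats = hits$repeats,
             length_bp = hits$repeats * hits$period,
             score = hits$repeats * hits$period,
             n_edits = 0L,
             stringsAsFactors = FALSE)
}

# Greedy one-directional extension of a tandem array allowing substitutions
# and single-base indels, chosen by one-base lookahead. `y` is the sequence
# ahead of the seed (already oriented so extension reads left to right) and
# `m` the motif in the same orientation, phased so m[1] is the expected next
# character. The extension is committed only at matching bases, and once an
# edit has occurred, only after a tandem segment of at least
# `seed_min_length` matches has followed the last edit: an interruption is
# part of the array only when the array demonstrably continues beyond it.
# This keeps flanking noise around a pure run from being annexed as edits.
extend_tandem <- function(y, m, params) {
  p <- length(m); n <- length(y)
  i <- 1L; phase <- 1L; consec <- 0L; streak <- 0L
  score <- 0L; edits <- 0L
  best <- list(len = 0L, score = 0L, edits = 0L)
  while (i <= n) {
    expected <- m[phase]
    if (y[i] == expected) {
      score <- score + 1L; consec <- 0L; streak <- streak + 1L
      if (edits == 0L || streak >= params$seed_min_length) {
        best <- list(len = i, score = score, edits = edits)
      }
      i <- i + 1L; phase <- phase %% p + 1L
      next
    }
    nxt <- m[phase %% p + 1L]
    if (i < n && y[i + 1L] == nxt) {            # substitution
      score <- score - params$mismatch_penalty
      i <- i + 1L; phase <- phase %% p + 1L
    } else if (y[i] == nxt && p > 1L) {         # deletion from the array
      score <- score - params$gap_penalty
      phase <- phase %% p + 1L
    } else if (i < n && y[i + 1L] == expected) {  # insertion into the array
      score <- score - params$gap_penalty
      i <- i + 1L
    } else {
      score <- score - params$mismatch_penalty
      i <- i + 1L; phase <- phase %% p + 1L
    }
    edits <- edits + 1L
    consec <- consec + 1L
    streak <- 0L
    if (consec > params$max_consecutive_edits) break
    if (score <= best$score - params$xdrop) break
  }
  best
}

#' Find imperfect microsatellites in one sequence
#'
#' Seed-and-extend detection of tandem arrays interrupted by substitutions
#' or short indels. Seeds are perfect runs with at least
#' \code{seed_min_repeats} copies and \code{seed_min_length} bases; each
#' seed is extended in both directions under the scoring scheme of
#' \code{\link{detector_params}}. A locus is reported when its score
#' reaches \code{min_score} and it carries at least one edit; pure perfect
#' runs are reported only by \code{\link{find_perfect_ssrs}}. An imperfect
#' locus may span loci that also qualify as perfect.
#'
#' @inheritParams find_perfect_ssrs
#' @param perfect_loci The perfect loci of the same sequence (used only for
#'   interface symmetry; zero-edit candidates are suppressed by the
#'   \code{n_edits} rule).
#' @return A data.frame of imperfect loci with alignment \code{score} and
#'   \code{n_edits}.
#' @export
find_imperfect_ssrs <- function(sequence, perfect_loci = NULL,
                                params = detector_params(),
                                seq_id = "seq") {
  seq <- check_alphabet(as_seq_string(sequence))
  if (nchar(seq) == 0L) return(empty_loci())
  seed_thr <- pmax(params$seed_min_repeats,
                   ceiling(params$seed_min_length / 1:6))
  seeds <- scan_perfect_cpp(seq, as.integer(seed_thr), 6L)
  if (nrow(seeds) == 0L) return(empty_loci())
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- list()
  last_end <- -1L
  for (r in seq_len(nrow(seeds))) {
    s0 <- seeds$start[r]; p <- seeds$period[r]
    e0 <- s0 + seeds$repeats[r] * p
    if (s0 < last_end) next     # seed swallowed by a previous extension
    m <- x[(s0 + 1L):(s0 + p)]
    # seed length is a whole number of copies, so rightward extension expects
    # the motif from phase 1; leftward extension reads the mirror image
    right <- extend_tandem(if (e0 < length(x)) x[(e0 + 1L):length(x)] else character(0),
                           m, params)
    left <- extend_tandem(if (s0 > 0L) rev(x[1:s0]) else character(0),
                          rev(m), params)
    start <- s0 - left$len
    end <- e0 + right$len
    score <- (e0 - s0) + left$score + right$score
    n_edits <- left$edits + right$edits
    if (n_edits >= 1L && score >= params$min_score) {
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id, start = start, end = end,
        ssr_type = "imperfect",
        motif = paste(m, collapse = ""),
        canonical_motif = canonical_motif(paste(m, collapse = "")),
        motif_len = p,
        repeats = as.integer(round((end - start) / p)),
        length_bp = end - start,
        score = as.integer(score), n_edits = as.integer(n_edits),
        stringsAsFactors = FALSE)
      last_end <- end
    } else {
      last_end <- max(last_end, e0)
    }
  }
  if (length(out) == 0L) return(empty_loci())
  do.call(rbind, out)
}

#' Find compound microsatellites
#'
#' Joins maximal chains of two or more perfect loci whose adjacent gaps are
#' at most \code{compound_max_gap} bases into compound loci. Member loci
#' are retained in the \code{members} list-column so that genomic loci can
#' be counted once: perfect loci absorbed into a compound are identified by
#' \code{member_rows}.
#'
#' @param perfect_loci Data.frame of perfect loci of one sequence, sorted
#'   by start.
#' @param params A \code{\link{detector_params}} object.
#' @return A data.frame of compound loci with \code{n_members},
#'   \code{members} (list of member data.frames) and \code{member_rows}
#'   (list of row indices into \code{perfect_loci}).
#' @export
find_compound_ssrs <- function(perfect_loci, params = detector_params()) {
  empty <- cbind(empty_loci(),
                 data.frame(n_members = integer()))
  empty$members <- list()
  empty$member_rows <- list()
  if (is.null(perfect_loci) || nrow(perfect_loci) == 0L) return(empty)
  perfect_loci <- perfect_loci[order(perfect_loci$seq_id,
                                     perfect_loci$start), , drop = FALSE]
  rownames(perfect_loci) <- NULL
  n <- nrow(perfect_loci)
  gap_ok <- c(FALSE,
              perfect_loci$start[-1] - perfect_loci$end[-n] <=
                params$compound_max_gap &
              perfect_loci$seq_id[-1] == perfect_loci$seq_id[-n])
  chain_id <- cumsum(!gap_ok)
  out <- list()
  for (id in unique(chain_id)) {
    rows <- which(chain_id == id)
    if (length(rows) < 2L) next
    mem <- perfect_loci[rows, , drop = FALSE]
    comp <- data.frame(
      seq_id = mem$seq_id[1],
      start = mem$start[1], end = mem$end[nrow(mem)],
      ssr_type = "compound",
      motif = paste(mem$motif, collapse = "-"),
      canonical_motif = paste(mem$canonical_motif, collapse = "-"),
      motif_len = NA_integer_, repeats = NA_integer_,
      length_bp = mem$end[nrow(mem)] - mem$start[1],
      score = NA_integer_, n_edits = NA_integer_,
      n_members = nrow(mem),
      stringsAsFactors = FALSE)
    comp$members <- list(mem)
    comp$member_rows <- list(rows)
    out[[length(out) + 1L]] <- comp
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Detect all SSR classes in a set of sequences
#'
#' Runs perfect, imperfect and compound detection on every sequence and
#' returns one combined locus table. Perfect loci absorbed into a compound
#' locus carry \code{in_compound = TRUE} so downstream statistics can count
#' each genomic locus once.
#'
#' @param sequences Named character vector or \code{DNAStringSet}.
#' @param params A \code{\link{detector_params}} object.
#' @return A data.frame of loci across all sequences, sorted by sequence
#'   and start, with an \code{in_compound} flag on perfect loci.
#' @export
detect_ssrs <- function(sequences, params = detector_params()) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  res <- lapply(names(sequences), function(id) {
    perf <- find_perfect_ssrs(sequences[[id]], params, seq_id = id)
    imp <- find_imperfect_ssrs(sequences[[id]], perf, params, seq_id = id)
    comp <- find_compound_ssrs(perf, params)
    perf$in_compound <- rep(FALSE, nrow(perf))
    if (nrow(comp) > 0L) {
      perf$in_compound[unlist(comp$member_rows)] <- TRUE
      comp$members <- NULL
      comp$member_rows <- NULL
      comp$in_compound <- rep(FALSE, nrow(comp))
    } else {
      comp <- NULL
    }
    imp$in_compound <- rep(FALSE, nrow(imp))
    imp$n_members <- rep(NA_integer_, nrow(imp))
    perf$n_members <- rep(NA_integer_, nrow(perf))
    rbind(perf, imp, if (!is.null(comp)) comp)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) {
    out <- empty_loci()
    out$in_compound <- logical()
    out$n_members <- integer()
    return(out)
  }
  out[order(out$seq_id, out$start, out$end), , drop = FALSE]
}

#' Write a locus table as TSV
#'
#' Coordinates are converted to 1-based inclusive for human consumption;
#' the column names say so.
#'
#' @param loci Locus data.frame (0-based half-open).
#' @param path Output file.
#' @export
write_loci_tsv <- function(loci, path) {
  keep <- intersect(c("seq_id", "start", "end", "ssr_type", "motif",
                      "canonical_motif", "motif_len", "repeats",
                      "length_bp", "score", "n_edits", "in_compound",
                      "region"), names(loci))
  out <- loci[, keep, drop = FALSE]
  names(out)[names(out) == "start"] <- "start_1based"
  names(out)[names(out) == "end"] <- "end_1based"
  out$start_1based <- out$start_1based + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write loci as BED6 (0-based half-open)
#'
#' @param loci Locus data.frame.
#' @param path Output file.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(loci$seq_id, loci$start, loci$end,
                    paste0(loci$ssr_type, ":", loci$canonical_motif),
                    0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
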