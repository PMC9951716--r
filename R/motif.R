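#' Reverse complement of a DNA motif
#'
#' @param motif Character vector of strings over \code{A,C,G,T}.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAG")   # "CTT"
#' @export
revcomp <- function(motif) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(motif)))
}

#' Test whether a motif is primitive
#'
#' A motif is primitive when it is not itself a tandem repetition of a
#' shorter unit ("ACAC" is not primitive, "ACA" is).
#'
#' @param motif Character vector.
#' @return Logical vector.
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 0L) return(FALSE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L &&
          m == strrep(substr(m, 1L, d), k %/% d)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i) {
    paste0(substr(m, i, k), substr(m, 1L, i - 1L))
  }, character(1))
}

#' Canonical representative of a repeat motif class
#'
#' Repeat motifs that are circular permutations of one another, or circular
#' permutations of each other's reverse complement, describe the same
#' microsatellite and are grouped into one class. The class representative
#' is the lexicographically smallest string among all rotations of the motif
#' and all rotations of its reverse complement, so e.g. "GA", "AG", "TC" and
#' "CT" all map to "AG".
#'
#' @param motif Character vector of primitive motifs over \code{A,C,G,T},
#'   length 1-6.
#' @return Character vector of canonical motifs, same length as the input.
#'   Idempotent: \code{canonical_motif(canonical_motif(x)) == canonical_motif(x)}.
#' @examples
#' canonical_motif(c("T", "GA", "GGC"))  # "A" "AG" "CCG"
#' @export
canonical_motif <- function(motif) {
  stopifnot(is.character(motif))
  bad <- !grepl("^[ACGT]{1,6}$", motif)
  if (any(bad)) {
    stop("motif must be a string over {A,C,G,T} of length 1-6: ",
         paste(motif[bad], collapse = ", "))
  }
  if (!all(is_primitive_motif(motif))) {
    stop("motif is not primitive: ",
         paste(motif[!is_primitive_motif(motif)], collapse = ", "))
  }
  rc <- revcomp(motif)
  vapply(seq_along(motif), function(i) {
    min(c(rotations(motif[i]), rotations(rc[i])))
  }, character(1))
}

#' Enumerate all primitive motifs of a given length
#'
#' @param k Motif length, 1-6.
#' @return Character vector of all primitive k-mers over \code{A,C,G,T}.
#' @export
primitive_motifs <- function(k) {
  stopifnot(length(k) == 1L, k >= 1L, k <= 6L)
  grids <- rep(list(c("A", "C", "G", "T")), k)
  all_kmers <- do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE))
  all_kmers[is_primitive_motif(all_kmers)]
}

#' Number of canonical motif classes for a motif length
#'
#' Counts the distinct equivalence classes of primitive k-mers under
#' rotation and reverse complementation, by exhaustive enumeration. These
#' are the possible canonical motifs of mono- to hexanucleotide SSRs:
#' 2, 4, 10, 33, 102 and 350 classes for k = 1..6.
#'
#' @param k Motif length, 1-6.
#' @return Integer count of canonical classes.
#' @export
motif_class_count <- function(k) {
  if (length(k) != 1L || !is.numeric(k) || k < 1 || k > 6) {
    stop("k must be a single integer between 1 and 6")
  }
  length(unique(canonical_motif(primitive_motifs(as.integer(k)))))
}
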