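# Assignment of SSR loci to genomic compartments and gene-end positional
# ranks, from GFF3 annotation.

#' Build an annotation index from a GFF3 file
#'
#' Reads gene / mRNA / exon / CDS features and derives, per gene, the
#' ordered exon and intron structure of its longest transcript (largest
#' summed exon length; introns are the gaps between consecutive exons and
#' are never read from the file). Exon and intron ranks are counted from
#' both gene ends honoring strand, so rank 1 from the 5' end of a
#' minus-strand gene is the genomically last exon; for every feature
#' \code{rank5 + rank3 == n + 1}.
#'
#' @param gff3 Path to a GFF3 file, or a \code{GRanges} as returned by
#'   \code{rtracklayer::import}.
#' @return An object of class \code{"annotation_index"}: a list of
#'   \code{GRanges} for genes, exons (with \code{gene_id}, \code{rank5},
#'   \code{rank3}), introns (ditto) and CDS.
#' @export
build_annotation_index <- function(gff3) {
  gr <- if (methods::is(gff3, "GRanges")) gff3 else {
    rtracklayer::import(gff3, format = "gff3")
  }
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("GFF3 contains no gene features")
  gene_ids <- as.character(genes$ID)
  tx <- gr[type %in% c("mRNA", "transcript")]
  exons <- gr[type == "exon"]
  cds <- gr[type == "CDS"]

  first_parent <- function(x) {
    p <- x$Parent
    vapply(as.list(p), function(v) if (length(v)) as.character(v[1]) else
      NA_character_, character(1))
  }
  n_skipped <- 0L

  # map each exon/CDS to its gene, through the transcript layer when present
  tx_parent <- setNames(first_parent(tx), as.character(tx$ID))
  to_gene <- function(parent) {
    out <- ifelse(parent %in% gene_ids, parent, tx_parent[parent])
    unname(out)
  }
  ex_par <- first_parent(exons)
  ex_gene <- to_gene(ex_par)
  drop <- is.na(ex_gene)
  if (any(drop)) {
    n_skipped <- n_skipped + sum(drop)
    warning(sum(drop), " exon(s) without a resolvable Parent skipped")
    exons <- exons[!drop]; ex_par <- ex_par[!drop]; ex_gene <- ex_gene[!drop]
  }
  cds_par <- first_parent(cds)
  cds_gene <- to_gene(cds_par)
  dropc <- is.na(cds_gene)
  if (any(dropc)) {
    n_skipped <- n_skipped + sum(dropc)
    cds <- cds[!dropc]; cds_par <- cds_par[!dropc]; cds_gene <- cds_gene[!dropc]
  }

  # longest transcript (summed exon width) per gene; genes whose exons point
  # straight at the gene act as single-transcript genes
  ex_tx <- ifelse(ex_par %in% gene_ids, paste0(ex_gene, ":self"), ex_par)
  txlen <- tapply(BiocGenerics::width(exons), ex_tx, sum)
  gene_of_tx <- setNames(ex_gene, ex_tx)[names(txlen)]
  keep_tx <- vapply(split(names(txlen), gene_of_tx), function(ids) {
    ids[which.max(txlen[ids])]
  }, character(1))

  exon_list <- list(); intron_list <- list(); cds_list <- list()
  gene_rows <- list()
  for (gid in names(keep_tx)) {
    tid <- keep_tx[[gid]]
    gidx <- match(gid, gene_ids)
    g <- genes[gidx]
    ex <- exons[ex_tx == tid]
    ex <- ex[order(BiocGenerics::start(ex))]
    # clamp exons that leak outside the gene span
    gs <- BiocGenerics::start(g); ge <- BiocGenerics::end(g)
    if (any(BiocGenerics::start(ex) < gs | BiocGenerics::end(ex) > ge)) {
      warning("exon outside gene span clamped for gene ", gid)
      ex <- IRanges::restrict(ex, start = gs, end = ge)
    }
    n_ex <- length(ex)
    minus <- as.character(BiocGenerics::strand(g)) == "-"
    r5 <- if (minus) rev(seq_len(n_ex)) else seq_len(n_ex)
    ex$gene_id <- gid
    ex$rank5 <- r5
    ex$rank3 <- n_ex + 1L - r5
    exon_list[[gid]] <- ex
    if (n_ex > 1L) {
      intr <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(g)[rep(1L, n_ex - 1L)],
        IRanges::IRanges(start = BiocGenerics::end(ex)[-n_ex] + 1L,
                         end = BiocGenerics::start(ex)[-1L] - 1L),
        strand = BiocGenerics::strand(g))
      ri5 <- if (minus) rev(seq_len(n_ex - 1L)) else seq_len(n_ex - 1L)
      intr$gene_id <- gid
      intr$rank5 <- ri5
      intr$rank3 <- n_ex - ri5
      intron_list[[gid]] <- intr
    }
    cc <- cds[ifelse(cds_par %in% gene_ids,
                     cds_gene == gid, cds_par == tid)]
    if (length(cc) > 0L) {
      cc$gene_id <- gid
      cds_list[[gid]] <- cc
    }
  }
  clean <- function(lst) {
    if (length(lst) == 0L) return(GenomicRanges::GRanges())
    lst <- lapply(lst, function(g) {
      S4Vectors::mcols(g) <- S4Vectors::mcols(g)[
        intersect(c("gene_id", "rank5", "rank3"), names(S4Vectors::mcols(g)))]
      g
    })
    do.call(c, unname(lst))
  }
  structure(list(genes = genes,
                 exons = clean(exon_list),
                 introns = clean(intron_list),
                 cds = clean(cds_list),
                 n_skipped = n_skipped),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:", length(x$genes), "genes,",
      length(x$exons), "exons,", length(x$introns), "introns,",
      length(x$cds), "CDS segments\n")
  invisible(x)
}

locus_midpoints <- function(loci) {
  # loci are 0-based half-open; the midpoint base, as a 1-based point
  mid0 <- (loci$start + loci$end) %/% 2L
  GenomicRanges::GRanges(loci$seq_id,
                         IRanges::IRanges(start = mid0 + 1L, width = 1L))
}

#' Assign SSR loci to genomic compartments
#'
#' Each locus is labeled by the compartment of its midpoint base, with
#' precedence CDS > exon_noncoding > intron > intergenic; a locus on a
#' sequence absent from the annotation is intergenic. The midpoint rule
#' gives every locus exactly one deterministic label even when it
#' straddles a feature boundary.
#'
#' @param loci Locus data.frame (0-based half-open coordinates).
#' @param index An \code{\link{build_annotation_index}} result.
#' @return The locus data.frame with a \code{region} factor column, levels
#'   \code{CDS}, \code{exon_noncoding}, \code{intron}, \code{intergenic}.
#' @export
assign_region <- function(loci, index) {
  stopifnot(inherits(index, "annotation_index"))
  labels <- rep("intergenic", nrow(loci))
  if (nrow(loci) > 0L) {
    pts <- locus_midpoints(loci)
    hit <- function(subject) {
      if (length(subject) == 0L) return(logical(length(pts)))
      IRanges::overlapsAny(pts, subject)
    }
    in_intron <- hit(index$introns)
    in_exon <- hit(index$exons)
    in_cds <- hit(index$cds)
    labels[in_intron] <- "intron"
    labels[in_exon] <- "exon_noncoding"
    labels[in_cds] <- "CDS"
  }
  loci$region <- factor(labels, levels = c("CDS", "exon_noncoding",
                                           "intron", "intergenic"))
  loci
}

#' Gene-end positional profile of SSR loci
#'
#' Counts loci per exon/intron rank from each gene end: a locus whose
#' midpoint falls in the exon of rank r from the 5' end of its gene
#' increments the 5' exon profile at r and the 3' profile at
#' \code{n_exons + 1 - r} (ranks above \code{top_n} are dropped). This is
#' the profile used to ask whether repeats concentrate near gene termini.
#'
#' @param loci Locus data.frame.
#' @param index An \code{\link{build_annotation_index}} result.
#' @param top_n Number of ranks kept from each end (default 30).
#' @return A data.frame with columns \code{rank}, \code{exon_5p},
#'   \code{exon_3p}, \code{intron_5p}, \code{intron_3p}.
#' @export
positional_profile <- function(loci, index, top_n = 30L) {
  stopifnot(inherits(index, "annotation_index"))
  top_n <- as.integer(top_n)
  out <- data.frame(rank = seq_len(top_n),
                    exon_5p = 0L, exon_3p = 0L,
                    intron_5p = 0L, intron_3p = 0L)
  if (nrow(loci) == 0L) return(out)
  pts <- locus_midpoints(loci)
  tally <- function(subject, col5, col3) {
    if (length(subject) == 0L) return()
    ov <- GenomicRanges::findOverlaps(pts, subject, select = "first")
    ov <- ov[!is.na(ov)]
    if (length(ov) == 0L) return()
    for (r in subject$rank5[ov][subject$rank5[ov] <= top_n]) {
      out[r, col5] <<- out[r, col5] + 1L
    }
    for (r in subject$rank3[ov][subject$rank3[ov] <= top_n]) {
      out[r, col3] <<- out[r, col3] + 1L
    }
  }
  tally(index$exons, "exon_5p", "exon_3p")
  tally(index$introns, "intron_5p", "intron_3p")
  out
}
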