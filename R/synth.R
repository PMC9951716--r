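# Synthetic genome simulator: non-repetitive background of configurable GC
# content, planted perfect / imperfect / compound SSRs, gene models, and a
# truth table, so every downstream stage can be validated against known
# ground truth.

BASES <- c("A", "C", "G", "T")

#' Specification of one planted SSR locus
#'
#' @param seq_id Target sequence name.
#' @param position 0-based start of the planted locus.
#' @param type \code{"perfect"}, \code{"imperfect"} or \code{"compound"}.
#' @param motif Primitive repeat unit (1-6 bp over A/C/G/T).
#' @param repeats Copy number of \code{motif}. Perfect plants must meet the
#'   class threshold of \code{\link{detector_params}}.
#' @param edits For imperfect plants, a data.frame with columns
#'   \code{offset} (0-based, into the unedited perfect array), \code{op}
#'   (\code{"sub"}, \code{"ins"} or \code{"del"}) and \code{base}.
#' @param gap For compound plants, bases of background between the two
#'   member arrays (must not exceed \code{compound_max_gap}).
#' @param motif2,repeats2 Second member of a compound plant.
#' @return A list of class \code{"plant_spec"}.
#' @export
plant_spec <- function(seq_id, position,
                       type = c("perfect", "imperfect", "compound"),
                       motif, repeats, edits = NULL, gap = 5L,
                       motif2 = NULL, repeats2 = NULL) {
  type <- match.arg(type)
  if (!grepl("^[ACGT]{1,6}$", motif) || !is_primitive_motif(motif)) {
    stop("motif must be a primitive 1-6 bp string over ACGT: ", motif)
  }
  if (type == "perfect") {
    thr <- detector_params()$min_repeats[nchar(motif)]
    if (repeats < thr) {
      stop("perfect plant ", motif, " x ", repeats,
           " is below the class threshold (", thr, ")")
    }
  }
  if (type == "imperfect") {
    if (is.null(edits) || nrow(edits) == 0L) {
      stop("imperfect plant needs at least one edit")
    }
    stopifnot(all(edits$op %in% c("sub", "ins", "del")),
              all(edits$offset >= 0),
              all(edits$offset < nchar(motif) * repeats))
  }
  if (type == "compound") {
    if (is.null(motif2) || is.null(repeats2)) {
      stop("compound plant needs motif2 and repeats2")
    }
    if (gap < 1L) stop("compound gap must be at least 1 base")
    if (!grepl("^[ACGT]{1,6}$", motif2) || !is_primitive_motif(motif2)) {
      stop("motif2 must be a primitive 1-6 bp string over ACGT: ", motif2)
    }
    for (mm in list(c(motif, repeats), c(motif2, repeats2))) {
      thr <- detector_params()$min_repeats[nchar(mm[1])]
      if (as.integer(mm[2]) < thr) {
        stop("compound member ", mm[1], " x ", mm[2],
             " is below the class threshold (", thr, ")")
      }
    }
  }
  structure(list(seq_id = seq_id, position = as.integer(position),
                 type = type, motif = motif, repeats = as.integer(repeats),
                 edits = edits, gap = as.integer(gap), motif2 = motif2,
                 repeats2 = if (is.null(repeats2)) NULL else
                   as.integer(repeats2)),
            class = "plant_spec")
}

#' Specification of one gene model
#'
#' Coordinates are 0-based half-open, like the locus tables; GFF3 output
#' converts to the 1-based inclusive convention of the format.
#'
#' @param seq_id Sequence name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons Two-column matrix of exon \code{start}, \code{end} pairs,
#'   ordered and non-overlapping.
#' @param cds Optional two-column matrix of CDS intervals, each contained
#'   in the exon union.
#' @param gene_id Identifier; autogenerated names are assigned at genome
#'   generation when missing.
#' @return A list of class \code{"gene_spec"}.
#' @export
gene_spec <- function(seq_id, strand, exons, cds = NULL, gene_id = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2)
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L,
            all(exons[, 2] > exons[, 1]))
  if (nrow(exons) > 1L) {
    if (any(diff(exons[, 1]) <= 0) ||
        any(exons[-1L, 1] < exons[-nrow(exons), 2])) {
      stop("exons must be ordered and non-overlapping")
    }
  }
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2)
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    }, logical(1))
    if (!all(inside)) stop("every CDS interval must lie within one exon")
  }
  structure(list(seq_id = seq_id, strand = strand, exons = exons,
                 cds = cds, gene_id = gene_id),
            class = "gene_spec")
}

#' Specification of a synthetic genome
#'
#' @param n_sequences Number of sequences.
#' @param seq_length Length of each sequence in bases.
#' @param background_gc Background GC fraction in [0, 1].
#' @param planted_ssrs List of \code{\link{plant_spec}} objects.
#' @param gene_models List of \code{\link{gene_spec}} objects.
#' @param rng_seed Integer seed; generation is fully deterministic given
#'   the spec.
#' @param seq_ids Sequence names (default \code{chr1..chrN}).
#' @param min_spacing Minimum background between planted loci (default 20,
#'   so compound merging never happens unless requested).
#' @return A list of class \code{"genome_spec"}.
#' @export
genome_spec <- function(n_sequences = 1L, seq_length = 10000L,
                        background_gc = 0.42, planted_ssrs = list(),
                        gene_models = list(), rng_seed = 1L,
                        seq_ids = paste0("chr", seq_len(n_sequences)),
                        min_spacing = 20L) {
  stopifnot(n_sequences >= 1L, seq_length >= 100L,
            background_gc >= 0, background_gc <= 1,
            length(seq_ids) == n_sequences)
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length),
                 background_gc = background_gc,
                 planted_ssrs = planted_ssrs,
                 gene_models = gene_models,
                 rng_seed = as.integer(rng_seed),
                 seq_ids = seq_ids,
                 min_spacing = as.integer(min_spacing)),
            class = "genome_spec")
}

draw_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# thresholds used for background purity: any run that could seed a perfect
# or an imperfect call is rejected and redrawn
purity_thresholds <- function(params) {
  pmin(params$min_repeats,
       pmax(params$seed_min_repeats,
            ceiling(params$seed_min_length / 1:6)))
}

# redraw background spans containing threshold-passing runs, leaving the
# positions in `frozen` untouched; returns the cleaned character vector
scrub_background <- function(x, gc, thr, frozen = logical(length(x)),
                             max_iter = 200L) {
  for (it in seq_len(max_iter)) {
    hits <- scan_perfect_cpp(paste(x, collapse = ""), as.integer(thr), 6L)
    if (nrow(hits) == 0L) return(x)
    dirty <- FALSE
    for (r in seq_len(nrow(hits))) {
      idx <- (hits$start[r] + 1L):(hits$start[r] +
                                     hits$repeats[r] * hits$period[r])
      idx <- idx[!frozen[idx]]
      if (length(idx) > 0L) {
        x[idx] <- draw_bases(length(idx), gc)
        dirty <- TRUE
      }
    }
    if (!dirty) return(x)   # every remaining run overlaps a planted locus
  }
  stop("background rejection sampling did not converge")
}

apply_edits <- function(seq_chars, edits) {
  # offsets refer to the unedited array; apply from the right so earlier
  # offsets stay valid
  edits <- edits[order(-edits$offset), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    o <- edits$offset[i] + 1L   # 1-based
    op <- edits$op[i]
    if (op == "sub") {
      seq_chars[o] <- edits$base[i]
    } else if (op == "ins") {
      seq_chars <- append(seq_chars, edits$base[i], after = o - 1L)
    } else {
      seq_chars <- seq_chars[-o]
    }
  }
  seq_chars
}

# materialize one plant: returns list(chars, motif_label, canonical_label,
# left_period, right_period)
build_plant <- function(plant, gc, params) {
  p <- nchar(plant$motif)
  if (plant$type == "perfect") {
    chars <- strsplit(strrep(plant$motif, plant$repeats), "")[[1]]
    list(chars = chars, motif = plant$motif,
         canonical = canonical_motif(plant$motif),
         p_left = p, p_right = p)
  } else if (plant$type == "imperfect") {
    chars <- apply_edits(strsplit(strrep(plant$motif, plant$repeats),
                                  "")[[1]],
                         plant$edits)
    hits <- scan_perfect_cpp(paste(chars, collapse = ""),
                             params$min_repeats, 6L)
    if (nrow(hits) > 0L) {
      stop("imperfect plant ", plant$motif, " x ", plant$repeats,
           " contains a perfect run meeting the class thresholds; ",
           "shorten the uninterrupted stretches")
    }
    list(chars = chars, motif = plant$motif,
         canonical = canonical_motif(plant$motif),
         p_left = p, p_right = p)
  } else {
    if (plant$gap > params$compound_max_gap) {
      stop("compound plant gap (", plant$gap,
           ") exceeds compound_max_gap (", params$compound_max_gap, ")")
    }
    p2 <- nchar(plant$motif2)
    a <- strsplit(strrep(plant$motif, plant$repeats), "")[[1]]
    b <- strsplit(strrep(plant$motif2, plant$repeats2), "")[[1]]
    g <- draw_bases(plant$gap, gc)
    # the gap must not extend either member array
    first_expect <- substr(plant$motif, 1, 1)
    if (g[1] == first_expect) {
      g[1] <- sample(setdiff(BASES, first_expect), 1)
    }
    last_expect <- substr(plant$motif2, p2, p2)
    if (g[length(g)] == last_expect) {
      g[length(g)] <- sample(setdiff(BASES, last_expect), 1)
    }
    list(chars = c(a, g, b),
         motif = paste(plant$motif, plant$motif2, sep = "-"),
         canonical = paste(canonical_motif(plant$motif),
                           canonical_motif(plant$motif2), sep = "-"),
         p_left = p, p_right = p2)
  }
}

region_of_point <- function(point0, genes) {
  # midpoint-rule compartment of a 0-based point, from the gene models
  label <- "intergenic"
  for (g in genes) {
    span <- range(g$exons)
    if (point0 < span[1] || point0 >= span[2]) next
    if (!is.null(g$cds) &&
        any(point0 >= g$cds[, 1] & point0 < g$cds[, 2])) return("CDS")
    if (any(point0 >= g$exons[, 1] & point0 < g$exons[, 2])) {
      return("exon_noncoding")
    }
    label <- "intron"
  }
  label
}

#' Generate a synthetic genome with planted SSRs and gene models
#'
#' Background sequence is drawn i.i.d. at the target GC content and
#' rejection-sampled so that no unplanted run passes either the perfect
#' thresholds or the imperfect seed thresholds: the truth table is
#' exhaustive. Planted loci appear verbatim at their stated coordinates;
#' the flanking bases are constrained so a planted array can never extend
#' into the background. Generation is deterministic given the spec.
#'
#' @param spec A \code{\link{genome_spec}}.
#' @param out_dir Optional directory; when given, writes
#'   \code{genome.fa} (60-column FASTA), \code{genes.gff3} and
#'   \code{truth.tsv} (BED-like, 0-based half-open).
#' @param params \code{\link{detector_params}} defining the thresholds the
#'   background must stay below.
#' @return List with \code{sequences} (named character vector),
#'   \code{truth} (data.frame: seq_id, start, end, ssr_type, motif,
#'   canonical_motif, repeats, region_label), \code{gene_models}, and file
#'   paths when \code{out_dir} was given.
#' @export
generate_genome <- function(spec, out_dir = NULL,
                            params = detector_params()) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$rng_seed)
  thr <- purity_thresholds(params)

  plants <- spec$planted_ssrs
  plant_seq <- vapply(plants, function(p) p$seq_id, character(1))
  genes <- spec$gene_models
  gene_seq <- vapply(genes, function(g) g$seq_id, character(1))
  if (!all(plant_seq %in% spec$seq_ids)) {
    stop("plant seq_id not in genome: ",
         paste(setdiff(plant_seq, spec$seq_ids), collapse = ", "))
  }

  sequences <- character(0)
  truth_rows <- list()
  for (sid in spec$seq_ids) {
    x <- draw_bases(spec$seq_length, spec$background_gc)
    frozen <- logical(spec$seq_length)
    sp <- plants[plant_seq == sid]
    built <- lapply(sp, build_plant, gc = spec$background_gc,
                    params = params)
    if (length(sp) > 0L) {
      starts <- vapply(sp, function(p) p$position, integer(1))
      lens <- vapply(built, function(b) length(b$chars), integer(1))
      o <- order(starts)
      sp <- sp[o]; built <- built[o]
      starts <- starts[o]; lens <- lens[o]
      ends <- starts + lens
      if (any(starts < 0L) || any(ends > spec$seq_length)) {
        stop("planted locus outside sequence bounds on ", sid)
      }
      if (length(sp) > 1L) {
        gap <- starts[-1L] - ends[-length(sp)]
        if (any(gap < 0L)) {
          i <- which(gap < 0L)[1]
          stop("planted loci overlap on ", sid, ": ",
               sp[[i]]$motif, "@", starts[i], " and ",
               sp[[i + 1L]]$motif, "@", starts[i + 1L])
        }
        if (any(gap < spec$min_spacing)) {
          warning("planted loci closer than min_spacing (", spec$min_spacing,
                  " bp) on ", sid, "; compound merging may occur")
        }
      }
      for (i in seq_along(sp)) {
        idx <- (starts[i] + 1L):ends[i]
        x[idx] <- built[[i]]$chars
        frozen[idx] <- TRUE
      }
    }
    # clean the background, then pin the flanks, iterating because a
    # redrawn flank is itself background
    for (pass in 1:50) {
      x <- scrub_background(x, spec$background_gc, thr, frozen)
      changed <- FALSE
      if (length(sp) > 0L) {
        for (i in seq_along(sp)) {
          pl <- built[[i]]$p_left; pr <- built[[i]]$p_right
          li <- starts[i]               # 1-based index of base before plant
          if (li >= 1L && x[li] == x[li + pl]) {
            x[li] <- sample(setdiff(BASES, x[li + pl]), 1)
            changed <- TRUE
          }
          ri <- ends[i] + 1L            # first base after plant
          if (ri <= spec$seq_length && x[ri] == x[ri - pr]) {
            x[ri] <- sample(setdiff(BASES, x[ri - pr]), 1)
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    sequences[[sid]] <- paste(x, collapse = "")
    if (length(sp) > 0L) {
      gsub_genes <- genes[gene_seq == sid]
      for (i in seq_along(sp)) {
        mid <- (starts[i] + ends[i]) %/% 2L
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          seq_id = sid, start = starts[i], end = ends[i],
          ssr_type = sp[[i]]$type,
          motif = built[[i]]$motif,
          canonical_motif = built[[i]]$canonical,
          repeats = if (sp[[i]]$type == "compound") NA_integer_ else
            sp[[i]]$repeats,
          region_label = region_of_point(mid, gsub_genes),
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               ssr_type = character(), motif = character(),
               canonical_motif = character(), repeats = integer(),
               region_label = character(), stringsAsFactors = FALSE)

  out <- list(sequences = sequences, truth = truth,
              gene_models = genes, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(out_dir, "genome.fa")
    dna <- Biostrings::DNAStringSet(sequences)
    Biostrings::writeXStringSet(dna, fasta, width = 60L)
    gff <- file.path(out_dir, "genes.gff3")
    write_gene_models_gff3(genes, gff)
    truth_path <- file.path(out_dir, "truth.tsv")
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$fasta <- fasta; out$gff <- gff; out$truth_path <- truth_path
  }
  out
}

#' Write gene models as GFF3
#'
#' Emits the standard gene -> mRNA -> exon/CDS hierarchy with ID/Parent
#' attributes, 1-based inclusive coordinates per the GFF3 specification.
#'
#' @param genes List of \code{\link{gene_spec}} objects.
#' @param path Output file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    gid <- if (is.null(g$gene_id)) paste0("gene", i) else g$gene_id
    tid <- paste0(gid, ".t1")
    span <- range(g$exons)
    add <- function(type, s0, e0, id = NA, parent = NA, phase = NA) {
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_id = g$seq_id, type = type, start = s0 + 1L, end = e0,
        strand = g$strand, id = id, parent = parent, phase = phase,
        stringsAsFactors = FALSE)
    }
    add("gene", span[1], span[2], id = gid)
    add("mRNA", span[1], span[2], id = tid, parent = gid)
    for (j in seq_len(nrow(g$exons))) {
      add("exon", g$exons[j, 1], g$exons[j, 2],
          id = paste0(tid, ".exon", j), parent = tid)
    }
    if (!is.null(g$cds)) {
      ord <- if (g$strand == "-") rev(seq_len(nrow(g$cds))) else
        seq_len(nrow(g$cds))
      done <- 0L
      for (j in ord) {
        add("CDS", g$cds[j, 1], g$cds[j, 2],
            id = paste0(tid, ".cds", j), parent = tid,
            phase = (3L - done %% 3L) %% 3L)
        done <- done + g$cds[j, 2] - g$cds[j, 1]
      }
    }
  }
  if (length(rows) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seq_id,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$id
  gr$Parent <- df$parent
  gr$phase <- as.integer(df$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate an ultrametric pure-birth tree
#'
#' Yule (pure-birth) tree with \code{n_taxa} tips, rescaled to unit depth,
#' standing in for a dated species phylogeny.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param rng_seed Integer seed.
#' @return An \code{ape::phylo} object with tip labels \code{t1..tN};
#'   export with \code{ape::write.tree} for a Newick string.
#' @export
generate_tree <- function(n_taxa, rng_seed = 1L) {
  if (n_taxa < 2L) stop("n_taxa must be at least 2")
  set.seed(rng_seed)
  phy <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth
  phy$tip.label <- paste0("t", seq_len(n_taxa))
  phy
}

#' Simulate correlated traits under Brownian motion on a tree
#'
#' Draws a species-by-trait matrix with matrix-normal structure: the
#' among-species covariance is the Brownian tree VCV and the among-trait
#' (evolutionary rate) covariance is \code{evo_cov}, with a root state of
#' zero.
#'
#' @param tree A tree accepted by \code{\link{tree_vcv}}.
#' @param n_traits Number of traits.
#' @param evo_cov Symmetric positive-definite trait covariance (default
#'   identity).
#' @param rng_seed Integer seed (NULL leaves the RNG state alone).
#' @return Numeric matrix, species x traits, rownames = tip labels.
#' @export
simulate_bm_traits <- function(tree, n_traits,
                               evo_cov = diag(n_traits), rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  C <- if (is.matrix(tree)) tree else tree_vcv(tree)
  evo_cov <- as.matrix(evo_cov)
  stopifnot(nrow(evo_cov) == n_traits, ncol(evo_cov) == n_traits)
  if (max(abs(evo_cov - t(evo_cov))) > 1e-8) {
    stop("evo_cov must be symmetric")
  }
  B <- tryCatch(chol(evo_cov),
                error = function(e) stop("evo_cov must be positive-definite"))
  A <- t(chol(C))
  Z <- matrix(rnorm(nrow(C) * n_traits), nrow(C), n_traits)
  X <- A %*% Z %*% B
  dimnames(X) <- list(rownames(C), paste0("trait", seq_len(n_traits)))
  X
}
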