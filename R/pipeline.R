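# Orchestration: per-species detection + statistics bundles, cross-species
# comparison with phylogenetic PCA, truth-table evaluation, and a
# YAML-configured end-to-end runner.

read_genome_input <- function(genome) {
  # accept a FASTA path, a DNAStringSet, a named character vector, or a
  # generate_genome() result
  if (is.list(genome) && !is.null(genome$sequences)) {
    return(list(sequences = genome$sequences,
                gene_models = genome$gene_models,
                source = "simulated"))
  }
  if (methods::is(genome, "DNAStringSet")) {
    return(list(sequences = setNames(as.character(genome), names(genome)),
                gene_models = NULL, source = "DNAStringSet"))
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    dna <- Biostrings::readDNAStringSet(genome)
    names(dna) <- sub("\\s.*$", "", names(dna))
    return(list(sequences = setNames(as.character(dna), names(dna)),
                gene_models = NULL, source = genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(list(sequences = genome, gene_models = NULL,
                source = "character"))
  }
  stop("genome must be a FASTA path, DNAStringSet, named character vector ",
       "or generate_genome() result")
}

#' Run the per-species SSR characterization pipeline
#'
#' Detects all SSR classes, assigns genomic compartments when annotation is
#' available, and computes the full set of summary statistics. With
#' \code{out_dir}, writes self-contained TSV outputs plus a JSON manifest
#' (input checksums, parameters, counts) so comparative stages can work
#' from the files alone. Outputs are deterministic functions of the
#' inputs.
#'
#' @param genome FASTA path, \code{DNAStringSet}, named character vector,
#'   or a \code{\link{generate_genome}} result (whose gene models are used
#'   when \code{gff} is NULL).
#' @param gff Optional GFF3 path; without annotation the region statistics
#'   and positional profile are skipped with a warning.
#' @param species Species identifier used in outputs.
#' @param params \code{\link{detector_params}}.
#' @param top_n_positional Ranks kept in the gene-end profile.
#' @param out_dir Optional output directory.
#' @return List: \code{loci}, \code{genome_length}, \code{proportions},
#'   \code{abundance}, \code{rcn_hist}, \code{cv}, \code{gc},
#'   \code{profile} (NULL without annotation), \code{species}.
#' @export
run_species <- function(genome, gff = NULL, species = "species",
                        params = detector_params(),
                        top_n_positional = 30L, out_dir = NULL) {
  gin <- read_genome_input(genome)
  sequences <- gin$sequences
  genome_length <- sum(nchar(sequences))
  loci <- detect_ssrs(sequences, params)

  index <- NULL
  if (!is.null(gff)) {
    index <- build_annotation_index(gff)
  } else if (!is.null(gin$gene_models) && length(gin$gene_models) > 0L) {
    tmp <- tempfile(fileext = ".gff3")
    write_gene_models_gff3(gin$gene_models, tmp)
    index <- build_annotation_index(tmp)
    unlink(tmp)
  }
  profile <- NULL
  if (!is.null(index)) {
    loci <- assign_region(loci, index)
    perf <- loci[loci$ssr_type == "perfect", , drop = FALSE]
    profile <- positional_profile(perf, index, top_n_positional)
  } else {
    warning("no annotation available; region statistics skipped")
  }

  res <- list(
    species = species,
    genome_length = genome_length,
    loci = loci,
    proportions = if (nrow(loci) > 0L) type_proportions(loci) else NULL,
    abundance = abundance_density(
      loci[loci$ssr_type == "perfect", , drop = FALSE],
      genome_length, by = "motif_len"),
    rcn_hist = rcn_histogram(loci),
    cv = cv_rcn(loci),
    gc = gc_content(loci[loci$ssr_type == "perfect", , drop = FALSE],
                    sequences),
    profile = profile)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_loci_tsv(loci, file.path(out_dir, "loci.tsv"))
    write_loci_bed(loci, file.path(out_dir, "loci.bed"))
    wt <- function(x, f) if (!is.null(x)) {
      write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    wt(data.frame(ssr_type = names(res$proportions),
                  percent = as.numeric(res$proportions)),
       "type_proportions.tsv")
    wt(res$abundance, "abundance_by_class.tsv")
    wt(res$rcn_hist, "rcn_histogram.tsv")
    wt(res$cv, "cv_rcn.tsv")
    wt(res$gc, "gc_content.tsv")
    wt(res$profile, "positional_profile.tsv")
    inputs <- if (is.character(genome) && length(genome) == 1L &&
                  file.exists(genome)) {
      list(fasta = unname(tools::md5sum(genome)),
           gff = if (!is.null(gff)) unname(tools::md5sum(gff)) else NULL)
    } else list(source = gin$source)
    manifest <- list(species = species,
                     genome_length = genome_length,
                     n_sequences = length(sequences),
                     n_loci = nrow(loci),
                     inputs = inputs,
                     params = unclass(params))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$out_dir <- out_dir
  }
  res
}

read_species_dir <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  loci <- read.table(file.path(dir, "loci.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  loci$start <- loci$start_1based - 1L
  loci$end <- loci$end_1based
  list(species = man$species, genome_length = man$genome_length,
       loci = loci)
}

#' Cross-species comparison of motif preferences with phylogenetic PCA
#'
#' Assembles species-by-canonical-motif abundance (loci/Mb) matrices per
#' motif-length class from per-species results and runs a
#' phylogenetically-informed PCA per class on them.
#'
#' @param species_results List of \code{\link{run_species}} results, or a
#'   character vector of per-species output directories.
#' @param tree Tree accepted by \code{\link{tree_vcv}}; tip labels must
#'   match the species identifiers.
#' @param classes Motif-length classes to analyze (default 2:6; a PCA of
#'   the two mononucleotide classes is rarely informative).
#' @param mode Passed to \code{\link{phylo_pca}}.
#' @param top_n Motif columns kept for classes >= 4 (default 25).
#' @param out_dir Optional directory for eigenvalue/loading/score TSVs.
#' @return List: \code{preference} (per-class matrices), \code{pca}
#'   (per-class \code{phylo_pca} objects), \code{tree}.
#' @export
run_comparative <- function(species_results, tree, classes = 2:6,
                            mode = "cov", top_n = 25L, out_dir = NULL) {
  if (is.character(species_results)) {
    species_results <- lapply(species_results, read_species_dir)
  }
  ids <- vapply(species_results, function(r) r$species, character(1))
  if (anyDuplicated(ids)) stop("duplicate species identifiers")
  if (length(ids) < 3L) stop("comparative analysis needs at least 3 species")
  phy <- as_phylo_or_matrix(tree)
  tips <- if (is.matrix(phy)) rownames(phy) else phy$tip.label
  if (!setequal(ids, tips)) {
    stop("species/tip mismatch; only in results: ",
         paste(setdiff(ids, tips), collapse = ", "),
         "; only in tree: ", paste(setdiff(tips, ids), collapse = ", "))
  }
  loci_by_species <- setNames(lapply(species_results, `[[`, "loci"), ids)
  lengths <- setNames(vapply(species_results, `[[`, numeric(1),
                             "genome_length"), ids)
  pref <- motif_preference(loci_by_species, lengths, top_n = top_n,
                           classes = classes)
  C <- if (is.matrix(phy)) phy else tree_vcv(phy)
  pca <- list()
  for (k in names(pref)) {
    X <- pref[[k]]$abundance
    if (ncol(X) < 2L) next
    pca[[k]] <- phylo_pca(X[ids, , drop = FALSE], C[ids, ids], mode = mode)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in names(pref)) {
      write.table(pref[[k]]$abundance,
                  file.path(out_dir, paste0("abundance_k", k, ".tsv")),
                  sep = "\t", quote = FALSE, col.names = NA)
      write.table(pref[[k]]$density,
                  file.path(out_dir, paste0("density_k", k, ".tsv")),
                  sep = "\t", quote = FALSE, col.names = NA)
    }
    for (k in names(pca)) {
      write.table(pca[[k]]$scores,
                  file.path(out_dir, paste0("pca_scores_k", k, ".tsv")),
                  sep = "\t", quote = FALSE, col.names = NA)
      write.table(pca[[k]]$loadings,
                  file.path(out_dir, paste0("pca_loadings_k", k, ".tsv")),
                  sep = "\t", quote = FALSE, col.names = NA)
      write.table(data.frame(component = names(pca[[k]]$eigenvalues),
                             eigenvalue = as.numeric(pca[[k]]$eigenvalues)),
                  file.path(out_dir, paste0("pca_eigenvalues_k", k, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(preference = pref, pca = pca, tree = phy)
}

as_phylo_or_matrix <- function(tree) {
  if (is.matrix(tree)) tree else as_phylo(tree)
}

#' Compare detected loci with a simulator truth table
#'
#' A truth row is recovered when a detected locus of the same type (and,
#' for perfect and imperfect loci, the same canonical motif) covers at
#' least \code{min_truth_cov} of its span -- perfect truth rows demand
#' exact coordinates. A detected locus is a true positive when it matches
#' a truth row the same way; a detected imperfect locus whose span is
#' mostly a planted perfect array counts as a redetection of that plant,
#' not a false positive. Perfect loci absorbed into compounds are not
#' double-counted.
#'
#' @param loci Detected loci (from \code{\link{detect_ssrs}}).
#' @param truth Truth table from \code{\link{generate_genome}}.
#' @param min_truth_cov Minimum fraction of a truth span a detected locus
#'   must cover (default 0.9).
#' @param min_hit_cov Minimum fraction of the detected span that must lie
#'   in the truth span (default 0.5).
#' @return List with \code{recall}, \code{precision}, \code{n_truth},
#'   \code{n_detected}, \code{missed} and \code{spurious} data.frames.
#' @export
evaluate_detection <- function(loci, truth, min_truth_cov = 0.9,
                               min_hit_cov = 0.5) {
  det <- count_once(loci)
  overlap_frac <- function(ts, te, ds, de) {
    ov <- pmax(0, pmin(te, de) - pmax(ts, ds))
    cbind(ov / (te - ts), ov / (de - ds))
  }
  match_truth_row <- function(tr) {
    cand <- det[det$seq_id == tr$seq_id, , drop = FALSE]
    if (tr$ssr_type == "perfect") {
      hit <- cand$ssr_type == "perfect" & cand$start == tr$start &
        cand$end == tr$end & cand$canonical_motif == tr$canonical_motif
      return(any(hit))
    }
    cand <- cand[cand$ssr_type == tr$ssr_type, , drop = FALSE]
    if (tr$ssr_type == "imperfect") {
      cand <- cand[cand$canonical_motif == tr$canonical_motif, ,
                   drop = FALSE]
    }
    if (nrow(cand) == 0L) return(FALSE)
    f <- overlap_frac(tr$start, tr$end, cand$start, cand$end)
    any(f[, 1] >= min_truth_cov & f[, 2] >= min_hit_cov)
  }
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    match_truth_row(truth[i, , drop = FALSE])
  }, logical(1))

  match_detected_row <- function(dr) {
    cand <- truth[truth$seq_id == dr$seq_id, , drop = FALSE]
    if (dr$ssr_type == "perfect") {
      return(any(cand$ssr_type == "perfect" & cand$start == dr$start &
                   cand$end == dr$end &
                   cand$canonical_motif == dr$canonical_motif))
    }
    types <- if (dr$ssr_type == "imperfect") c("imperfect", "perfect") else
      dr$ssr_type
    cand <- cand[cand$ssr_type %in% types, , drop = FALSE]
    if (nrow(cand) == 0L) return(FALSE)
    f <- overlap_frac(cand$start, cand$end, dr$start, dr$end)
    any(f[, 1] >= min_truth_cov & f[, 2] >= min_hit_cov)
  }
  tp <- vapply(seq_len(nrow(det)), function(i) {
    match_detected_row(det[i, , drop = FALSE])
  }, logical(1))

  list(recall = if (nrow(truth) == 0L) NA_real_ else mean(recovered),
       precision = if (nrow(det) == 0L) NA_real_ else mean(tp),
       n_truth = nrow(truth), n_detected = nrow(det),
       missed = truth[!recovered, , drop = FALSE],
       spurious = det[!tp, , drop = FALSE])
}

#' Genome specification emulating one surveyed species
#'
#' A 100 kb sequence with four multi-exon genes at fixed positions and a
#' randomized mix of 54 planted loci laid out on a regular grid crossing
#' exons, introns, CDS and intergenic space: six perfect plants per
#' motif-length class, two imperfect plants per class, and six compound
#' plants. Motif identity is drawn with species-specific log-normal
#' weights so that species differ in motif preference, which is what the
#' comparative stage measures.
#'
#' @param species Species identifier (also the seq prefix).
#' @param seed Integer seed for this species' genome.
#' @param seq_length Sequence length (default 100000).
#' @param background_gc Background GC fraction (default 0.42, a typical
#'   avian genome-wide value).
#' @param bias_sd Spread of the species-specific log-weights on motifs
#'   (default 1).
#' @return A \code{\link{genome_spec}}.
#' @export
study_genome_spec <- function(species, seed, seq_length = 100000L,
                              background_gc = 0.42, bias_sd = 1) {
  stopifnot(seq_length >= 95000L)
  set.seed(seed)
  thr <- detector_params()$min_repeats
  sid <- paste0(species, "_chr1")

  exon_rel <- cbind(c(0L, 1200L, 2400L, 3600L, 4800L),
                    c(600L, 1800L, 3000L, 4200L, 5400L))
  cds_rel <- cbind(c(1300L, 2400L, 3600L), c(1800L, 3000L, 4100L))
  gene_starts <- c(10000L, 35000L, 60000L, 85000L)
  strands <- c("+", "-", "+", "-")
  genes <- lapply(seq_along(gene_starts), function(i) {
    gene_spec(sid, strands[i], exon_rel + gene_starts[i],
              cds_rel + gene_starts[i],
              gene_id = paste0(species, "_g", i))
  })

  # species-specific motif weights per class
  weights <- lapply(1:6, function(k) {
    mot <- primitive_motifs(k)
    setNames(exp(rnorm(length(mot), 0, bias_sd)), mot)
  })
  pick_motif <- function(k) {
    w <- weights[[k]]
    sample(names(w), 1, prob = w)
  }

  plant_types <- c(rep(paste0("P", 1:6), each = 6),
                   rep(paste0("I", 1:6), each = 2),
                   rep("C", 6))
  plant_types <- sample(plant_types)       # spread classes over regions
  positions <- 1000L + 1750L * (seq_along(plant_types) - 1L)

  imp_r <- c(17L, 11L, 8L, 6L, 6L, 6L)     # total copies per class
  imp_left <- c(8L, 5L, 4L, 3L, 3L, 3L)    # copies before the substitution
  plants <- vector("list", length(plant_types))
  for (i in seq_along(plant_types)) {
    tt <- plant_types[i]
    if (tt == "C") {
      k1 <- sample(1:3, 1); k2 <- sample(2:4, 1)
      plants[[i]] <- plant_spec(
        sid, positions[i], "compound",
        motif = pick_motif(k1), repeats = thr[k1] + sample(0:3, 1),
        gap = sample(2:8, 1),
        motif2 = pick_motif(k2), repeats2 = thr[k2] + sample(0:3, 1))
    } else {
      k <- as.integer(substr(tt, 2, 2))
      m <- pick_motif(k)
      if (substr(tt, 1, 1) == "P") {
        plants[[i]] <- plant_spec(sid, positions[i], "perfect", m,
                                  repeats = thr[k] + rbinom(1, 8, 0.3))
      } else {
        off <- imp_left[k] * k
        orig <- substr(strrep(m, 2), off %% k + 1L, off %% k + 1L)
        plants[[i]] <- plant_spec(
          sid, positions[i], "imperfect", m, repeats = imp_r[k],
          edits = data.frame(offset = off, op = "sub",
                             base = sample(setdiff(BASES, orig), 1)))
      }
    }
  }
  genome_spec(n_sequences = 1L, seq_length = as.integer(seq_length),
              background_gc = background_gc, planted_ssrs = plants,
              gene_models = genes, rng_seed = seed + 1L,
              seq_ids = sid)
}

#' Simulate and analyze a multi-species study end to end
#'
#' Generates an ultrametric tree and one synthetic genome per tip,
#' runs the per-species pipeline on each, and the comparative
#' phylogenetic PCA across them.
#'
#' @param n_species Number of species (>= 3).
#' @param seed Master seed; per-species seeds are derived from it.
#' @param out_dir Optional output root (one subdirectory per species plus
#'   \code{comparative/}).
#' @param seq_length Genome length per species.
#' @param classes Motif-length classes for the comparative stage.
#' @return List: \code{tree}, \code{species} (per-species results),
#'   \code{genomes} (with truth tables), \code{comparative}.
#' @export
simulate_study <- function(n_species = 8L, seed = 1L, out_dir = NULL,
                           seq_length = 100000L, classes = 2:4) {
  tree <- generate_tree(n_species, rng_seed = seed)
  ids <- tree$tip.label
  genomes <- list(); species_res <- list()
  for (i in seq_along(ids)) {
    spec <- study_genome_spec(ids[i], seed = seed * 1000L + i,
                              seq_length = seq_length)
    g <- generate_genome(spec)
    genomes[[ids[i]]] <- g
    species_res[[ids[i]]] <- run_species(
      g, species = ids[i],
      out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, ids[i]))
  }
  comp <- run_comparative(species_res, tree, classes = classes,
                          out_dir = if (is.null(out_dir)) NULL else
                            file.path(out_dir, "comparative"))
  list(tree = tree, species = species_res, genomes = genomes,
       comparative = comp)
}

#' Run the pipeline from a YAML configuration
#'
#' The configuration lists species (each either \code{fasta}/\code{gff}
#' paths or a \code{simulate} block with a \code{seed}), an optional
#' \code{tree} (path, Newick string, or \code{simulate: n_taxa}), and
#' output options. See the package vignette for the schema.
#'
#' @param config Path to a YAML file, or an equivalent list.
#' @param out_dir Output root; overrides the config's \code{out_dir}.
#' @return As \code{\link{simulate_study}}: per-species results plus the
#'   comparative stage when a tree and >= 3 species are available.
#' @export
run_all <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$out_dir
  params <- do.call(detector_params,
                    cfg$detector %||% list())
  species_res <- list()
  genomes <- list()
  for (sp in cfg$species) {
    id <- sp$id %||% stop("each species entry needs an id")
    if (!is.null(sp$simulate)) {
      spec <- study_genome_spec(
        id, seed = sp$simulate$seed %||% 1L,
        seq_length = sp$simulate$seq_length %||% 100000L,
        background_gc = sp$simulate$background_gc %||% 0.42)
      g <- generate_genome(spec, params = params)
      genomes[[id]] <- g
      species_res[[id]] <- run_species(
        g, species = id, params = params,
        top_n_positional = cfg$top_n_positional %||% 30L,
        out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, id))
    } else {
      species_res[[id]] <- run_species(
        sp$fasta, gff = sp$gff, species = id, params = params,
        top_n_positional = cfg$top_n_positional %||% 30L,
        out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, id))
    }
  }
  comp <- NULL
  if (!is.null(cfg$tree) && length(species_res) >= 3L) {
    tree <- if (!is.null(cfg$tree$simulate)) {
      tr <- generate_tree(length(species_res),
                          rng_seed = cfg$tree$simulate$seed %||% 1L)
      tr$tip.label <- names(species_res)
      tr
    } else cfg$tree
    comp <- run_comparative(species_res, tree,
                            classes = cfg$classes %||% 2:6,
                            mode = cfg$mode %||% "cov",
                            top_n = cfg$top_n_motifs %||% 25L,
                            out_dir = if (is.null(out_dir)) NULL else
                              file.path(out_dir, "comparative"))
  }
  list(species = species_res, genomes = genomes, comparative = comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
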