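# Shared fixtures, built once per test run.

# motifs used for threshold-boundary cases; a flanking G never continues
# any of them in either direction
boundary_motifs <- c("A", "AC", "AAC", "AAAC", "AAAAC", "AAAAAC")

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# one simulated study genome with genes and a full plant mix
study_fixture <- function() {
  fixture("study", function() {
    spec <- study_genome_spec("spA", seed = 301L)
    g <- generate_genome(spec, out_dir = file.path(tempdir(), "study_spA"))
    g$loci <- detect_ssrs(g$sequences)
    g$index <- suppressWarnings(build_annotation_index(g$gff))
    g$loci <- assign_region(g$loci, g$index)
    g
  })
}

# a small three-species study for pipeline-level tests
mini_study_fixture <- function() {
  fixture("mini_study", function() {
    suppressWarnings(simulate_study(n_species = 3, seed = 77L,
                                    classes = 2:3))
  })
}

# a compact two-gene annotation built by hand
toy_genes <- function() {
  list(
    gene_spec("chr1", "+",
              exons = rbind(c(100L, 200L), c(300L, 400L), c(500L, 620L)),
              cds = rbind(c(320L, 400L), c(500L, 560L)),
              gene_id = "gplus"),
    gene_spec("chr1", "-",
              exons = rbind(c(1000L, 1100L), c(1300L, 1450L)),
              gene_id = "gminus"))
}

count_once_for_test <- function(loci) {
  loci[!(loci$ssr_type == "perfect" & loci$in_compound), , drop = FALSE]
}

toy_index <- function() {
  fixture("toy_index", function() {
    path <- tempfile(fileext = ".gff3")
    write_gene_models_gff3(toy_genes(), path)
    build_annotation_index(path)
  })
}
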