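# Phylogenetically-informed PCA of species-by-motif preference matrices:
# GLS ancestral mean, evolutionary covariance under Brownian motion, and
# eigendecomposition, implemented directly on the tree variance-covariance
# matrix.

#' Brownian-motion variance-covariance matrix of a tree
#'
#' C[i, j] is the branch length shared from the root by tips i and j (the
#' depth of their most recent common ancestor); the diagonal holds each
#' tip's root-to-tip depth. Under Brownian motion this matrix is the
#' among-species covariance structure.
#'
#' @param tree A Newick string, a path to a Newick file, or an
#'   \code{ape::phylo} object. Must be rooted with branch lengths and
#'   unique tip labels.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
tree_vcv <- function(tree) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("tree must have branch lengths on every edge")
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  }
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips")
  # node depths from the root by preorder accumulation over the edge list
  phy <- stats::reorder(phy, "cladewise")
  depth <- numeric(n + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + phy$edge.length[e]
  }
  mrca <- ape::mrca(phy)
  C <- matrix(depth[mrca], n, n,
              dimnames = list(phy$tip.label, phy$tip.label))
  diag(C) <- depth[seq_len(n)]
  C
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1L)
  if (grepl(";", tree, fixed = TRUE)) {
    ape::read.tree(text = tree)
  } else {
    ape::read.tree(tree)
  }
}

#' Phylogenetically-informed principal component analysis
#'
#' PCA of a species-by-trait matrix that accounts for species
#' non-independence under Brownian motion. The trait mean is the GLS
#' estimate at the root, \eqn{a = (1'C^{-1}1)^{-1} 1'C^{-1}X}; the
#' evolutionary covariance is \eqn{R = (X-1a)' C^{-1} (X-1a) / (n-1)}
#' (rescaled to a correlation matrix when \code{mode = "corr"}); principal
#' axes are the eigenvectors of R and species scores are the centered data
#' projected on them, \eqn{S = (X-1a)V}. With a star phylogeny (C = I) the
#' result reduces to ordinary PCA. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param X Numeric matrix, species in rows (rownames must match the tips
#'   of \code{C}), traits in columns.
#' @param C Tree variance-covariance matrix from \code{\link{tree_vcv}},
#'   or a tree accepted by it. A near-singular C is regularized by a small
#'   ridge (1e-8 * trace(C)/n) with a message.
#' @param mode \code{"cov"} (default) or \code{"corr"}.
#' @return An object of class \code{"phylo_pca"}: list with \code{anc_mean},
#'   \code{evo_cov}, \code{eigenvalues} (descending), \code{loadings}
#'   (orthonormal columns), \code{scores}, and \code{mode}.
#' @export
phylo_pca <- function(X, C, mode = c("cov", "corr")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  if (!is.matrix(C)) C <- tree_vcv(C)
  n <- nrow(X); m <- ncol(X)
  if (nrow(C) != n) stop("rows of X (", n, ") do not match tips of C (",
                         nrow(C), ")")
  if (!is.null(rownames(X)) && !is.null(rownames(C))) {
    if (!setequal(rownames(X), rownames(C))) {
      stop("species mismatch between X and C: ",
           paste(c(setdiff(rownames(X), rownames(C)),
                   setdiff(rownames(C), rownames(X))), collapse = ", "))
    }
    C <- C[rownames(X), rownames(X)]
  }
  if (n <= m) {
    warning("n species <= m traits: evolutionary covariance is rank deficient")
  }
  Ci <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Ci) || !all(is.finite(Ci))) {
    ridge <- 1e-8 * sum(diag(C)) / n
    message("C is numerically singular; adding ridge ", signif(ridge, 3))
    Ci <- solve(C + diag(ridge, n))
  }
  one <- matrix(1, n, 1)
  a <- drop(solve(t(one) %*% Ci %*% one) %*% t(one) %*% Ci %*% X)
  Xc <- X - one %*% t(a)
  R <- t(Xc) %*% Ci %*% Xc / (n - 1)
  R <- (R + t(R)) / 2
  if (mode == "corr") {
    # correlation-mode PCA works on traits standardized by their GLS
    # evolutionary standard deviations
    sds <- sqrt(diag(R))
    X <- sweep(X, 2, sds, "/")
    a <- a / sds
    Xc <- X - one %*% t(a)
    R <- stats::cov2cor(R)
  }
  eig <- eigen(R, symmetric = TRUE)
  V <- eig$vectors
  # reproducible signs: largest-magnitude loading of each axis is positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  S <- Xc %*% V
  dimnames(S) <- list(rownames(X), colnames(V))
  structure(list(anc_mean = setNames(a, colnames(X)),
                 evo_cov = R,
                 eigenvalues = setNames(eig$values, colnames(V)),
                 loadings = V,
                 scores = S,
                 mode = mode),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  ev <- x$eigenvalues
  cat("Phylogenetically-informed PCA (mode =", x$mode, ")\n")
  cat("Eigenvalues:", paste(signif(ev, 4), collapse = " "), "\n")
  cat("Proportion of variance (PC1, PC2):",
      paste(signif(100 * ev[seq_len(min(2, length(ev)))] / sum(ev), 4),
            collapse = " "), "%\n")
  invisible(x)
}
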