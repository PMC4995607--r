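#' Principal component analysis of genotype dosages
#'
#' Standard centred-genotype PCA: per-locus missing dosages are mean
#' imputed, columns are centred (and optionally standardized by the
#' binomial frequency scale `sqrt(p(1-p))`), and components come from
#' [stats::prcomp()]. Signs are fixed by convention: each component is
#' flipped so its largest-magnitude loading is positive, making the output
#' deterministic.
#'
#' @param g a QC'd, LD-pruned [genotype_matrix()].
#' @param n_components number of components to return.
#' @param standardize divide each centred column by `sqrt(p(1-p))`
#'   (default `FALSE`).
#' @return A list with `scores` (samples x components, rownames = sample
#'   ids), `loadings`, `explained_variance` (fraction per component), and
#'   `samples` (the sample metadata, for plotting).
#' @export
pca_genotypes <- function(g, n_components = 10, standardize = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (n_components > nrow(g$dosage))
    stop("more components requested than samples")
  x <- g$dosage
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, mu, "-")
  if (standardize) {
    p <- mu / 2
    sc <- sqrt(p * (1 - p))
    keep <- sc > 0
    x <- sweep(x[, keep, drop = FALSE], 2, sc[keep], "/")
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {   # deterministic sign: top |loading| positive
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(k)], samples = g$samples)
}

#' Pairwise population distance matrix from genome-wide F_ST
#'
#' Distance between two populations is the genome-wide ratio-of-sums
#' Weir-Cockerham theta ([multilocus_fst()]); slightly negative estimates
#' (possible for undifferentiated pairs) are clamped to 0 so the result is
#' a valid distance matrix.
#'
#' @param g a [genotype_matrix()].
#' @return A symmetric matrix with zero diagonal, dimnames = population
#'   labels.
#' @export
population_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(g$samples$population)
  if (length(pops) < 2) stop("need at least 2 populations")
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    th <- multilocus_fst(g, pops[i], pops[j])
    d[i, j] <- d[j, i] <- max(0, th)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The classic Saitou-Nei agglomeration: repeatedly join the pair
#' minimizing the Q criterion `Q(i,j) = (n-2) d(i,j) - R_i - R_j` (ties
#' broken toward the lowest index pair), with the standard branch-length
#' and distance-update formulas. NJ recovers the generating tree exactly
#' on additive matrices. Negative branch lengths are clamped to 0 with a
#' warning. Returns the unrooted tree in Newick text.
#'
#' @param d symmetric distance matrix with labelled dimnames, >= 3 taxa.
#' @return A list of class `"nj_tree"` with `newick` and `n_taxa`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  clamped <- FALSE
  branch <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)
  node <- as.list(labels)   # growing Newick fragments

  while (nrow(d) > 3) {
    n <- nrow(d)
    R <- rowSums(d)
    q <- (n - 2) * d - outer(R, R, "+")
    diag(q) <- Inf
    # lowest-index (i < j) pair among the minima
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- branch(d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2)))
    lj <- branch(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))))
    new_node <- paste0("(", node[[i]], ":", fmt(li), ",",
                       node[[j]], ":", fmt(lj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    d <- d2
    node <- c(node[keep], new_node)
  }
  # final three-way join: closed-form branch lengths
  la <- branch((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- branch((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- branch((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- paste0("(", node[[1]], ":", fmt(la), ",",
                   node[[2]], ":", fmt(lb), ",",
                   node[[3]], ":", fmt(lc), ");")
  if (clamped)
    warning("negative neighbor-joining branch length(s) clamped to 0")
  structure(list(newick = newick, n_taxa = length(labels)),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("nj_tree with", x$n_taxa, "taxa:\n", x$newick, "\n")
  invisible(x)
}
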