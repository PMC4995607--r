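# Weir & Cockerham (1984) two-population variance components, vectorized
# over loci. Inputs are per-locus vectors: sample sizes n1/n2 (non-missing
# diploids), a2-allele frequencies p1/p2, and observed heterozygote
# fractions h1/h2. With r = 2 populations:
#   nbar = (n1+n2)/2,  nc = (r*nbar - sum(ni^2)/(r*nbar)) / (r-1)
#   pbar = weighted mean frequency, s2 = weighted among-pop variance,
#   hbar = weighted mean observed heterozygosity
#   a = nbar/nc * (s2 - (pbar(1-pbar) - s2*(r-1)/r - hbar/4)/(nbar-1))
#   b = nbar/(nbar-1) * (pbar(1-pbar) - s2*(r-1)/r - (2*nbar-1)/(4*nbar)*hbar)
#   c = hbar/2,  theta = a/(a+b+c)
# Loci monomorphic in both populations (a+b+c == 0), or with fewer than one
# genotyped diploid in a population, get theta = NA (undefined sentinel).
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  bad <- n1 < 1 | n2 < 1 | nbar <= 1 | !is.finite(denom) | denom == 0
  theta <- ifelse(bad, NA_real_, a / denom)
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(a = a, b = b, c = cc, theta = theta)
}

#' Weir-Cockerham pairwise F_ST at one locus
#'
#' The unbiased two-population estimator built from the 1984 variance
#' components: `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals), with
#' `theta = a / (a + b + c)`. Negative estimates are retained, never
#' truncated at zero. A locus monomorphic in both populations is undefined
#' (all components `NA`), not an error.
#'
#' @param counts1,counts2 length-3 integer vectors of genotype counts
#'   (homozygote a1, heterozygote, homozygote a2) in the two populations.
#' @return A list with `a`, `b`, `c`, `theta`, `defined`.
#' @examples
#' wc_fst_locus(c(50, 0, 0), c(0, 0, 50))$theta  # fixed difference: 1
#' @export
wc_fst_locus <- function(counts1, counts2) {
  stopifnot(length(counts1) == 3, length(counts2) == 3,
            all(counts1 >= 0), all(counts2 >= 0))
  n1 <- sum(counts1); n2 <- sum(counts2)
  if (n1 == 0 || n2 == 0) stop("zero genotyped samples in a population")
  p1 <- (counts1[2] + 2 * counts1[3]) / (2 * n1)
  p2 <- (counts2[2] + 2 * counts2[3]) / (2 * n2)
  h1 <- counts1[2] / n1
  h2 <- counts2[2] / n2
  z <- wc_components(n1, p1, h1, n2, p2, h2)
  list(a = z$a, b = z$b, c = z$c, theta = z$theta,
       defined = !is.na(z$theta))
}

#' Per-locus pairwise F_ST of a focal population against references
#'
#' Applies the Weir-Cockerham estimator to every locus for every
#' (focal, reference) pair. Missing genotypes are dropped per locus per
#' population, so a locus can be defined against one reference and
#' undefined against another.
#'
#' @param g a [genotype_matrix()].
#' @param focal focal population label.
#' @param references character vector of reference population labels
#'   (must not contain `focal`).
#' @return An object of class `"pairwise_fst_table"`: list with `focal`,
#'   `references`, `theta` (loci x references matrix, `NA` = undefined),
#'   `a` and `abc` (component matrices for ratio-of-sums summaries), and
#'   `loci` (the locus metadata).
#' @export
pairwise_fst_table <- function(g, focal, references) {
  stopifnot(inherits(g, "genotype_matrix"), length(references) >= 1)
  if (focal %in% references)
    stop("focal population must not appear among the references")
  all_pops <- unique(g$samples$population)
  missing_pop <- setdiff(c(focal, references), all_pops)
  if (length(missing_pop))
    stop("population not found: ", paste(missing_pop, collapse = ", "))

  sf <- pop_locus_stats(g, focal)
  m <- ncol(g$dosage)
  theta <- a_mat <- abc <- matrix(
    NA_real_, m, length(references),
    dimnames = list(g$loci$id, references))
  for (k in seq_along(references)) {
    sr <- pop_locus_stats(g, references[k])
    if (all(sr$n < 2))
      stop("reference ", references[k],
           " has fewer than 2 genotyped diploids at every locus")
    z <- wc_components(sf$n, sf$p, sf$h, sr$n, sr$p, sr$h)
    theta[, k] <- z$theta
    a_mat[, k] <- z$a
    abc[, k] <- z$a + z$b + z$c
  }
  structure(list(focal = focal, references = references, theta = theta,
                 a = a_mat, abc = abc, loci = g$loci),
            class = "pairwise_fst_table")
}

#' Genome-wide mean and standard deviation of pairwise F_ST
#'
#' Per reference pair, the mean and sample standard deviation (n - 1
#' denominator) of the per-locus estimates over defined loci only. These
#' are the moments that standardize the d_i statistic.
#'
#' @param table a [pairwise_fst_table()].
#' @return data.frame with `reference`, `mean_fst`, `sd_fst`, `n_defined`.
#' @export
fst_moments <- function(table) {
  stopifnot(inherits(table, "pairwise_fst_table"))
  out <- data.frame(
    reference = table$references,
    mean_fst = unname(apply(table$theta, 2, mean, na.rm = TRUE)),
    sd_fst = unname(apply(table$theta, 2, stats::sd, na.rm = TRUE)),
    n_defined = {
      nd <- colSums(!is.na(table$theta))
      storage.mode(nd) <- "integer"
      nd
    },
    stringsAsFactors = FALSE, row.names = NULL)
  if (any(out$n_defined < 2))
    stop("reference pair with fewer than 2 defined loci: ",
         paste(out$reference[out$n_defined < 2], collapse = ", "))
  if (any(out$sd_fst == 0))
    warning("reference pair with zero F_ST standard deviation: ",
            paste(out$reference[out$sd_fst == 0], collapse = ", "))
  out
}

#' Genome-wide multi-locus F_ST between two populations
#'
#' The ratio-of-sums estimator `sum(a) / sum(a + b + c)` over defined loci —
#' not the mean of per-locus ratios, which would weight loci incorrectly.
#'
#' @param g a [genotype_matrix()].
#' @param pop1,pop2 population labels.
#' @return A single numeric theta estimate.
#' @export
multilocus_fst <- function(g, pop1, pop2) {
  stopifnot(inherits(g, "genotype_matrix"))
  s1 <- pop_locus_stats(g, pop1)
  s2 <- pop_locus_stats(g, pop2)
  z <- wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  ok <- !is.na(z$theta)
  if (!any(ok)) stop("no defined loci for this population pair")
  sum(z$a[ok]) / sum(z$a[ok] + z$b[ok] + z$c[ok])
}
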