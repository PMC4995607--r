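# Independent brute-force oracles. These deliberately re-derive each
# quantity with plain scalar arithmetic (general r-population formulas,
# O(N^2) loops, exhaustive enumeration) so they share no code path with the
# vectorized implementations they check.

# Weir & Cockerham (1984) theta for r populations, scalar transcription.
# counts_list: list of length-3 genotype-count vectors (dos 0/1/2).
oracle_wc_theta <- function(counts_list) {
  r <- length(counts_list)
  n <- sapply(counts_list, sum)
  p <- sapply(counts_list, function(cc) (cc[2] + 2 * cc[3]) / (2 * sum(cc)))
  h <- sapply(counts_list, function(cc) cc[2] / sum(cc))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# genotype counts (dos 0/1/2) of one population at one locus
geno_counts <- function(g, population, locus) {
  d <- g$dosage[g$samples$population == population,
                match(locus, g$loci$id)]
  d <- d[!is.na(d)]
  c(sum(d == 0), sum(d == 1), sum(d == 2))
}

# O(N^2) empirical tail proportion
oracle_empirical_p <- function(di) {
  vapply(di, function(x) mean(di >= x), 0)
}

# exhaustive two-sided Fisher p: sum hypergeometric probabilities of all
# tables with the observed margins that are as or less probable
oracle_fisher_p <- function(alt1, n1, alt2, n2) {
  m <- alt1 + alt2           # total alt chromosomes
  k <- seq(max(0, m - n2), min(n1, m))
  probs <- dhyper(k, n1, n2, m)
  p_obs <- dhyper(alt1, n1, n2, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all-pairs interval overlap scan (1-based site vs 0-based half-open track)
oracle_overlap <- function(sites, intervals) {
  vapply(seq_len(nrow(sites)), function(i) {
    any(intervals$chrom == sites$chrom[i] &
          intervals$start <= sites$pos[i] - 1 &
          sites$pos[i] - 1 < intervals$end)
  }, TRUE)
}

# small hand-buildable genotype matrix
toy_matrix <- function(dosage, populations, altitude = NULL,
                       chrom = "1", pos = NULL, a1 = "A", a2 = "G") {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(altitude)) altitude <- rep("low", n)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(
    dosage,
    samples = data.frame(id = paste0("s", seq_len(n)),
                         population = populations, altitude = altitude,
                         stringsAsFactors = FALSE),
    loci = data.frame(id = paste0("l", seq_len(m)),
                      chrom = rep(chrom, length.out = m), pos = pos,
                      a1 = a1, a2 = a2, stringsAsFactors = FALSE))
}

# random genotype matrix with the given population layout
random_matrix <- function(pops, n_per_pop, m, seed = 1, miss = 0) {
  set.seed(seed)
  n <- length(pops) * n_per_pop
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)[rep(seq_len(m),
                                                        each = n)]),
                n, m)
  if (miss > 0) dos[runif(n * m) < miss] <- NA
  toy_matrix(dos, populations = rep(pops, each = n_per_pop))
}
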