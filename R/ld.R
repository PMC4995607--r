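#' Squared genotype correlation between two loci
#'
#' The composite (genotype-based) r2: the squared Pearson correlation of the
#' dosage vectors after dropping samples missing at either locus. No phasing
#' is used or assumed.
#'
#' @param g a [genotype_matrix()].
#' @param locus_i,locus_j locus ids.
#' @param population optional population label; default uses all samples.
#' @return A list with `locus_i`, `locus_j`, `r2`, `distance_bp` (`NA` when
#'   the loci sit on different chromosomes), `n` complete pairs, and
#'   `defined` (`FALSE` when either locus is monomorphic in the chosen set).
#' @export
ld_r2 <- function(g, locus_i, locus_j, population = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ji <- match(locus_i, g$loci$id); jj <- match(locus_j, g$loci$id)
  if (is.na(ji) || is.na(jj)) stop("locus not found")
  rows <- if (is.null(population)) seq_len(nrow(g$dosage))
          else pop_rows(g, population)
  x <- g$dosage[rows, ji]; y <- g$dosage[rows, jj]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  same_chrom <- g$loci$chrom[ji] == g$loci$chrom[jj]
  dist_bp <- if (same_chrom) abs(g$loci$pos[ji] - g$loci$pos[jj]) else NA_integer_
  if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(locus_i = locus_i, locus_j = locus_j, r2 = NA_real_,
                distance_bp = dist_bp, n = length(x), defined = FALSE))
  }
  list(locus_i = locus_i, locus_j = locus_j,
       r2 = stats::cor(x, y)^2, distance_bp = dist_bp,
       n = length(x), defined = TRUE)
}

# r2 matrix among a block of locus columns (pairwise-complete), NA where
# monomorphic; used by the pruner and the decay curve
r2_block <- function(d) {
  suppressWarnings(r <- stats::cor(d, use = "pairwise.complete.obs"))
  r * r
}

#' Prune loci in linkage disequilibrium
#'
#' Sliding-window pruning in the style of PLINK `--indep-pairwise`: windows
#' of `window_snps` loci advanced by `step_snps` within each chromosome;
#' inside a window, while any retained pair has r2 above `r2_threshold`, one
#' member of the pair is removed. The removed member is the one with the
#' lower pooled MAF (tie: the later locus in map order). On completion no
#' retained pair within any window exceeds the threshold.
#'
#' @param g a [genotype_matrix()] (already QC'd).
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps step size in SNPs (default 5).
#' @param r2_threshold removal threshold on r2 (default 0.2).
#' @return Character vector of retained locus ids, in map order.
#' @export
ld_prune <- function(g, window_snps = 50, step_snps = 5, r2_threshold = 0.2) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (step_snps > window_snps) stop("step_snps must not exceed window_snps")
  maf <- locus_summary(g)$maf
  keep <- rep(TRUE, ncol(g$dosage))
  for (chrom in unique(g$loci$chrom)) {
    idx <- which(g$loci$chrom == chrom)
    start <- 1L
    repeat {
      win <- idx[seq(start, min(start + window_snps - 1L, length(idx)))]
      live <- win[keep[win]]
      if (length(live) >= 2) {
        r2 <- r2_block(g$dosage[, live, drop = FALSE])
        repeat {
          r2[lower.tri(r2, diag = TRUE)] <- NA
          off <- which(!is.na(r2) & r2 > r2_threshold, arr.ind = TRUE)
          if (!nrow(off)) break
          i <- live[off[1, 1]]; j <- live[off[1, 2]]
          # drop the lower-MAF member; tie -> later in map order (j > i)
          drop <- if (isTRUE(maf[i] < maf[j])) i else j
          keep[drop] <- FALSE
          k <- match(drop, live)
          live <- live[-k]
          if (length(live) < 2) break
          r2 <- r2[-k, -k, drop = FALSE]
        }
      }
      if (start + window_snps - 1L >= length(idx)) break
      start <- start + step_snps
    }
  }
  g$loci$id[keep]
}

#' Mean r2 as a function of inter-locus distance
#'
#' Assigns every same-chromosome locus pair to a distance bin and reports
#' the mean r2 and pair count per bin. Pairs where either locus is
#' monomorphic in the chosen sample set are skipped.
#'
#' @param g a [genotype_matrix()].
#' @param population optional population label (default: all samples).
#' @param breaks increasing numeric vector of bin edges in bp; a pair at
#'   distance d falls in bin k when `breaks[k] <= d < breaks[k+1]`.
#' @return data.frame with `bin_start`, `bin_end`, `n_pairs`, `mean_r2`
#'   (`NA` for empty bins).
#' @export
ld_decay_curve <- function(g, population = NULL,
                           breaks = c(0, 1e4, 5e4, 1e5, 5e5, 1e6, Inf)) {
  stopifnot(inherits(g, "genotype_matrix"), length(breaks) >= 2,
            !is.unsorted(breaks))
  rows <- if (is.null(population)) seq_len(nrow(g$dosage))
          else pop_rows(g, population)
  nb <- length(breaks) - 1L
  s <- numeric(nb); cnt <- integer(nb)
  for (chrom in unique(g$loci$chrom)) {
    idx <- which(g$loci$chrom == chrom)
    if (length(idx) < 2) next
    r2 <- r2_block(g$dosage[rows, idx, drop = FALSE])
    pos <- g$loci$pos[idx]
    dmat <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(r2)
    r2v <- r2[ut]; dv <- dmat[ut]
    ok <- !is.na(r2v)
    bin <- findInterval(dv[ok], breaks, rightmost.closed = FALSE)
    bin <- pmin(bin, nb)
    for (k in seq_len(nb)) {
      sel <- bin == k
      s[k] <- s[k] + sum(r2v[ok][sel])
      cnt[k] <- cnt[k] + sum(sel)
    }
  }
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             n_pairs = cnt,
             mean_r2 = ifelse(cnt > 0, s / cnt, NA_real_))
}
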