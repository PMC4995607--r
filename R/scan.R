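#' Selection-scan configuration
#'
#' @param significance_proportion empirical-p cutoff: loci with
#'   `P_E < significance_proportion` are called significant
#'   (default 0.005, the top 0.5% of the empirical distribution).
#' @param merge_gap_bp maximum gap between consecutive significant SNPs
#'   merged into one sweep region, inclusive (default 500,000 bp).
#' @param scan_min_maf minor-allele-frequency floor applied across the
#'   pooled focal + reference samples before scanning (default 0.05; loci
#'   with pooled MAF below it are excluded, MAF exactly at it retained).
#' @return A list of class `"scan_config"`.
#' @export
scan_config <- function(significance_proportion = 0.005,
                        merge_gap_bp = 500000,
                        scan_min_maf = 0.05) {
  if (significance_proportion <= 0 || significance_proportion >= 1)
    stop("significance_proportion must lie in (0, 1)")
  if (merge_gap_bp < 0) stop("merge_gap_bp must be >= 0")
  structure(list(significance_proportion = significance_proportion,
                 merge_gap_bp = merge_gap_bp,
                 scan_min_maf = scan_min_maf),
            class = "scan_config")
}

#' The d_i breed-differentiation statistic
#'
#' For a focal population i, at each locus:
#' `d_i = sum_j (F_ST(i,j) - E[F_ST(i,j)]) / sd[F_ST(i,j)]`,
#' summing over reference populations j, where the expectation and standard
#' deviation are the genome-wide moments of that pair. Large d_i marks loci
#' where the focal population is unusually differentiated from many
#' references at once. Pairs undefined at a locus contribute 0 (logged);
#' a pair with zero standard deviation contributes 0 everywhere, with a
#' warning.
#'
#' @param table a [pairwise_fst_table()].
#' @param moments the matching [fst_moments()] (computed on the same loci).
#' @return Numeric vector of per-locus d_i, named by locus id, with the
#'   per-pair standardized terms attached as attribute `"z"`.
#' @export
di_statistic <- function(table, moments) {
  stopifnot(inherits(table, "pairwise_fst_table"),
            identical(moments$reference, table$references))
  z <- sweep(table$theta, 2, moments$mean_fst, "-")
  z <- sweep(z, 2, moments$sd_fst, "/")
  degenerate <- moments$sd_fst == 0 | !is.finite(moments$sd_fst)
  if (any(degenerate)) {
    warning("pair(s) with zero F_ST standard deviation contribute 0 to d_i: ",
            paste(moments$reference[degenerate], collapse = ", "))
    z[, degenerate] <- 0
  }
  n_undef <- sum(is.na(z))
  if (n_undef > 0)
    message("di_statistic: ", n_undef,
            " undefined locus-pair terms contribute 0")
  z[is.na(z)] <- 0
  di <- rowSums(z)
  names(di) <- rownames(table$theta)
  attr(di, "z") <- z
  di
}

#' Empirical p-values of the d_i distribution
#'
#' `P_E(locus) = #\{k : d_k >= d_locus\} / N`: the proportion of loci whose
#' statistic is at least as large, so the genome itself is the null
#' distribution. Tied values share a P_E; the maximum gets `1/N`, and
#' `P_E` is always in `(0, 1]`. Non-finite values are excluded from `N`
#' (their P_E is `NA`) with a warning.
#'
#' @param di numeric vector of d_i values.
#' @return Numeric vector of empirical p-values, same length and names.
#' @export
empirical_p <- function(di) {
  if (!length(di)) stop("empty d_i vector")
  ok <- is.finite(di)
  if (!any(ok)) stop("no finite d_i values")
  if (!all(ok)) warning(sum(!ok), " non-finite d_i value(s) excluded")
  n <- sum(ok)
  pe <- rep(NA_real_, length(di))
  # count of values >= x equals n - (strictly smaller) = n - min-rank + 1
  pe[ok] <- (n - rank(di[ok], ties.method = "min") + 1) / n
  names(pe) <- names(di)
  pe
}

#' Significant loci under the top-quantile rule
#'
#' Selects loci with `P_E` strictly below the significance proportion. With
#' N distinct values this keeps exactly the top k loci where k is the
#' largest integer with `k/N < proportion` (e.g. 219 of 43,835 at 0.005).
#'
#' @param pe empirical p-values (named by locus id).
#' @param config a [scan_config()].
#' @return Character vector of significant locus ids (or integer indices if
#'   unnamed), in decreasing d_i order of their P_E.
#' @export
significant_loci <- function(pe, config = scan_config()) {
  sel <- which(!is.na(pe) & pe < config$significance_proportion)
  sel <- sel[order(pe[sel])]
  if (is.null(names(pe))) sel else names(pe)[sel]
}

#' Merge significant SNPs into sweep regions
#'
#' Single-linkage chaining per chromosome: consecutive significant SNPs
#' (sorted by position) whose gap is at most `merge_gap_bp` (inclusive)
#' join one region. Region bounds are the member SNPs' min and max
#' positions; an isolated SNP forms a width-0 region. Merging is a
#' fixpoint: re-merging the output changes nothing.
#'
#' @param loci data.frame with columns `id`, `chrom`, `pos` for the
#'   significant SNPs.
#' @param config a [scan_config()].
#' @return data.frame of regions sorted by (chrom, start): `chrom`,
#'   `start_bp`, `end_bp`, `width_bp`, `n_snps`, `locus_ids`
#'   (comma-separated, in position order).
#' @export
merge_regions <- function(loci, config = scan_config()) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(loci)))
  if (!nrow(loci))
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), width_bp = numeric(),
                      n_snps = integer(), locus_ids = character(),
                      stringsAsFactors = FALSE))
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  out <- lapply(split(loci, loci$chrom), function(d) {
    gap <- c(Inf, diff(d$pos))
    grp <- cumsum(gap > config$merge_gap_bp)
    do.call(rbind, lapply(split(d, grp), function(r) {
      data.frame(chrom = r$chrom[1], start_bp = min(r$pos),
                 end_bp = max(r$pos), width_bp = max(r$pos) - min(r$pos),
                 n_snps = nrow(r),
                 locus_ids = paste(r$id, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export sweep regions as BED text
#'
#' Converts the 1-based inclusive region coordinates to the 0-based
#' half-open BED convention (`start - 1`, `end`).
#'
#' @param regions output of [merge_regions()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(paste(regions$chrom, regions$start_bp - 1, regions$end_bp,
                   paste0("region", seq_len(nrow(regions))), regions$n_snps,
                   sep = "\t"),
             path)
  invisible(path)
}

#' Run the full breed-specific selection scan for one focal population
#'
#' End to end: pooled-MAF filter over focal + reference samples, per-locus
#' pairwise Weir-Cockerham F_ST against every reference, genome-wide
#' per-pair moments, d_i, empirical p-values, top-quantile outlier calling,
#' and 500-kb region merging. The result is invariant to sample and locus
#' order.
#'
#' @param g a QC'd [genotype_matrix()].
#' @param focal focal population label.
#' @param references character vector of reference populations (non-empty,
#'   excluding `focal`).
#' @param config a [scan_config()].
#' @return An object of class `"di_scan"`: list with `focal`, `scan`
#'   (per-locus data.frame: `id`, `chrom`, `pos`, `di`, `pe`,
#'   `significant`), `regions` (from [merge_regions()]), `moments`,
#'   `n_loci_scanned`, and `config`.
#' @export
run_scan <- function(g, focal, references, config = scan_config()) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!length(references)) stop("reference list must be non-empty")
  if (focal %in% references)
    stop("focal population must not appear among the references")

  pool <- which(g$samples$population %in% c(focal, references))
  gs <- subset_genotypes(g, samples = pool)
  maf <- locus_summary(gs)$maf
  keep <- !is.na(maf) & maf >= config$scan_min_maf
  message("run_scan: ", sum(keep), " of ", length(keep),
          " loci pass the pooled MAF filter")
  gs <- subset_genotypes(gs, loci = which(keep))

  tab <- pairwise_fst_table(gs, focal, references)
  mom <- fst_moments(tab)
  di <- di_statistic(tab, mom)
  pe <- empirical_p(di)
  sig_ids <- significant_loci(pe, config)
  scan <- data.frame(id = gs$loci$id, chrom = gs$loci$chrom,
                     pos = gs$loci$pos, di = unname(di), pe = unname(pe),
                     significant = gs$loci$id %in% sig_ids,
                     stringsAsFactors = FALSE)
  regions <- merge_regions(scan[scan$significant, c("id", "chrom", "pos")],
                           config)
  structure(list(focal = focal, scan = scan, regions = regions,
                 moments = mom, n_loci_scanned = nrow(scan),
                 config = config),
            class = "di_scan")
}

#' @export
print.di_scan <- function(x, ...) {
  cat("di_scan for focal population ", x$focal, ": ", x$n_loci_scanned,
      " loci, ", sum(x$scan$significant), " significant (P_E < ",
      x$config$significance_proportion, "), ", nrow(x$regions),
      " merged regions\n", sep = "")
  invisible(x)
}
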