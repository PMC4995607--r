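#' Diploid genotype matrix with sample and locus metadata
#'
#' The central container of the package: alt-allele dosages (copies of the
#' second listed allele `a2`) for `n` diploid samples at `m` biallelic loci,
#' together with sample metadata (population, altitude class) and locus
#' metadata (id, chromosome, position, alleles). Missing genotypes are `NA`,
#' never 0. Loci are kept sorted by (chromosome, position).
#'
#' @param dosage integer matrix, samples x loci, values in `{0, 1, 2, NA}`.
#' @param samples data.frame with columns `id`, `population`,
#'   `altitude` (each `"high"` or `"low"`); one row per matrix row.
#' @param loci data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `a1`, `a2`; one row per matrix column.
#'
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `dosage`, `samples`, `loci`.
#' @examples
#' g <- genotype_matrix(
#'   dosage  = matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'                    dimnames = list(c("s1", "s2"), c("l1", "l2"))),
#'   samples = data.frame(id = c("s1", "s2"),
#'                        population = c("P1", "P2"),
#'                        altitude = c("high", "low")),
#'   loci    = data.frame(id = c("l1", "l2"), chrom = "1",
#'                        pos = c(100L, 200L), a1 = "A", a2 = "G")
#' )
#' dim(g$dosage)
#' @export
genotype_matrix <- function(dosage, samples, loci) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)

  stopifnot(
    all(c("id", "population", "altitude") %in% names(samples)),
    all(c("id", "chrom", "pos", "a1", "a2") %in% names(loci))
  )
  if (nrow(samples) != nrow(dosage))
    stop("samples metadata (", nrow(samples), " rows) does not match dosage (",
         nrow(dosage), " rows)")
  if (nrow(loci) != ncol(dosage))
    stop("locus metadata (", nrow(loci), " rows) does not match dosage (",
         ncol(dosage), " columns)")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage values must be 0, 1, 2 or NA")
  if (anyDuplicated(loci$id))
    stop("duplicate locus id: ",
         paste(unique(loci$id[duplicated(loci$id)]), collapse = ", "))
  if (anyDuplicated(samples$id))
    stop("duplicate sample id")
  if (any(loci$pos < 1)) stop("locus positions must be >= 1")
  if (any(loci$a1 == loci$a2)) stop("locus alleles a1 and a2 must differ")
  if (!all(samples$altitude %in% c("high", "low")))
    stop("altitude must be 'high' or 'low'")
  alt_per_pop <- tapply(samples$altitude, samples$population,
                        function(x) length(unique(x)))
  if (any(alt_per_pop > 1))
    stop("each population must map to exactly one altitude class")

  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(loci) <- NULL
  rownames(samples) <- NULL
  dimnames(dosage) <- list(samples$id, loci$id)

  structure(list(dosage = dosage, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " loci\n", sep = "")
  pops <- table(x$samples$population)
  cat("populations:", paste0(names(pops), " (n=", pops, ")", collapse = ", "),
      "\n")
  cat("missing genotypes:",
      sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), "\n")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or loci
#'
#' @param g a [genotype_matrix()].
#' @param samples logical/integer/character index into samples (default all).
#' @param loci logical/integer/character index into loci (default all).
#' @return A `genotype_matrix` restricted to the selected rows/columns.
#' @export
subset_genotypes <- function(g, samples = NULL, loci = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(g$dosage)) else samples
  if (is.character(si)) si <- match(si, g$samples$id)
  li <- if (is.null(loci)) seq_len(ncol(g$dosage)) else loci
  if (is.character(li)) li <- match(li, g$loci$id)
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(li)) stop("unknown locus id in subset")
  genotype_matrix(g$dosage[si, li, drop = FALSE],
                  g$samples[si, , drop = FALSE],
                  g$loci[li, , drop = FALSE])
}

# row indices of the samples belonging to one population
pop_rows <- function(g, population) {
  idx <- which(g$samples$population == population)
  if (!length(idx)) stop("population not found: ", population)
  idx
}

# names of populations in a given altitude class
populations_of <- function(g, altitude = c("high", "low")) {
  altitude <- match.arg(altitude)
  unique(g$samples$population[g$samples$altitude == altitude])
}

# per-population per-locus summaries used by the FST machinery:
# n (non-missing diploids), p (freq of a2), h (observed het fraction)
pop_locus_stats <- function(g, population) {
  d <- g$dosage[pop_rows(g, population), , drop = FALSE]
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}
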