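#' Quality-control thresholds
#'
#' Bundle of the SNP-array QC rules. The inequalities are strict, exactly as
#' conventionally applied: loci with call rate < `min_call_rate`, minor
#' allele frequency < `min_maf` or missingness > `max_locus_missing` are
#' removed, as are samples with missingness > `max_sample_missing`.
#'
#' @param min_call_rate minimum locus call rate retained (default 0.90).
#' @param min_maf minimum minor allele frequency retained (default 0.05).
#' @param max_locus_missing maximum locus missing fraction (default 0.10).
#' @param max_sample_missing maximum sample missing fraction (default 0.10).
#' @param autosomes chromosome labels considered autosomal, or `NULL` to
#'   keep all chromosomes. Labels are opaque strings; no species is
#'   hard-coded.
#' @return A list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_maf = 0.05,
                          max_locus_missing = 0.10,
                          max_sample_missing = 0.10,
                          autosomes = NULL) {
  vals <- c(min_call_rate, min_maf, max_locus_missing, max_sample_missing)
  if (any(vals < 0 | vals > 1))
    stop("QC thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 max_locus_missing = max_locus_missing,
                 max_sample_missing = max_sample_missing,
                 autosomes = autosomes),
            class = "qc_thresholds")
}

#' Allele frequency of one allele at one locus in one population
#'
#' Counts allele copies among non-missing chromosomes:
#' frequency = copies / (2 x non-missing diploids). If every genotype in the
#' population is missing the frequency is undefined (`NA`, flagged), never 0.
#'
#' @param g a [genotype_matrix()].
#' @param population population label.
#' @param locus locus id.
#' @param allele which allele to count, `"a1"`, `"a2"`, or an allele string.
#' @return A list with `freq`, `count` (copies), `n_chrom` (non-missing
#'   chromosomes), and `defined`.
#' @examples
#' \dontrun{
#' allele_frequency(g, "Bhyanglung", "snp1", "a2")
#' }
#' @export
allele_frequency <- function(g, population, locus, allele = "a2") {
  stopifnot(inherits(g, "genotype_matrix"))
  j <- match(locus, g$loci$id)
  if (is.na(j)) stop("locus not found: ", locus)
  d <- g$dosage[pop_rows(g, population), j]
  n_chrom <- 2L * sum(!is.na(d))
  if (!(allele %in% c("a1", "a2"))) {
    if (allele == g$loci$a1[j]) allele <- "a1"
    else if (allele == g$loci$a2[j]) allele <- "a2"
    else stop("allele ", allele, " not present at locus ", locus)
  }
  copies_a2 <- sum(d, na.rm = TRUE)
  count <- if (allele == "a2") copies_a2 else n_chrom - copies_a2
  list(freq = if (n_chrom > 0) count / n_chrom else NA_real_,
       count = as.integer(count),
       n_chrom = as.integer(n_chrom),
       defined = n_chrom > 0)
}

# pooled (all-sample) a2 frequency and call statistics per locus
locus_summary <- function(g) {
  d <- g$dosage
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  data.frame(id = g$loci$id,
             call_rate = n / nrow(d),
             missing = 1 - n / nrow(d),
             maf = pmin(p, 1 - p),
             stringsAsFactors = FALSE)
}

#' Filter a genotype matrix by QC rules
#'
#' Filters are applied in a fixed, documented order: (1) samples exceeding
#' the missingness bound, then on the surviving samples (2) loci failing
#' call rate or locus missingness, (3) loci failing the MAF bound, and
#' finally (4) restriction to autosomes when an autosome list is supplied.
#' Because removing loci changes sample missingness (and vice versa), the
#' four-step pass is repeated until nothing more is removed, which makes
#' the operation idempotent by construction. The rules use strict
#' inequalities (a locus at MAF exactly `min_maf` is retained).
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return A list with `matrix` (the filtered [genotype_matrix()]) and
#'   `report`, a data.frame of every removal with columns `type`
#'   (`"sample"`/`"locus"`), `id`, `rule` and `value`.
#' @export
qc_filter <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  report <- data.frame(type = character(), id = character(),
                       rule = character(), value = numeric(),
                       stringsAsFactors = FALSE)
  note <- function(type, id, rule, value) {
    if (length(id))
      report <<- rbind(report, data.frame(type = type, id = id, rule = rule,
                                          value = value,
                                          stringsAsFactors = FALSE))
  }

  repeat {
    removed_before <- nrow(report)

    # 1. sample missingness
    smiss <- rowMeans(is.na(g$dosage))
    drop_s <- nrow(g$loci) > 0 & smiss > thresholds$max_sample_missing
    note("sample", g$samples$id[drop_s], "sample_missing", smiss[drop_s])
    if (any(drop_s)) g <- subset_genotypes(g, samples = which(!drop_s))

    # 2. locus call rate / missingness
    ls <- locus_summary(g)
    drop_cr <- ls$call_rate < thresholds$min_call_rate |
      ls$missing > thresholds$max_locus_missing
    note("locus", ls$id[drop_cr], "call_rate", ls$call_rate[drop_cr])
    if (any(drop_cr)) {
      g <- subset_genotypes(g, loci = which(!drop_cr))
      ls <- ls[!drop_cr, , drop = FALSE]
    }

    # 3. MAF (computed on the post-sample-filter matrix); strict "< min_maf"
    drop_maf <- is.na(ls$maf) | ls$maf < thresholds$min_maf
    note("locus", ls$id[drop_maf], "maf", ls$maf[drop_maf])
    if (any(drop_maf)) g <- subset_genotypes(g, loci = which(!drop_maf))

    # 4. autosome restriction
    if (!is.null(thresholds$autosomes)) {
      drop_chr <- !(g$loci$chrom %in% thresholds$autosomes)
      note("locus", g$loci$id[drop_chr], "non_autosomal", NA_real_)
      if (any(drop_chr)) g <- subset_genotypes(g, loci = which(!drop_chr))
    }

    if (nrow(report) == removed_before) break
  }

  message("qc_filter: removed ", sum(report$type == "sample"), " samples, ",
          sum(report$type == "locus"), " loci; retained ",
          nrow(g$dosage), " x ", ncol(g$dosage))
  list(matrix = g, report = report)
}
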