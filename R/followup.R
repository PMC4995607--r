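#' Read a two-group re-sequencing panel from a VCF file
#'
#' Loads biallelic SNVs from a VCF v4.x file (via the vcfR package) and
#' tallies per-site per-group alternate-allele counts from the GT fields.
#' Missing genotypes are excluded from the denominators; multi-allelic or
#' non-SNV records are skipped with a message.
#'
#' @param vcf_path path to the VCF file.
#' @param groups named list of two character vectors of sample ids; the
#'   first element is group 1 (conventionally the highland group).
#' @return A `"reseq_panel"` (see [simulate_reseq_panel()]).
#' @export
read_panel_vcf <- function(vcf_path, groups) {
  stopifnot(length(groups) == 2, !is.null(names(groups)))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  absent <- setdiff(unlist(groups), colnames(gt))
  if (length(absent))
    stop("sample(s) not present in VCF: ", paste(absent, collapse = ", "))

  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snv))
    message("read_panel_vcf: skipping ", sum(!snv),
            " non-biallelic-SNV record(s)")
  fix <- fix[snv, , drop = FALSE]
  gt <- gt[snv, , drop = FALSE]

  gt_dosage <- function(x) {
    # unphased or phased diploid GT -> alt-allele dosage
    d <- rep(NA_integer_, length(x))
    clean <- gsub("\\|", "/", x)
    known <- !is.na(clean) & clean %in% c("0/0", "0/1", "1/0", "1/1")
    d[known] <- vapply(strsplit(clean[known], "/"),
                       function(a) sum(as.integer(a)), 0L)
    d
  }
  geno <- lapply(groups, function(ids) {
    m <- apply(gt[, ids, drop = FALSE], 2, gt_dosage)
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(gt),
                                     dimnames = list(NULL, ids))
    m
  })
  pos <- as.integer(fix$POS)
  ord <- order(pos)
  new_reseq_panel(
    region = list(chrom = fix$CHROM[1], start = min(pos), end = max(pos)),
    sites = data.frame(pos = pos[ord], ref = fix$REF[ord],
                       alt = fix$ALT[ord], stringsAsFactors = FALSE),
    groups = groups,
    geno = lapply(geno, function(m) m[ord, , drop = FALSE]))
}

#' Filter panel sites by pooled minor allele frequency
#'
#' Retains sites whose minor-allele frequency, pooled across both groups'
#' non-missing chromosomes, is strictly greater than `min_maf`.
#'
#' @param panel a `"reseq_panel"`.
#' @param min_maf the (strict) MAF floor, default 0.05.
#' @return The panel restricted to passing sites.
#' @export
site_maf_filter <- function(panel, min_maf = 0.05) {
  stopifnot(inherits(panel, "reseq_panel"))
  alt <- rowSums(panel$alt_count)
  tot <- rowSums(panel$n_chrom)
  maf <- ifelse(tot > 0, pmin(alt / tot, 1 - alt / tot), NA_real_)
  keep <- !is.na(maf) & maf > min_maf
  panel$sites <- panel$sites[keep, , drop = FALSE]
  panel$geno <- lapply(panel$geno, function(m) m[keep, , drop = FALSE])
  panel$alt_count <- panel$alt_count[keep, , drop = FALSE]
  panel$n_chrom <- panel$n_chrom[keep, , drop = FALSE]
  rownames(panel$sites) <- NULL
  panel
}

#' Fisher's exact test of allele-frequency divergence at one site
#'
#' Two-sided exact test of the 2x2 table of (alt, ref) chromosome counts by
#' group, using the standard "as-or-less-probable tables" two-sided rule.
#' A table with a zero margin yields p = 1 and is flagged degenerate.
#'
#' @param alt1,n1 alternate copies and total non-missing chromosomes in
#'   group 1.
#' @param alt2,n2 likewise for group 2.
#' @param threshold significance cutoff on p (strict; default 0.001).
#' @return A list with `p_value`, `freq1`, `freq2`, `significant`,
#'   `fixed_in_group1` (one allele fixed in group 1),
#'   `segregating_in_group2` (both alleles seen in group 2), `degenerate`.
#' @export
fisher_exact_site <- function(alt1, n1, alt2, n2, threshold = 0.001) {
  stopifnot(alt1 >= 0, alt2 >= 0, alt1 <= n1, alt2 <= n2)
  tab <- matrix(c(alt1, n1 - alt1, alt2, n2 - alt2), 2, 2)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  p <- min(p, 1)
  list(p_value = p,
       freq1 = if (n1 > 0) alt1 / n1 else NA_real_,
       freq2 = if (n2 > 0) alt2 / n2 else NA_real_,
       significant = p < threshold,
       fixed_in_group1 = n1 > 0 && (alt1 == 0 || alt1 == n1),
       segregating_in_group2 = alt2 > 0 && alt2 < n2,
       degenerate = degenerate)
}

#' Scan every panel site for allele-frequency divergence
#'
#' Applies [fisher_exact_site()] to each site; sites with all genotypes
#' missing in a group are excluded (logged). For every significant site the
#' fixed-in-group-1 / segregating-in-group-2 footprint flags are reported —
#' the pattern expected when a sweep has completed in the highland group.
#'
#' @param panel a (MAF-filtered) `"reseq_panel"`.
#' @param threshold strict p cutoff (default 0.001).
#' @return data.frame sorted by position: `pos`, `ref`, `alt`, `p_value`,
#'   `freq1`, `freq2`, `significant`, `fixed_in_group1`,
#'   `segregating_in_group2`.
#' @export
divergence_scan <- function(panel, threshold = 0.001) {
  stopifnot(inherits(panel, "reseq_panel"))
  testable <- panel$n_chrom[, 1] > 0 & panel$n_chrom[, 2] > 0
  if (any(!testable))
    message("divergence_scan: ", sum(!testable),
            " site(s) with a fully missing group excluded")
  rows <- which(testable)
  res <- lapply(rows, function(i) {
    fisher_exact_site(panel$alt_count[i, 1], panel$n_chrom[i, 1],
                      panel$alt_count[i, 2], panel$n_chrom[i, 2],
                      threshold = threshold)
  })
  out <- data.frame(
    pos = panel$sites$pos[rows],
    ref = panel$sites$ref[rows],
    alt = panel$sites$alt[rows],
    p_value = vapply(res, `[[`, 0, "p_value"),
    freq1 = vapply(res, `[[`, 0, "freq1"),
    freq2 = vapply(res, `[[`, 0, "freq2"),
    significant = vapply(res, `[[`, TRUE, "significant"),
    fixed_in_group1 = vapply(res, `[[`, TRUE, "fixed_in_group1"),
    segregating_in_group2 = vapply(res, `[[`, TRUE, "segregating_in_group2"),
    stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

#' Summarize an allele-frequency gradient across altitude-ranked populations
#'
#' Orders per-population allele frequencies by altitude rank and reports
#' the Spearman rank correlation between rank and frequency (midranks for
#' ties), plus whether the frequencies increase strictly monotonically with
#' altitude.
#'
#' @param frequencies data.frame with columns `population`,
#'   `altitude_rank` (higher = higher altitude) and `freq`.
#' @return A list with `table` (sorted low to high altitude), `rho`
#'   (`NA` with `constant = TRUE` when all frequencies are equal), and
#'   `monotone_increasing`.
#' @export
altitude_gradient_summary <- function(frequencies) {
  stopifnot(all(c("population", "altitude_rank", "freq") %in%
                  names(frequencies)))
  if (nrow(frequencies) < 3)
    stop("need at least 3 populations with distinct altitude ranks")
  if (anyDuplicated(frequencies$altitude_rank))
    stop("altitude ranks must be distinct")
  tab <- frequencies[order(frequencies$altitude_rank), , drop = FALSE]
  rownames(tab) <- NULL
  constant <- length(unique(tab$freq)) == 1
  rho <- if (constant) NA_real_ else
    stats::cor(tab$altitude_rank, tab$freq, method = "spearman")
  list(table = tab, rho = rho, constant = constant,
       monotone_increasing = !constant && all(diff(tab$freq) > 0))
}
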