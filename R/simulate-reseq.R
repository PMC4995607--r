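#' Configuration for the re-sequencing panel simulator
#'
#' Describes a dense variant panel over one candidate region, genotyped in
#' two groups (highland and lowland individuals). A configured fraction of
#' sites is divergent: fixed for the alternate allele in the highland group
#' while still segregating (both alleles observed) in the lowland group —
#' the footprint a completed sweep leaves in re-sequencing data. Defaults
#' follow a 12-individual candidate-gene panel: 400 sites over
#' chr7:57,774,972-57,846,735, 4 highland vs 8 lowland diploids.
#'
#' @param chrom chromosome label.
#' @param start,end 1-based region bounds in bp (`start < end`).
#' @param n_sites number of biallelic sites.
#' @param n_high,n_low diploid counts of the two groups (each >= 1).
#' @param fraction_divergent fraction of sites made divergent.
#' @param seed integer seed.
#' @return A list of class `"reseq_config"`.
#' @export
reseq_config <- function(chrom = "chr7", start = 57774972, end = 57846735,
                         n_sites = 400, n_high = 4, n_low = 8,
                         fraction_divergent = 0.05, seed = 1) {
  if (start >= end) stop("start must be < end")
  if (n_high < 1 || n_low < 1) stop("group sizes must be >= 1")
  if (n_sites > end - start + 1) stop("n_sites exceeds region length")
  if (fraction_divergent < 0 || fraction_divergent > 1)
    stop("fraction_divergent must be in [0, 1]")
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), n_sites = as.integer(n_sites),
                 n_high = as.integer(n_high), n_low = as.integer(n_low),
                 fraction_divergent = fraction_divergent,
                 seed = as.integer(seed)),
            class = "reseq_config")
}

# assemble a reseq_panel object from per-group genotype matrices
# (sites x diploids, dosages 0/1/2, NA = missing)
new_reseq_panel <- function(region, sites, groups, geno) {
  counts <- lapply(geno, function(m) {
    list(alt = rowSums(m, na.rm = TRUE),
         n_chrom = 2L * as.integer(rowSums(!is.na(m))))
  })
  structure(list(region = region, sites = sites, groups = groups,
                 geno = geno,
                 alt_count = cbind(group1 = counts[[1]]$alt,
                                   group2 = counts[[2]]$alt),
                 n_chrom = cbind(group1 = counts[[1]]$n_chrom,
                                 group2 = counts[[2]]$n_chrom)),
            class = "reseq_panel")
}

#' @export
print.reseq_panel <- function(x, ...) {
  cat("reseq_panel: ", nrow(x$sites), " sites in ", x$region$chrom, ":",
      x$region$start, "-", x$region$end, "\n", sep = "")
  cat("groups: ", names(x$groups)[1], " (", ncol(x$geno[[1]]), " diploids) vs ",
      names(x$groups)[2], " (", ncol(x$geno[[2]]), " diploids)\n", sep = "")
  invisible(x)
}

#' Simulate a two-group re-sequencing variant panel
#'
#' Neutral sites share one allele frequency between groups; divergent sites
#' are fixed for the alternate allele in the highland group and drawn to be
#' strictly polymorphic in the lowland group (frequency in (0.2, 0.8),
#' redrawn until both alleles are observed).
#'
#' @param config a [reseq_config()].
#' @param vcf_path optional path; when given the panel is also written as a
#'   VCF v4.2 text file via [write_panel_vcf()].
#' @return A list with `panel` (class `"reseq_panel"`), `truth` (logical
#'   vector marking divergent sites), and `vcf_path` (or `NULL`).
#' @export
simulate_reseq_panel <- function(config, vcf_path = NULL) {
  stopifnot(inherits(config, "reseq_config"))
  set.seed(stage_seed(config$seed, "reseq"))
  ns <- config$n_sites
  pos <- sort(sample(seq(config$start, config$end), ns))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  n_div <- round(config$fraction_divergent * ns)
  divergent <- rep(FALSE, ns)
  if (n_div > 0) divergent[sample(ns, n_div)] <- TRUE

  gh <- matrix(NA_integer_, ns, config$n_high)
  gl <- matrix(NA_integer_, ns, config$n_low)
  shared <- stats::runif(ns, 0.05, 0.95)
  for (i in seq_len(ns)) {
    if (divergent[i]) {
      gh[i, ] <- 2L
      repeat {
        f <- stats::runif(1, 0.2, 0.8)
        gl[i, ] <- stats::rbinom(config$n_low, 2L, f)
        a <- sum(gl[i, ])
        if (a > 0 && a < 2 * config$n_low) break
      }
    } else {
      gh[i, ] <- stats::rbinom(config$n_high, 2L, shared[i])
      gl[i, ] <- stats::rbinom(config$n_low, 2L, shared[i])
    }
  }
  groups <- list(highland = paste0("HI", seq_len(config$n_high)),
                 lowland = paste0("LO", seq_len(config$n_low)))
  colnames(gh) <- groups$highland
  colnames(gl) <- groups$lowland
  panel <- new_reseq_panel(
    region = list(chrom = config$chrom, start = config$start,
                  end = config$end),
    sites = data.frame(pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
    groups = groups, geno = list(highland = gh, lowland = gl))
  if (!is.null(vcf_path)) write_panel_vcf(panel, vcf_path)
  list(panel = panel, truth = divergent, vcf_path = vcf_path)
}

#' Write a re-sequencing panel as a VCF v4.2 text file
#'
#' Emits one biallelic SNV record per site with unphased `GT` genotypes for
#' every sample of both groups (`./.` for missing).
#'
#' @param panel a `"reseq_panel"`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "reseq_panel"))
  gt_code <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
  }
  gmat <- cbind(panel$geno[[1]], panel$geno[[2]])
  gt <- apply(gmat, 2, gt_code)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(panel$sites))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", panel$region$chrom, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gmat)), collapse = "\t"))
  body <- paste(panel$region$chrom, panel$sites$pos,
                paste0(panel$region$chrom, "_", panel$sites$pos),
                panel$sites$ref, panel$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
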