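# derive a reproducible sub-seed for a named simulation stage so stages are
# independently reproducible from one root seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + sum(utf8ToInt(stage)) %% 100003L
}

#' Configuration for the Balding-Nichols panel simulator
#'
#' Describes a multi-population SNP-array panel: each locus has an ancestral
#' frequency drawn from `ancestral_freq_law`, and each population's
#' frequency is Beta-distributed around it with variance
#' `p (1 - p) drift_F` (the Balding-Nichols model, whose `drift_F` equals
#' the expected fixation index against the ancestral pool). Designated
#' sweep loci override the highland-population frequencies with an
#' end-state target frequency, emulating directional selection.
#'
#' Defaults emulate a SheepHapMap-scale study: 12 populations (4 highland,
#' 8 lowland) of 24 diploids each, 45,000 autosomal SNPs on 26 chromosomes,
#' drift at `F = 0.10` (pairwise differentiation in the 0.08-0.20 band).
#'
#' @param n_loci number of biallelic loci.
#' @param populations data.frame with columns `name`, `altitude`
#'   (`"high"`/`"low"`), `n` (diploids), `drift_F` (in (0,1)).
#' @param ancestral_freq_law function of one integer argument returning that
#'   many ancestral frequencies; default uniform on (0.05, 0.95).
#' @param sweep_loci data.frame with columns `index` (locus index),
#'   `high_freq` (target highland frequency in `[0,1]`) and optionally
#'   `ancestral` (forced ancestral frequency at that locus); or `NULL`.
#' @param n_chrom number of chromosomes the loci are laid out on.
#' @param spacing_bp base-pair spacing between adjacent loci.
#' @param missing_rate uniform genotype missingness rate (default 0).
#' @param ld_block_size if > 1, loci are generated in blocks of this many
#'   adjacent near-copies of one template genotype column, creating LD
#'   blocks for pruning/decay tests.
#' @param ld_block_noise per-genotype probability that a block member is
#'   redrawn independently instead of copying the template (default 0.05).
#' @param seed root integer seed; all stages derive named sub-streams.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_loci = 45000,
                       populations = default_populations(),
                       ancestral_freq_law = function(n) stats::runif(n, 0.05, 0.95),
                       sweep_loci = NULL,
                       n_chrom = 26,
                       spacing_bp = 50000,
                       missing_rate = 0,
                       ld_block_size = 1,
                       ld_block_noise = 0.05,
                       seed = 1) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "altitude", "n", "drift_F") %in% names(populations)))
  if (any(populations$drift_F <= 0 | populations$drift_F >= 1))
    stop("drift_F must lie strictly inside (0, 1)")
  if (!all(populations$altitude %in% c("high", "low")))
    stop("altitude must be 'high' or 'low'")
  if (!is.null(sweep_loci)) {
    sweep_loci <- as.data.frame(sweep_loci)
    stopifnot(all(c("index", "high_freq") %in% names(sweep_loci)))
    if (any(sweep_loci$index < 1 | sweep_loci$index > n_loci))
      stop("sweep locus index out of range")
    if (any(sweep_loci$high_freq < 0 | sweep_loci$high_freq > 1))
      stop("sweep target frequency must lie in [0, 1]")
    if (is.null(sweep_loci$ancestral)) sweep_loci$ancestral <- NA_real_
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0, 1)")
  structure(list(n_loci = as.integer(n_loci), populations = populations,
                 ancestral_freq_law = ancestral_freq_law,
                 sweep_loci = sweep_loci, n_chrom = as.integer(n_chrom),
                 spacing_bp = as.integer(spacing_bp),
                 missing_rate = missing_rate,
                 ld_block_size = as.integer(ld_block_size),
                 ld_block_noise = ld_block_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_populations <- function() {
  data.frame(
    name = c(paste0("HIGH", 1:4), paste0("LOW", 1:8)),
    altitude = rep(c("high", "low"), c(4, 8)),
    n = 24L,
    drift_F = 0.10,
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-population genotype panel
#'
#' Draws per-population allele frequencies from the Balding-Nichols Beta
#' model around ancestral frequencies, then genotypes as two independent
#' allele draws (Hardy-Weinberg within population). Sweep loci override the
#' highland frequencies with the configured end-state target. The same
#' configuration (same seed) reproduces the panel exactly.
#'
#' @param config a [sim_config()].
#' @return A list with `matrix` (a [genotype_matrix()]), `truth`
#'   (data.frame of sweep loci: `locus_id`, `index`, `high_freq`), and
#'   `pop_freq` (loci x populations matrix of realized allele frequencies).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_loci
  pops <- config$populations

  set.seed(stage_seed(config$seed, "ancestral"))
  n_profiles <- if (config$ld_block_size > 1)
    ceiling(m / config$ld_block_size) else m
  p_anc_prof <- config$ancestral_freq_law(n_profiles)
  if (any(p_anc_prof <= 0 | p_anc_prof >= 1))
    stop("ancestral_freq_law must return frequencies strictly inside (0, 1)")

  set.seed(stage_seed(config$seed, "drift"))
  freq_prof <- matrix(NA_real_, n_profiles, nrow(pops))
  for (k in seq_len(nrow(pops))) {
    F <- pops$drift_F[k]
    shape <- (1 - F) / F
    freq_prof[, k] <- stats::rbeta(n_profiles, p_anc_prof * shape,
                                   (1 - p_anc_prof) * shape)
  }
  # expand profiles into LD blocks of adjacent, nearly identical loci
  block_of <- rep(seq_len(n_profiles), each = config$ld_block_size)[seq_len(m)]
  freq <- freq_prof[block_of, , drop = FALSE]
  p_anc <- p_anc_prof[block_of]

  if (!is.null(config$sweep_loci)) {
    sl <- config$sweep_loci
    high_cols <- which(pops$altitude == "high")
    if (!length(high_cols)) stop("sweep loci configured but no highland population")
    forced <- !is.na(sl$ancestral)
    if (any(forced)) {
      # redraw the non-highland frequencies around the forced ancestral value
      set.seed(stage_seed(config$seed, "sweep-ancestral"))
      for (r in which(forced)) {
        p_anc[sl$index[r]] <- sl$ancestral[r]
        for (k in seq_len(nrow(pops))) {
          F <- pops$drift_F[k]
          shape <- (1 - F) / F
          freq[sl$index[r], k] <- stats::rbeta(1, sl$ancestral[r] * shape,
                                               (1 - sl$ancestral[r]) * shape)
        }
      }
    }
    freq[sl$index, high_cols] <- sl$high_freq
  }

  set.seed(stage_seed(config$seed, "genotypes"))
  n_total <- sum(pops$n)
  dosage <- matrix(NA_integer_, n_total, m)
  row0 <- 0L
  for (k in seq_len(nrow(pops))) {
    nk <- pops$n[k]
    if (config$ld_block_size > 1) {
      # LD blocks: loci in a block copy a shared template genotype column,
      # each copy perturbed by independent redraws at rate ld_block_noise
      template <- matrix(
        stats::rbinom(nk * n_profiles, 2L,
                      rep(freq_prof[, k], each = nk)), nk, n_profiles)
      gk <- template[, block_of, drop = FALSE]
      flip <- stats::runif(nk * m) < config$ld_block_noise
      if (any(flip))
        gk[flip] <- stats::rbinom(sum(flip), 2L,
                                  rep(freq[, k], each = nk)[flip])
      dosage[row0 + seq_len(nk), ] <- gk
    } else {
      dosage[row0 + seq_len(nk), ] <- matrix(
        stats::rbinom(nk * m, 2L, rep(freq[, k], each = nk)), nk, m)
    }
    row0 <- row0 + nk
  }
  if (config$missing_rate > 0) {
    set.seed(stage_seed(config$seed, "missing"))
    dosage[stats::runif(length(dosage)) < config$missing_rate] <- NA_integer_
  }

  per_chrom <- ceiling(m / config$n_chrom)
  chrom_idx <- rep(seq_len(config$n_chrom), each = per_chrom)[seq_len(m)]
  pos_in_chrom <- stats::ave(seq_len(m), chrom_idx, FUN = seq_along)
  loci <- data.frame(
    id = sprintf("snp%06d", seq_len(m)),
    chrom = sprintf("chr%02d", chrom_idx),
    pos = pos_in_chrom * config$spacing_bp,
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  samples <- data.frame(
    id = paste0(rep(pops$name, pops$n), "_",
                unlist(lapply(pops$n, seq_len))),
    population = rep(pops$name, pops$n),
    altitude = rep(pops$altitude, pops$n), stringsAsFactors = FALSE)

  truth <- if (is.null(config$sweep_loci)) {
    data.frame(locus_id = character(), index = integer(),
               high_freq = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(locus_id = loci$id[config$sweep_loci$index],
               index = config$sweep_loci$index,
               high_freq = config$sweep_loci$high_freq,
               stringsAsFactors = FALSE)
  }
  colnames(freq) <- pops$name
  rownames(freq) <- loci$id
  list(matrix = genotype_matrix(dosage, samples, loci),
       truth = truth, pop_freq = freq)
}

#' Inject a directional-selection signal at one locus
#'
#' Redraws the genotypes of every highland sample at `locus` from
#' Hardy-Weinberg proportions at `target_freq`; lowland genotypes are left
#' untouched. Emulates the end state of a sweep (the high-altitude allele
#' near fixation in highland populations).
#'
#' @param g a [genotype_matrix()].
#' @param locus locus id.
#' @param target_freq target frequency of allele `a2` in `[0, 1]`.
#' @param seed optional integer seed for the redraw.
#' @return The modified [genotype_matrix()].
#' @export
inject_sweep <- function(g, locus, target_freq, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  j <- match(locus, g$loci$id)
  if (is.na(j)) stop("locus not found: ", locus)
  if (target_freq < 0 || target_freq > 1) stop("target_freq must be in [0, 1]")
  rows <- which(g$samples$altitude == "high")
  if (!length(rows)) stop("no highland population present")
  if (!is.null(seed)) set.seed(seed)
  g$dosage[rows, j] <- stats::rbinom(length(rows), 2L, target_freq)
  g
}
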