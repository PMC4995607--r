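#' Read genotypes from PLINK PED/MAP text files
#'
#' Parses the white-space separated PED/MAP dialect. The MAP file may have
#' the standard 4 columns (chrom, id, cM, pos) or 6 columns with the two
#' alleles appended (chrom, id, cM, pos, a1, a2), as written by
#' [write_genotypes()]. With a 4-column MAP the alleles observed at each
#' locus are assigned lexicographically (`a1` sorts first); dosage always
#' counts copies of `a2`. The PED missing-allele code is `"0"`.
#'
#' The PED family-ID column is taken as the population label. Altitude
#' classes are supplied via `population_altitude`; populations not named
#' there default to `"low"`.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @param population_altitude named character vector mapping population
#'   labels to `"high"`/`"low"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(ped_path, map_path, population_altitude = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  ncol_map <- if (length(map_fields)) lengths(map_fields) else integer(0)
  if (length(ncol_map) && !all(ncol_map %in% c(4L, 6L)))
    stop("MAP parse error at line ", which(!(ncol_map %in% c(4L, 6L)))[1],
         ": expected 4 or 6 fields")
  has_alleles <- length(ncol_map) > 0 && all(ncol_map == 6L)
  loci <- data.frame(
    id    = vapply(map_fields, `[`, "", 2L),
    chrom = vapply(map_fields, `[`, "", 1L),
    pos   = as.integer(vapply(map_fields, `[`, "", 4L)),
    a1    = if (has_alleles) vapply(map_fields, `[`, "", 5L) else NA_character_,
    a2    = if (has_alleles) vapply(map_fields, `[`, "", 6L) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (anyNA(loci$pos))
    stop("MAP parse error at line ", which(is.na(loci$pos))[1],
         ": position is not an integer")
  if (anyDuplicated(loci$id))
    stop("duplicate locus id in MAP: ",
         loci$id[duplicated(loci$id)][1])
  m <- nrow(loci)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  dosage <- matrix(NA_integer_, n, m)
  al1 <- matrix(NA_character_, n, m)  # raw allele calls, resolved afterwards
  al2 <- matrix(NA_character_, n, m)
  fam <- character(n); iid <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("PED parse error at line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(f))
    fam[i] <- f[1]; iid[i] <- f[2]
    g <- f[-(1:6)]
    al1[i, ] <- g[seq(1, 2 * m, by = 2)]
    al2[i, ] <- g[seq(2, 2 * m, by = 2)]
  }
  half_missing <- xor(al1 == "0", al2 == "0")
  if (any(half_missing))
    stop("PED parse error: half-missing genotype at line ",
         which(rowSums(half_missing) > 0)[1])
  al1[al1 == "0"] <- NA; al2[al2 == "0"] <- NA

  for (j in seq_len(m)) {
    obs <- sort(unique(stats::na.omit(c(al1[, j], al2[, j]))))
    if (length(obs) > 2)
      stop("locus ", loci$id[j], " has more than two alleles")
    if (is.na(loci$a1[j])) {   # 4-column MAP: lexicographic assignment
      loci$a1[j] <- if (length(obs) >= 1) obs[1] else "A"
      loci$a2[j] <- if (length(obs) == 2) obs[2] else
        if (loci$a1[j] == "A") "B" else "A"
    } else if (length(obs) && !all(obs %in% c(loci$a1[j], loci$a2[j]))) {
      stop("locus ", loci$id[j], ": PED alleles disagree with MAP alleles")
    }
    dosage[, j] <- (al1[, j] == loci$a2[j]) + (al2[, j] == loci$a2[j])
  }

  alt <- rep("low", n)
  if (!is.null(population_altitude)) {
    hit <- fam %in% names(population_altitude)
    alt[hit] <- unname(population_altitude[fam[hit]])
  }
  genotype_matrix(dosage,
                  data.frame(id = iid, population = fam, altitude = alt,
                             stringsAsFactors = FALSE),
                  loci)
}

#' Write genotypes to PLINK PED/MAP text files
#'
#' Emits a 6-column MAP (chrom, id, cM = 0, pos, a1, a2) so that the
#' dosage-counting allele is explicit and [read_genotypes()] reproduces the
#' matrix exactly. Missing dosages are written as `"0 0"`.
#'
#' @param g a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_genotypes <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "genotype_matrix"))
  map <- if (nrow(g$loci) == 0) character(0) else
    with(g$loci, paste(chrom, id, 0L, pos, a1, a2, sep = "\t"))
  writeLines(map, map_path)

  m <- ncol(g$dosage)
  n <- nrow(g$dosage)
  gen <- matrix("", n, 2 * m)
  if (m > 0) {
    a1 <- matrix(g$loci$a1, n, m, byrow = TRUE)
    a2 <- matrix(g$loci$a2, n, m, byrow = TRUE)
    d <- g$dosage
    first  <- ifelse(is.na(d), "0", ifelse(d >= 1, a2, a1))
    second <- ifelse(is.na(d), "0", ifelse(d == 2, a2, a1))
    gen[, seq(1, 2 * m, by = 2)] <- first
    gen[, seq(2, 2 * m, by = 2)] <- second
  }
  lead <- cbind(g$samples$population, g$samples$id, "0", "0", "0", "-9")
  writeLines(apply(cbind(lead, gen), 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}
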