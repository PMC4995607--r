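test_that("VCF round trip reproduces the simulator's counts exactly", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  sp <- simulate_reseq_panel(reseq_config(n_sites = 80,
                                          fraction_divergent = 0.1,
                                          seed = 9), vcf_path = vcf)
  p2 <- read_panel_vcf(vcf, sp$panel$groups)
  expect_equal(p2$sites, sp$panel$sites)
  expect_identical(unname(p2$alt_count), unname(sp$panel$alt_count))
  expect_identical(unname(p2$n_chrom), unname(sp$panel$n_chrom))
  expect_error(read_panel_vcf(vcf, list(a = "HI1", b = "NOPE")),
               "not present")
})

test_that("multi-allelic and non-SNV records are skipped, missing GT dropped", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A1", "A2", "B1", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1\t0/0",
    "chr1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",   # multi-allelic
    "chr1\t300\t.\tAT\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",    # not a SNV
    "chr1\t400\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t1/1"), vcf)
  expect_message(p <- read_panel_vcf(vcf, list(hi = c("A1", "A2"),
                                               lo = "B1")),
                 "skipping 2")
  expect_identical(p$sites$pos, c(100L, 400L))
  expect_identical(unname(p$alt_count[, 1]), c(3, 1))   # phased GT counted
  expect_identical(unname(p$n_chrom), cbind(c(4L, 2L), c(2L, 2L)))
})

test_that("the pooled-MAF site filter is strict at the boundary", {
  # 24 chromosomes total (4 + 8 diploids): alt counts 1 (MAF ~0.042),
  # 2 would give 1/12 > 0.05; craft counts to land under, at, and over 0.05
  gh <- matrix(0L, 3, 2)  # 2 highland diploids
  gl <- matrix(0L, 3, 8)  # 8 lowland diploids -> 20 chromosomes pooled
  gh[1, 1] <- 1L                       # site 1: 1/20  = 0.05 exactly
  gh[2, 1] <- 1L; gl[2, 1] <- 1L       # site 2: 2/20  = 0.10 > 0.05
  panel <- altsweep:::new_reseq_panel(
    region = list(chrom = "chr7", start = 1, end = 1000),
    sites = data.frame(pos = c(10L, 20L, 30L), ref = "A", alt = "G"),
    groups = list(hi = paste0("H", 1:2), lo = paste0("L", 1:8)),
    geno = list(hi = gh, lo = gl))
  kept <- site_maf_filter(panel, min_maf = 0.05)
  expect_identical(kept$sites$pos, 20L)   # 0.05 exactly is removed (strict >)
  # recount a simulated panel against a hand loop
  sp <- simulate_reseq_panel(reseq_config(n_sites = 400, seed = 21,
                                          fraction_divergent = 0.05))
  flt <- site_maf_filter(sp$panel)
  pooled <- rowSums(sp$panel$alt_count) / rowSums(sp$panel$n_chrom)
  expect_identical(nrow(flt$sites),
                   sum(pmin(pooled, 1 - pooled) > 0.05))
})

test_that("Fisher p agrees with exhaustive enumeration", {
  # fixed alt in 4 highland diploids vs fixed ref in 8 lowland diploids
  res <- fisher_exact_site(8, 8, 0, 16)
  expect_equal(res$p_value, 1 / choose(24, 8), tolerance = 1e-12)
  expect_true(res$significant)
  expect_true(res$fixed_in_group1)
  expect_false(res$segregating_in_group2)
  # perfect homogeneity
  expect_equal(fisher_exact_site(5, 10, 5, 10)$p_value, 1)
  # zero margin -> degenerate, p = 1
  z <- fisher_exact_site(0, 8, 0, 16)
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
  # randomized small tables vs the enumeration oracle
  set.seed(12)
  for (rep in 1:40) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    a1 <- sample(0:n1, 1); a2 <- sample(0:n2, 1)
    got <- fisher_exact_site(a1, n1, a2, n2)$p_value
    want <- if ((a1 + a2) %in% c(0, n1 + n2)) 1 else
      oracle_fisher_p(a1, n1, a2, n2)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Fisher p is invariant to group swap and allele relabelling", {
  set.seed(30)
  for (rep in 1:15) {
    n1 <- sample(2:16, 1); n2 <- sample(2:16, 1)
    a1 <- sample(0:n1, 1); a2 <- sample(0:n2, 1)
    p <- fisher_exact_site(a1, n1, a2, n2)$p_value
    expect_equal(fisher_exact_site(a2, n2, a1, n1)$p_value, p,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_site(n1 - a1, n1, n2 - a2, n2)$p_value, p,
                 tolerance = 1e-12)
  }
})

test_that("a fixed-vs-balanced site is below the test's resolution", {
  # fixed 8/8 in group 1 but 8/16 in group 2: not significant at 0.001
  res <- fisher_exact_site(8, 8, 8, 16)
  expect_false(res$significant)
  expect_equal(res$p_value, oracle_fisher_p(8, 8, 8, 16),
               tolerance = 1e-12)
})

test_that("divergence_scan flags the sweep footprint and sorts by position", {
  sp <- simulate_reseq_panel(reseq_config(n_sites = 200,
                                          fraction_divergent = 0.3,
                                          n_high = 8, n_low = 8,
                                          seed = 41))
  flt <- site_maf_filter(sp$panel)
  scan <- divergence_scan(flt)
  expect_false(is.unsorted(scan$pos))
  expect_gt(sum(scan$significant), 0)
  sig <- scan[scan$significant, ]
  # significant sites in this construction are fixed-high, segregating-low
  expect_true(all(sig$fixed_in_group1))
  expect_true(all(sig$p_value < 0.001))
  truth_pos <- sp$panel$sites$pos[sp$truth]
  expect_true(all(sig$pos %in% truth_pos))
})

test_that("a null panel yields (almost) no significant divergence", {
  total <- 0
  for (seed in 1:20) {
    sp <- simulate_reseq_panel(reseq_config(n_sites = 300,
                                            fraction_divergent = 0,
                                            seed = seed))
    scan <- divergence_scan(site_maf_filter(sp$panel))
    total <- total + sum(scan$significant)
  }
  expect_lte(total, 2)
})

test_that("site classification partitions positions against the gene model", {
  gm <- gene_model("FGF7", "chr7", "+", tx_start = 60000, tx_end = 70000,
                   exons = data.frame(start = c(60000, 65000),
                                      end = c(61000, 66000)),
                   start_codon_pos = 60000)
  expect_identical(classify_site(gm, "chr7", 57997)$class, "upstream")
  expect_equal(classify_site(gm, "chr7", 57997)$distance_bp, 2003)
  expect_identical(classify_site(gm, "chr7", 60500)$class, "exonic")
  expect_identical(classify_site(gm, "chr7", 63000)$class, "intronic")
  expect_identical(classify_site(gm, "chr7", 71000)$class, "downstream")
  expect_identical(classify_site(gm, "chr7", 49000)$class, "intergenic")
  expect_identical(classify_site(gm, "chr7", 76001)$class, "intergenic")
  expect_identical(classify_site(gm, "chr1", 60500)$class, "intergenic")
  # minus strand mirrors the geometry
  gmm <- gene_model("G", "chr2", "-", 1000, 5000,
                    exons = data.frame(start = 4000, end = 5000),
                    start_codon_pos = 5000)
  up <- classify_site(gmm, "chr2", 6003)
  expect_identical(up$class, "upstream")
  expect_equal(up$distance_bp, 1003)
  expect_identical(classify_site(gmm, "chr2", 500)$class, "downstream")
  # every position gets exactly one class
  classes <- vapply(seq(54000, 76000, by = 117),
                    function(p) classify_site(gm, "chr7", p)$class, "")
  expect_true(all(classes %in% c("exonic", "intronic", "upstream",
                                 "downstream", "intergenic")))
})

test_that("conserved-element overlap honours the BED coordinate convention", {
  track <- conservation_track(data.frame(
    chrom = "chr7", start = 99, end = 150, score = 3.2))
  hit <- overlap_conserved(data.frame(chrom = "chr7", pos = 100), track)
  expect_true(hit$overlaps)
  expect_equal(hit$score, 3.2)
  expect_false(overlap_conserved(data.frame(chrom = "chr7", pos = 99),
                                 track)$overlaps)
  expect_true(overlap_conserved(data.frame(chrom = "chr7", pos = 150),
                                track)$overlaps)
  expect_false(overlap_conserved(data.frame(chrom = "chr7", pos = 151),
                                 track)$overlaps)
  # random sites vs an all-pairs scan
  set.seed(18)
  iv <- data.frame(chrom = sample(c("1", "2"), 30, TRUE),
                   start = sample(1000, 30))
  iv$end <- iv$start + sample(50, 30)
  iv$score <- runif(30)
  sites <- data.frame(chrom = sample(c("1", "2"), 200, TRUE),
                      pos = sample(1100, 200))
  got <- overlap_conserved(sites, conservation_track(iv))
  expect_identical(got$overlaps, oracle_overlap(sites, iv))
})

test_that("the altitude gradient summary orders and correlates correctly", {
  freqs <- data.frame(
    population = c("Lampuchhre", "Kage", "Baruwal", "Bhyanglung"),
    altitude_rank = 1:4,
    freq = c(0.025, 0.1071, 0.5645, 1.0))
  out <- altitude_gradient_summary(freqs)
  expect_identical(out$table$population[4], "Bhyanglung")
  expect_true(out$monotone_increasing)
  expect_equal(out$rho, 1)
  rev_out <- altitude_gradient_summary(transform(freqs, freq = rev(freq)))
  expect_equal(rev_out$rho, -1)
  const <- altitude_gradient_summary(transform(freqs, freq = 0.5))
  expect_true(const$constant)
  expect_true(is.na(const$rho))
  expect_error(altitude_gradient_summary(freqs[1:2, ]), "at least 3")
})
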