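fake_table <- function(theta, refs = colnames(theta)) {
  structure(list(focal = "F", references = refs,
                 theta = theta),
            class = "pairwise_fst_table")
}

test_that("d_i is the sum of standardized per-pair F_ST", {
  # one pair, locus exactly 1 sd above the pair mean -> d_i = 1
  th <- cbind(R1 = c(0.1, 0.2, 0.3))
  tab <- fake_table(th)
  mom <- fst_moments(tab)
  di <- di_statistic(tab, mom)
  expect_equal(unname(di[3]), (0.3 - 0.2) / 0.1)
  # loci at the pair means -> d_i = 0
  th2 <- cbind(R1 = c(0.1, 0.3), R2 = c(0.2, 0.4))
  tab2 <- fake_table(th2)
  di2 <- di_statistic(tab2, fst_moments(tab2))
  expect_equal(max(abs(di2 + rev(di2))), 0, tolerance = 1e-12)  # symmetric z
})

test_that("d_i matches a brute-force per-locus loop", {
  set.seed(6)
  th <- matrix(rnorm(90, 0.15, 0.06), 30, 3,
               dimnames = list(paste0("l", 1:30), c("A", "B", "C")))
  th[sample(90, 6)] <- NA
  tab <- fake_table(th)
  mom <- fst_moments(tab)
  di <- suppressMessages(di_statistic(tab, mom))
  for (i in 1:30) {
    want <- 0
    for (k in 1:3) {
      v <- th[, k][!is.na(th[, k])]
      mu <- mean(v); sdv <- sd(v)
      if (!is.na(th[i, k])) want <- want + (th[i, k] - mu) / sdv
    }
    expect_equal(unname(di[i]), want, tolerance = 1e-12)
  }
})

test_that("standardized columns are centred with unit sd, so mean d_i ~ 0", {
  g <- random_matrix(c("F", "R1", "R2", "R3"), 15, 200, seed = 20)
  tab <- pairwise_fst_table(g, "F", c("R1", "R2", "R3"))
  mom <- fst_moments(tab)
  di <- suppressMessages(di_statistic(tab, mom))
  z <- attr(di, "z")
  for (k in 1:3) {
    zk <- z[!is.na(tab$theta[, k]), k]
    expect_equal(mean(zk), 0, tolerance = 1e-9)
    expect_equal(sd(zk), 1, tolerance = 1e-9)
  }
  expect_lt(abs(mean(di)), 1e-9)
})

test_that("a zero-sd pair contributes nothing, with a warning", {
  th <- cbind(R1 = c(0.2, 0.2, 0.2), R2 = c(0.1, 0.2, 0.3))
  tab <- fake_table(th)
  mom <- suppressWarnings(fst_moments(tab))
  expect_warning(di <- di_statistic(tab, mom), "zero F_ST standard deviation")
  expect_equal(unname(di), (th[, 2] - 0.2) / 0.1, ignore_attr = TRUE)
})

test_that("empirical p is the tail proportion with shared ties", {
  expect_equal(unname(empirical_p(c(1, 2, 3, 4, 5))[5]), 1 / 5)
  expect_equal(unname(empirical_p(rep(2, 7))), rep(1, 7))
  set.seed(14)
  di <- c(rnorm(500), rnorm(250), rnorm(250))  # plenty of scope for ties
  di[sample(1000, 100)] <- di[sample(1000, 100)]
  pe <- empirical_p(di)
  expect_equal(unname(pe), oracle_empirical_p(di), tolerance = 1e-12)
  expect_true(all(pe > 0 & pe <= 1))
  # monotone non-increasing in d_i
  ord <- order(di, decreasing = TRUE)
  expect_true(all(diff(pe[ord]) >= 0))
})

test_that("non-finite d_i values are excluded from N with a warning", {
  expect_warning(pe <- empirical_p(c(1, 2, NA, Inf, 3)), "non-finite")
  expect_true(all(is.na(pe[3:4])))
  expect_equal(unname(pe[1:2]), c(3, 2) / 3)
})

test_that("the strict top-quantile rule selects the documented counts", {
  set.seed(99)
  cfgs <- list(c(n = 1000, k = 4), c(n = 200, k = 0))
  # n = 1000 distinct values: largest k with k/n < 0.005 is 4
  pe <- empirical_p(sample(seq_len(1000)))
  expect_length(significant_loci(pe, scan_config()), 4)
  # all tied -> P_E = 1 everywhere -> nothing selected
  pe_t <- empirical_p(rep(1.5, 50))
  expect_length(significant_loci(pe_t, scan_config()), 0)
  # selection is an upper set of the d_i order
  di <- rnorm(2000)
  pe2 <- empirical_p(di)
  sel <- significant_loci(pe2, scan_config(significance_proportion = 0.01))
  cutoff <- min(di[sel])
  expect_true(all(di[-sel] <= cutoff))
})

test_that("region merging reproduces the printed sweep arithmetic", {
  cfg <- scan_config()
  three <- data.frame(id = c("s1", "s2", "s3"), chrom = "chr7",
                      pos = c(57764872, 57816492, 57915106))
  r3 <- merge_regions(three, cfg)
  expect_identical(nrow(r3), 1L)
  expect_equal(r3$width_bp, 150234)          # 150.2 kb
  expect_equal(r3$start_bp, 57764872)
  expect_equal(r3$end_bp, 57915106)
  r2 <- merge_regions(three[1:2, ], cfg)
  expect_equal(r2$width_bp, 51620)           # 51.6 kb
})

test_that("the 500-kb merge gap is inclusive and merging is a fixpoint", {
  cfg <- scan_config()
  at <- function(gap) merge_regions(
    data.frame(id = c("a", "b"), chrom = "1", pos = c(1e6, 1e6 + gap)), cfg)
  expect_identical(nrow(at(500000)), 1L)     # exactly 500 kb: merged
  expect_identical(nrow(at(500001)), 2L)     # one bp more: separate
  # fixpoint: re-merging region midpoints-as-loci of an already merged set
  set.seed(77)
  loci <- data.frame(id = paste0("x", 1:40),
                     chrom = sample(c("1", "2"), 40, TRUE),
                     pos = sample(1e7, 40))
  r <- merge_regions(loci, cfg)
  again <- merge_regions(
    data.frame(id = r$locus_ids, chrom = r$chrom,
               pos = r$start_bp), cfg)
  expect_identical(nrow(again), nrow(r))
  # regions partition the significant loci
  expect_identical(sort(unlist(strsplit(r$locus_ids, ","))), sort(loci$id))
  expect_equal(sum(r$n_snps), 40)
})

test_that("run_scan is invariant to sample and locus order", {
  cfg <- sim_config(n_loci = 300,
                    populations = data.frame(
                      name = c("F", "R1", "R2"),
                      altitude = c("high", "low", "low"),
                      n = 20, drift_F = 0.08),
                    n_chrom = 2, seed = 55)
  g <- simulate_panel(cfg)$matrix
  res <- suppressMessages(run_scan(g, "F", c("R1", "R2")))
  perm <- sample(nrow(g$dosage))
  gp <- genotype_matrix(g$dosage[perm, ], g$samples[perm, ], g$loci)
  resp <- suppressMessages(run_scan(gp, "F", c("R1", "R2")))
  expect_equal(res$scan$di, resp$scan$di, tolerance = 1e-12)
  expect_identical(res$regions, resp$regions)
  expect_error(run_scan(g, "F", character(0)), "non-empty")
})

test_that("run_scan applies the pooled-MAF floor before scanning", {
  g <- random_matrix(c("F", "R1"), 10, 30, seed = 16)
  g$dosage[, 5] <- 0L
  g$dosage[1, 5] <- 1L          # pooled MAF 1/40 = 0.025 < 0.05
  res <- suppressMessages(run_scan(g, "F", "R1"))
  expect_false(g$loci$id[5] %in% res$scan$id)
  expect_lt(res$n_loci_scanned, 30)
})

test_that("injected sweeps are recovered by the full scan", {
  # the panel must be large enough that the top-0.5% set can hold all ten
  # sweeps (k = floor-below 0.005 N >= 10 needs N > 2000 scanned loci)
  hits <- 0
  for (seed in 1:20) {
    cfg <- sim_config(
      n_loci = 5000,
      populations = data.frame(
        name = c("H1", "H2", "L1", "L2", "L3", "L4"),
        altitude = rep(c("high", "low"), c(2, 4)),
        n = 25, drift_F = 0.05),
      sweep_loci = data.frame(index = 1:10 * 450L, high_freq = 0.95,
                              ancestral = 0.1),
      n_chrom = 4, seed = seed)
    sim <- simulate_panel(cfg)
    res <- suppressMessages(run_scan(sim$matrix, "H1",
                                     c("L1", "L2", "L3", "L4")))
    found <- sum(sim$truth$locus_id %in%
                   res$scan$id[res$scan$significant])
    hits <- hits + found
  }
  expect_gte(hits / 20, 9)   # median >= 9 of 10 implied by a high mean
})
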