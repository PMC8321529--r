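test_that("sim_config validates its invariants", {
  expect_error(sim_config(fate_mix = c(conserved = 0.5, pseudogenized = 0.2,
                                       neofunctionalized = 0.2,
                                       subfunctionalized = 0.2)), "sum to 1")
  expect_error(sim_config(n_families = 0), "positive")
  expect_error(sim_config(psv_rate = 1), "psv_rate")
  expect_error(sim_config(duplicon_length = 50, read_length = 100),
               "exceed")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("fate-conditional structure holds exactly at noise 0", {
  cfg <- sim_config(n_families = 40, expression_noise_sd = 0, seed = 17)
  sim <- simulate_families(cfg)
  tmH <- dupfate:::tissue_means(sim$human)
  tmO <- dupfate:::tissue_means(sim$ortholog)
  fates <- sim$truth$fates
  for (i in seq_len(nrow(fates))) {
    fid <- fates$family[i]
    fam <- sim$families[sim$families$family == fid, ]
    anc <- fam$gene[fam$role == "ancestral"]
    ders <- fam$gene[fam$role == "derived"]
    o <- tmO[fam$gene[fam$role == "ortholog"], ]
    if (fates$fate[i] == "pseudogenized") {
      expect_true(all(tmH[ders, ] == 0))
      expect_equal(unname(tmH[anc, ]), unname(o))
    } else if (fates$fate[i] == "conserved" ||
               fates$fate[i] == "neofunctionalized") {
      expect_equal(cross_tissue_correlation(tmH[anc, ], o), 1)
    } else { # subfunctionalized: members sum exactly to the ortholog
      total <- colSums(tmH[c(anc, ders), , drop = FALSE])
      expect_equal(unname(total), unname(o), tolerance = 1e-9)
    }
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 23, n_families = 5, n_reads = 300,
                    genome_length = 1e6, n_sd = 5, sd_length = 1e4,
                    n_peaks = 200)
  expect_identical(simulate_families(cfg), simulate_families(cfg))
  expect_identical(simulate_duplicated_reads(cfg),
                   simulate_duplicated_reads(cfg))
  expect_identical(simulate_peak_landscape(cfg),
                   simulate_peak_landscape(cfg))
  expect_identical(simulate_cn(cfg, letters[1:4]),
                   simulate_cn(cfg, letters[1:4]))
  # stage streams are independent: changing read settings leaves the
  # expression world untouched
  cfg2 <- cfg; cfg2$n_reads <- 301L
  expect_identical(simulate_families(cfg), simulate_families(cfg2))
})

test_that("duplicated-read simulation matches its analytic structure", {
  # psv_rate 0: identical sequences, every read has two candidates
  r0 <- suppressWarnings(
    simulate_duplicated_reads(sim_config(seed = 2, psv_rate = 0,
                                         n_reads = 500)))
  expect_identical(r0$sequences[["locusA"]], r0$sequences[["locusB"]])
  expect_true(all(r0$truth$n_candidates == 2L))
  # a PSV density so high every read covers one leaves no multireads
  expect_warning(simulate_duplicated_reads(sim_config(seed = 2,
                                                      psv_rate = 0.5,
                                                      n_reads = 50)),
                 "no multi-mapping")

  # reads covering a PSV have exactly one candidate, and vice versa
  cfg <- sim_config(seed = 5, n_reads = 2000)
  rd <- simulate_duplicated_reads(cfg)
  rl <- cfg$read_length
  covers <- vapply(seq_len(nrow(rd$truth)), function(i)
    any(rd$psv_positions > rd$truth$pos[i] &
          rd$psv_positions <= rd$truth$pos[i] + rl), NA)
  expect_equal(rd$truth$n_candidates == 1L, covers)

  # unique fraction: exact conditional oracle given the realized PSVs
  L <- cfg$duplicon_length
  p_cond <- mean(vapply(0:(L - rl), function(s)
    any(rd$psv_positions > s & rd$psv_positions <= s + rl), NA))
  uf <- mean(rd$truth$n_candidates == 1L)
  expect_lt(abs(uf - p_cond), 3 * sqrt(p_cond * (1 - p_cond) / 2000))

  # ...and the marginal expectation 1 - (1 - rate)^len across seeds
  ufs <- vapply(1:20, function(s) {
    r <- simulate_duplicated_reads(sim_config(seed = s, n_reads = 1000))
    mean(r$truth$n_candidates == 1L)
  }, 0)
  analytic <- 1 - (1 - cfg$psv_rate)^rl
  expect_lt(abs(mean(ufs) - analytic), 3 * sd(ufs) / sqrt(length(ufs)))
})

test_that("PSV counts are Poisson-consistent with psv_rate x length", {
  lam <- 0.01 * 2000
  counts <- vapply(1:300, function(s) {
    cfg <- sim_config(seed = s, psv_rate = 0.01, duplicon_length = 2000,
                      read_length = 50, n_reads = 1)
    length(suppressWarnings(simulate_duplicated_reads(cfg))$psv_positions)
  }, 0L)
  # chi-square goodness of fit against Poisson(lambda), pooled tails
  brk <- qpois(c(0.05, 0.25, 0.5, 0.75, 0.95), lam)
  cuts <- c(-Inf, brk, Inf)
  obs <- table(cut(counts, cuts))
  expp <- diff(ppois(c(-Inf, brk, Inf), lam))
  chi <- sum((as.numeric(obs) - 300 * expp)^2 / (300 * expp))
  expect_lt(chi, qchisq(0.99, df = length(obs) - 1))
})

test_that("peak landscape respects bounds and depletion extremes", {
  land <- small_landscape()
  expect_true(all(land$sd_intervals$start >= 0))
  expect_true(all(land$sd_intervals$end <= land$genome$length))
  merged_sd <- merge_intervals(land$sd_intervals)
  expect_equal(nrow(merged_sd), nrow(land$sd_intervals)) # non-overlapping
  expect_true(all(land$peaks$end - land$peaks$start == 400L))
  l0 <- simulate_peak_landscape(sim_config(seed = 3, genome_length = 1e6,
                                           n_sd = 10, sd_length = 2e4,
                                           n_peaks = 500,
                                           depletion_factor = 0))
  expect_equal(fraction_covered(l0$sd_intervals, l0$peaks), 0)
  expect_error(simulate_peak_landscape(sim_config(genome_length = 1e5,
                                                  n_sd = 10,
                                                  sd_length = 5e4)),
               "too small")
})

test_that("CN genotypes are truncated-Gaussian around the configured mean", {
  cn <- simulate_cn(sim_config(seed = 9, cn_mean = 2, cn_sd = 0.5),
                    paste0("g", 1:40))
  expect_true(all(cn >= 0))
  expect_lt(abs(mean(cn) - 2), 3 * 0.5 / sqrt(length(cn)) + 0.01)
})
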