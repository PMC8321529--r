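iv <- function(chrom, start, end) data.frame(chrom = chrom, start = start,
                                             end = end)

test_that("merge_intervals merges overlaps and bookends, preserves bases", {
  expect_equal(merge_intervals(iv("c", c(0, 5), c(10, 15))),
               iv("c", 0, 15))
  expect_equal(merge_intervals(iv("c", c(0, 10), c(10, 20))),
               iv("c", 0, 20))
  disjoint <- iv("c", c(0, 100, 50), c(10, 120, 60))
  m <- merge_intervals(disjoint)
  expect_equal(nrow(m), 3)
  expect_equal(sum(m$end - m$start), sum(disjoint$end - disjoint$start))
  # different chromosomes never merge
  m2 <- merge_intervals(iv(c("a", "b"), c(0, 0), c(10, 10)))
  expect_equal(nrow(m2), 2)
  expect_error(merge_intervals(iv("c", 10, 5)), "invalid interval")
})

test_that("fraction_covered is exact interval arithmetic", {
  reg <- iv("c", 0, 100)
  expect_equal(fraction_covered(reg, iv("c", 50, 150)), 0.5)
  expect_equal(fraction_covered(reg, iv("c", 0, 200)), 1)
  expect_equal(fraction_covered(reg, iv("c", 500, 600)), 0)
  # invariant to fragmentation and order of inputs
  frag <- iv("c", c(70, 50), c(150, 75))
  expect_equal(fraction_covered(reg, frag),
               fraction_covered(reg, merge_intervals(frag)))
  reg_frag <- iv("c", c(50, 0, 25), c(100, 30, 60))
  expect_equal(fraction_covered(reg_frag, iv("c", 0, 100)), 1)
  expect_error(fraction_covered(reg[0, ], iv("c", 0, 1)), "empty")
})

test_that("prefix-sum coverage equals the interval-algebra path", {
  land <- small_landscape()
  pr <- dupfate:::peaks_prefix(land$peaks)
  # on region sets with no internal overlap the two routes agree exactly
  set.seed(14)
  for (i in 1:5) {
    starts <- sort(sample.int(9e5, 20)) + (0:19) * 2000 # disjoint by offset
    regs <- iv("chrS", starts, starts + 1500)
    fast <- sum(dupfate:::covered_upto(pr$chrS, regs$end) -
                  dupfate:::covered_upto(pr$chrS, regs$start)) /
      sum(regs$end - regs$start)
    expect_equal(fast, fraction_covered(regs, land$peaks), tolerance = 1e-12)
  }
})

test_that("permute_regions preserves lengths, bounds and determinism", {
  genome <- data.frame(chrom = c("c1", "c2"), length = c(1e5, 5e4))
  regs <- iv(c("c1", "c1", "c2"), c(0, 1000, 10), c(500, 3000, 5010))
  p1 <- permute_regions(regs, genome, 20, seed = 3)
  p2 <- permute_regions(regs, genome, 20, seed = 3)
  expect_identical(p1, p2)
  for (rep in p1) {
    expect_equal(rep$end - rep$start, regs$end - regs$start)
    expect_equal(rep$chrom, regs$chrom)
    expect_true(all(rep$start >= 0))
    expect_true(all(rep$end <= genome$length[match(rep$chrom, genome$chrom)]))
  }
  # a region as long as its chromosome has a single placement
  g1 <- data.frame(chrom = "c1", length = 100)
  pfull <- permute_regions(iv("c1", 0, 100), g1, 5, seed = 1)
  for (rep in pfull) expect_equal(rep, iv("c1", 0, 100))
  expect_error(permute_regions(iv("c1", 0, 200), g1, 2), "longer")
})

test_that("empirical_p implements (M+1)/(N+1) with its bounds", {
  expect_equal(empirical_p(0.01, rep(0.5, 1000))$empirical_p, 1 / 1001)
  expect_equal(round(empirical_p(0.01, rep(0.5, 1000))$empirical_p, 3), 0.001)
  expect_equal(empirical_p(0.9, rep(0.5, 7))$empirical_p, 1) # M = N
  nd <- empirical_p(0.5, c(rep(0.1, 4), rep(0.9, 5)))
  expect_equal(nd$M, 4)
  expect_equal(nd$empirical_p, 0.5)
  expect_error(empirical_p(0.5, numeric(0)), "empty")
  set.seed(15)
  for (i in 1:25) {
    nv <- runif(sample(1:50, 1))
    p <- empirical_p(runif(1), nv)$empirical_p
    expect_true(p >= 1 / (length(nv) + 1) && p <= 1)
  }
})

test_that("depletion_test: calibrated null at factor 1, detection at 0", {
  land <- small_landscape()
  dens <- local({
    m <- merge_intervals(land$peaks)
    sum(m$end - m$start) / land$genome$length
  })
  dep <- depletion_test(land$sd_intervals, land$peaks, land$genome,
                        n = 500, seed = 5)
  # null mean of the coverage fraction matches genome-wide peak density
  se <- sd(dep$null_values) / sqrt(length(dep$null_values))
  expect_lt(abs(mean(dep$null_values) - dens), 3 * se + 0.003)
  # factor-1 observed value sits inside the central 95% for most seeds
  inside <- vapply(1:8, function(s) {
    l <- simulate_peak_landscape(sim_config(seed = s, genome_length = 1e6,
                                            n_sd = 10L, sd_length = 2e4,
                                            n_peaks = 500L))
    d <- depletion_test(l$sd_intervals, l$peaks, l$genome, n = 200,
                        seed = 100 + s)
    q <- stats::quantile(d$null_values, c(0.025, 0.975))
    d$observed >= q[1] && d$observed <= q[2]
  }, NA)
  expect_gte(mean(inside), 6 / 8)

  # total depletion: zero covered bases in SDs, minimal p
  l0 <- simulate_peak_landscape(sim_config(seed = 4, genome_length = 1e6,
                                           n_sd = 10L, sd_length = 2e4,
                                           n_peaks = 500L,
                                           depletion_factor = 0))
  expect_equal(fraction_covered(l0$sd_intervals, l0$peaks), 0)
  d0 <- depletion_test(l0$sd_intervals, l0$peaks, l0$genome, n = 200,
                       seed = 6)
  expect_lte(d0$empirical_p, 5 / 201)
  # determinism of the test itself
  dA <- depletion_test(land$sd_intervals, land$peaks, land$genome,
                       n = 100, seed = 9)
  dB <- depletion_test(land$sd_intervals, land$peaks, land$genome,
                       n = 100, seed = 9)
  expect_identical(dA$null_values, dB$null_values)
})

test_that("filter_hsd applies the strict identity threshold then merges", {
  tab <- data.frame(chrom = c("c1", "c1", "c1", "c2"),
                    chromStart = c(0, 50, 300, 0),
                    chromEnd = c(100, 150, 400, 50),
                    fracMatch = c(0.97, 0.985, 0.999, 0.98))
  out <- filter_hsd(tab)
  expect_equal(out, iv("c1", c(50, 300), c(150, 400)))
  # exactly at the threshold is dropped (strict >)
  expect_equal(nrow(filter_hsd(data.frame(chrom = "c", chromStart = 0,
                                          chromEnd = 10, fracMatch = 0.98))),
               0)
  expect_equal(nrow(filter_hsd(tab, threshold = 0.999)), 0)
  expect_error(filter_hsd(data.frame(chrom = "c", chromStart = 0,
                                     chromEnd = 1)), "fracMatch")
  expect_error(filter_hsd(data.frame(chrom = "c", chromStart = 0,
                                     chromEnd = 1, fracMatch = 1.2)), "0, 1")
})
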