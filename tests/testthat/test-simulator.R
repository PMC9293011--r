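test_that("panel construction is deterministic and validates fst", {
  p1 <- make_source_panels(500, 20, 0.15, c(0.5, 0.5), seed = 31)
  p2 <- make_source_panels(500, 20, 0.15, c(0.5, 0.5), seed = 31)
  expect_identical(p1[[1]]$haps, p2[[1]]$haps)
  expect_identical(p1[[2]]$haps, p2[[2]]$haps)
  expect_identical(p1[[1]]$snp, p2[[1]]$snp)
  expect_error(make_source_panels(100, 10, 0, c(1), seed = 1), "fst")
  expect_error(make_source_panels(100, 10, 1.2, c(1), seed = 1), "fst")
})

test_that("panel divergence matches the Hudson FST oracle", {
  p <- make_source_panels(10000, 60, 0.15, rep(1, 4), seed = 32)
  fst <- hudson_fst(p[[1]]$haps, p[[2]]$haps)
  expect_lt(abs(fst - 0.15), 0.03)
  # fst -> 0 limit: population frequencies become indistinguishable
  p0 <- make_source_panels(10000, 60, 0.002, rep(1, 4), seed = 33)
  expect_lt(mean(abs(p0[[1]]$pop_freq - p0[[2]]$pop_freq)),
            mean(abs(p[[1]]$pop_freq - p[[2]]$pop_freq)) / 3)
})

test_that("markers are partitioned by length and sorted within chromosomes", {
  p <- make_source_panels(999, 10, 0.1, c(2, 1), seed = 34)[[1]]
  tab <- table(p$snp$chrom)
  expect_equal(unname(tab["1"] / tab["2"]), 2, tolerance = 0.01)
  for (ch in unique(p$snp$chrom))
    expect_true(!is.unsorted(p$snp$gpos[p$snp$chrom == ch]))
})

test_that("alpha = 1 yields pure source1 mosaics", {
  p <- make_source_panels(800, 30, 0.2, c(0.7, 0.7), seed = 35)
  sim <- simulate_admixed(p[[1]], p[[2]], admixture_spec(1, 10, 3, seed = 36))
  expect_true(all(sim$truth$source == "source1"))
  expect_true(all(sim$genotypes$calls %in% 0:2))
})

test_that("simulation is deterministic given the seed", {
  p <- make_source_panels(600, 25, 0.2, c(0.6, 0.6), seed = 37)
  s1 <- simulate_admixed(p[[1]], p[[2]], admixture_spec(0.3, 8, 3, seed = 38))
  s2 <- simulate_admixed(p[[1]], p[[2]], admixture_spec(0.3, 8, 3, seed = 38))
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$truth, s2$truth)
})

test_that("truth tracks tile every haploid chromosome exactly", {
  p <- make_source_panels(1000, 40, 0.2, c(0.8, 0.5), seed = 39)
  sim <- simulate_admixed(p[[1]], p[[2]], admixture_spec(0.4, 20, 4, seed = 40))
  lens <- c("1" = 0.8, "2" = 0.5)
  for (h in unique(sim$truth$haploid)) {
    for (ch in c("1", "2")) {
      seg <- sim$truth[sim$truth$haploid == h & sim$truth$chrom == ch, ]
      expect_equal(seg$start[1], 0)
      expect_equal(seg$end[nrow(seg)], unname(lens[ch]))
      if (nrow(seg) > 1)
        expect_equal(seg$start[-1], seg$end[-nrow(seg)])
    }
  }
})

test_that("recombination count matches the analytic expectation at t = 1", {
  p <- make_source_panels(2000, 120, 0.2, 1.0, seed = 41)
  sim <- simulate_admixed(p[[1]], p[[2]], admixture_spec(0.5, 1, 25, seed = 42))
  gaps <- diff(p[[1]]$snp$gpos)
  expected <- sum(1 - exp(-2 * gaps))   # lambda_sim = t + 1 = 2
  nseg <- table(sim$truth$haploid)
  expect_equal(mean(nseg - 1), expected, tolerance = 0.35)
})

test_that("realized ancestry fractions obey the law of large numbers", {
  p <- make_source_panels(5000, c(60, 90), 0.2, rep(1.5, 6), seed = 43)
  sim <- simulate_admixed(p[[1]], p[[2]], admixture_spec(0.2, 15, 10, seed = 44))
  tr <- sim$truth
  frac <- sum((tr$end - tr$start)[tr$source == "source1"]) /
          sum(tr$end - tr$start)
  expect_lt(abs(frac - 0.2), 0.05)
})

test_that("mean ancestry tract length shrinks with admixture time", {
  p <- make_source_panels(4000, c(120, 260), 0.2, rep(1.5, 4), seed = 45)
  mean_len <- function(t, seed) {
    sim <- simulate_admixed(p[[1]], p[[2]],
                            admixture_spec(0.3, t, 5, seed = seed))
    mean(sim$truth$end - sim$truth$start)
  }
  expect_lt(mean_len(100, 46), mean_len(10, 47))
})

test_that("pool exhaustion and the 2n haplotype floor raise errors", {
  p <- make_source_panels(400, 6, 0.2, c(0.5), seed = 48)
  expect_error(simulate_admixed(p[[1]], p[[2]],
                                admixture_spec(0.5, 5, 3, seed = 49)),
               "more than 2n")
  p2 <- make_source_panels(3000, 8, 0.2, c(3), seed = 50)
  expect_error(simulate_admixed(p2[[1]], p2[[2]],
                                admixture_spec(0.5, 40, 3, seed = 51)),
               "pool exhausted|increase the panel size")
})

test_that("pseudo-haploidisation resolves heterozygotes fairly and nothing else", {
  # no heterozygotes: identity apart from the ploidy flag
  gm0 <- tiny_gm(rbind(c(0L, 2L, 9L)), gpos = c(0.1, 0.2, 0.3))
  ph0 <- pseudo_haploidize(gm0, seed = 52)
  expect_identical(unname(ph0$calls), unname(gm0$calls))
  expect_identical(ph0$ploidy, "pseudo_haploid")
  # all-heterozygote row splits about evenly
  gm1 <- tiny_gm(matrix(1L, 1, 10000), gpos = sort(runif(10000)))
  ph1 <- pseudo_haploidize(gm1, seed = 53)
  expect_true(all(ph1$calls %in% c(0L, 2L)))
  expect_lt(abs(mean(ph1$calls == 2L) - 0.5), 0.02)
  # deterministic given the seed
  ph2 <- pseudo_haploidize(gm1, seed = 53)
  expect_identical(ph1$calls, ph2$calls)
  expect_error(pseudo_haploidize(ph1, seed = 1), "diploid")
})

test_that("random masking hits the requested rate and only non-missing calls", {
  gm <- tiny_gm(matrix(rep(c(0L, 1L, 2L, 9L), 2500), 1), gpos = sort(runif(10000)))
  expect_identical(mask_missing(gm, 0, seed = 54), gm)
  mm <- mask_missing(gm, 0.6, seed = 55)
  was_missing <- gm$calls == 9L
  expect_true(all(mm$calls[was_missing] == 9L))
  new_rate <- mean(mm$calls[!was_missing] == 9L)
  expect_lt(abs(new_rate - 0.6), 0.02)
  expect_error(mask_missing(gm, 1, seed = 1), "rate")
})

test_that("multi-way admixture reduces and composes correctly", {
  p <- make_source_panels(1500, 40, 0.2, c(0.8, 0.8), seed = 56, n_sources = 3)
  ev1 <- admixture_spec(0.5, 30, 8, seed = 57)
  ev2 <- admixture_spec(0.6, 10, 3, seed = 58)
  # one event reduces to the two-way simulator
  one <- simulate_multiway(p[1:2], list(ev1))
  two <- simulate_admixed(p[[1]], p[[2]], ev1)
  expect_identical(one$genotypes$calls, two$genotypes$calls)
  # second pulse entirely from the third panel wipes earlier ancestry
  ev2_all3 <- admixture_spec(0, 10, 3, seed = 58)
  m <- simulate_multiway(p, list(ev1, ev2_all3))
  expect_true(all(m$truth$source == "source3"))
  # a genuine three-way mix carries all three labels
  m3 <- simulate_multiway(p, list(ev1, ev2))
  expect_setequal(unique(m3$truth$source), c("source1", "source2", "source3"))
})

test_that("admixture_spec validates its ranges and encodes lambda = t + 1", {
  sp <- admixture_spec(0.2, 50, 10, seed = 1)
  expect_identical(sp$lambda_sim, 51)
  expect_error(admixture_spec(0.2, 0, 10, seed = 1), "t must be")
  expect_error(admixture_spec(1.2, 10, 10, seed = 1), "alpha")
  expect_error(admixture_spec(0.2, 10, 0, seed = 1), "n_individuals")
})

test_that("truth tracks serialise as labelled genetic-coordinate text", {
  p <- make_source_panels(300, 20, 0.2, c(0.4), seed = 59)
  sim <- simulate_admixed(p[[1]], p[[2]], admixture_spec(0.5, 5, 2, seed = 60))
  f <- tempfile(fileext = ".txt")
  write_truth_track(sim$truth, f)
  lines <- readLines(f)
  expect_match(lines[1], "GENETIC")
  body <- utils::read.table(f, comment.char = "#")
  expect_equal(nrow(body), nrow(sim$truth))
  expect_equal(body[[2]], sim$truth$start * 100, tolerance = 1e-5)
})
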