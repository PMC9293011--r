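test_that("a toy triplet is transcribed into an individuals x markers table", {
  pre <- toy_eigenstrat()
  gm <- read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                        paste0(pre, ".ind"))
  # .geno rows "29" and "01" are markers; individual 1 reads (2, 0)
  expect_identical(unname(gm$calls), rbind(c(2L, 0L), c(9L, 1L)))
  expect_identical(gm$snp$snp_id, c("rs1", "rs2"))
  expect_identical(gm$snp$gpos, c(0.01, 0.02))
  expect_identical(gm$ind$group, c("pop1", "pop2"))
})

test_that("read/write round trips are the identity", {
  pre <- toy_eigenstrat()
  gm <- read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                        paste0(pre, ".ind"))
  out1 <- tempfile("rt1")
  write_eigenstrat(gm, out1)
  gm2 <- read_eigenstrat(paste0(out1, ".geno"), paste0(out1, ".snp"),
                         paste0(out1, ".ind"))
  expect_identical(gm2$calls, gm$calls)
  expect_equal(gm2$snp, gm$snp)
  expect_identical(gm2$ind, gm$ind)
  # canonical files (our own output) reproduce byte-identically
  out2 <- tempfile("rt2")
  write_eigenstrat(gm2, out2)
  for (ext in c(".geno", ".snp", ".ind"))
    expect_identical(readLines(paste0(out2, ext)),
                     readLines(paste0(out1, ext)))
})

test_that("simulator output survives a 1000-marker round trip", {
  panels <- make_source_panels(1000, c(12, 12), 0.15, c(0.5, 0.5), seed = 5)
  sim <- simulate_admixed(panels[[1]], panels[[2]],
                          admixture_spec(0.3, 5, 4, seed = 6))
  pre <- tempfile("simrt")
  write_eigenstrat(sim$genotypes, pre)
  back <- read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                          paste0(pre, ".ind"))
  expect_identical(back$calls, sim$genotypes$calls)
  expect_equal(back$snp$gpos, sim$genotypes$snp$gpos, tolerance = 1e-9)
})

test_that("structural violations raise parse errors naming the spot", {
  pre <- toy_eigenstrat(geno = c("291", "011"))  # width 3, 2 individuals
  expect_error(read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                               paste0(pre, ".ind")),
               "width 3.*2 individuals")
  pre <- toy_eigenstrat(geno = c("29", "01", "11"))  # 3 rows, 2 snps
  expect_error(read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                               paste0(pre, ".ind")),
               "3 marker rows.*2 rows")
  pre <- toy_eigenstrat(geno = c("29", "0x"))
  expect_error(read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                               paste0(pre, ".ind")),
               "invalid genotype character 'x'.*row 2")
})

test_that("reading ignores trailing whitespace and missing final newline", {
  pre <- toy_eigenstrat()
  ref <- read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                         paste0(pre, ".ind"))
  # trailing spaces / CR and no final newline
  cat("29 \t\n01", file = paste0(pre, ".geno"))
  cat("rs1 1 0.01 100 A G   \nrs2 1 0.02 200 C T", file = paste0(pre, ".snp"))
  messy <- read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                           paste0(pre, ".ind"))
  expect_identical(messy$calls, ref$calls)
  expect_equal(messy$snp, ref$snp)
})

test_that("markers unsorted within a chromosome are sorted with a warning", {
  pre <- toy_eigenstrat(geno = c("29", "01"),
                        snp = c("rs1 1 0.02 200 A G", "rs2 1 0.01 100 C T"))
  expect_warning(
    gm <- read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                          paste0(pre, ".ind")),
    "re-sorted")
  expect_identical(gm$snp$snp_id, c("rs2", "rs1"))
  expect_identical(unname(gm$calls[, 1]), c(0L, 1L))  # rs2 column first
  expect_true(all(diff(gm$snp$gpos) >= 0))
})

test_that("pseudo-haploid matrices refuse heterozygous calls", {
  expect_error(tiny_gm(c(0L, 1L), gpos = c(0.1, 0.2), ploidy = "pseudo_haploid"),
               "heterozygous")
  gm <- tiny_gm(c(0L, 2L), gpos = c(0.1, 0.2), ploidy = "pseudo_haploid")
  expect_s3_class(gm, "geno_matrix")
})

test_that("an empty matrix (0 individuals) round-trips with the snp table intact", {
  snp <- data.frame(snp_id = c("a", "b"), chrom = "1", gpos = c(0.1, 0.2),
                    ppos = 1:2, ref = "A", alt = "G")
  ind <- data.frame(ind_id = character(), sex = character(), group = character())
  gm <- geno_matrix(matrix(integer(), 0, 2), snp, ind)
  pre <- tempfile("empty")
  write_eigenstrat(gm, pre)
  back <- read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                          paste0(pre, ".ind"))
  expect_identical(nrow(back$ind), 0L)
  expect_identical(back$snp$snp_id, c("a", "b"))
})

test_that("allele frequencies follow the ploidy-aware counting rule", {
  # two diploids both homozygous alt: freq 1, 4 observed alleles
  gm <- tiny_gm(rbind(c(2L, 0L), c(2L, 9L)), gpos = c(0.1, 0.2))
  fp <- allele_frequencies(gm)
  expect_equal(fp$freq[1], 1.0)
  expect_equal(fp$count[1], 4L)
  expect_equal(fp$count[2], 2L)
  # pseudo-haploid {2, 9}: one observed allele, freq 1
  gp <- tiny_gm(rbind(c(2L, 0L), c(9L, 2L)), gpos = c(0.1, 0.2),
                ploidy = "pseudo_haploid")
  fph <- allele_frequencies(gp)
  expect_equal(fph$freq[1], 1.0)
  expect_equal(fph$count[1], 1L)
  # zero observations <=> unavailable
  gz <- tiny_gm(rbind(c(9L, 0L)), gpos = c(0.1, 0.2))
  fz <- allele_frequencies(gz)
  expect_false(fz$ok[1])
  expect_true(is.na(fz$freq[1]))
})

test_that("frequencies match a brute-force per-marker tally on random panels", {
  set.seed(42)
  for (ploidy in c("diploid", "pseudo_haploid")) {
    codes <- if (ploidy == "diploid") c(0L, 1L, 2L, 9L) else c(0L, 2L, 9L)
    calls <- matrix(sample(codes, 6 * 50, replace = TRUE), nrow = 6)
    gm <- tiny_gm(calls, gpos = sort(runif(50)), ploidy = ploidy)
    fp <- allele_frequencies(gm)
    per <- if (ploidy == "diploid") 2 else 1
    for (j in seq_len(50)) {
      g <- calls[, j][calls[, j] != 9L]
      cnt <- length(g) * per
      expect_equal(fp$count[j], cnt)
      if (cnt > 0)
        expect_equal(fp$freq[j], sum(g / 2 * per) / cnt)
    }
    expect_true(all(fp$freq[fp$ok] >= 0 & fp$freq[fp$ok] <= 1))
  }
})

test_that("individual subsetting resolves ids and groups, errors otherwise", {
  gm <- tiny_gm(rbind(c(0L, 2L), c(1L, 1L)), gpos = c(0.1, 0.2))
  gm$ind$group <- c("popA", "popB")
  expect_identical(subset_individuals(gm, "popA")$ind$ind_id, "i1")
  expect_identical(nrow(subset_individuals(gm, c("i1", "popB"))$ind), 2L)
  expect_error(subset_individuals(gm, "nope"), "no individual or group")
  expect_error(allele_frequencies(gm, "nope"), "no individual or group")
})

test_that("sampling ages come from the side table with zero default", {
  p <- tempfile()
  writeLines(c("i1 5000", "i2 0"), p)
  ages <- read_age_table(p)
  expect_equal(unname(ages["i1"]), 5000)
  writeLines("i1 -5", p)
  expect_error(read_age_table(p), "non-negative")
})
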