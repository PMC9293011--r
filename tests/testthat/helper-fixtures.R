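# Small in-code fixtures and independent oracles shared across test files.

# write a toy EIGENSTRAT triplet and return the path prefix
toy_eigenstrat <- function(geno = c("29", "01"),
                           snp = c("rs1 1 0.01 100 A G", "rs2 1 0.02 200 C T"),
                           ind = c("i1 M pop1", "i2 F pop2"),
                           prefix = tempfile("toy")) {
  writeLines(geno, paste0(prefix, ".geno"))
  writeLines(snp, paste0(prefix, ".snp"))
  writeLines(ind, paste0(prefix, ".ind"))
  prefix
}

# hand-built geno_matrix on one or more chromosomes
tiny_gm <- function(calls, gpos, chrom = rep("1", length(gpos)),
                    ploidy = "diploid") {
  calls <- matrix(as.integer(calls), ncol = length(gpos))
  snp <- data.frame(snp_id = paste0("s", seq_along(gpos)), chrom = chrom,
                    gpos = gpos, ppos = seq_along(gpos), ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  ind <- data.frame(ind_id = paste0("i", seq_len(nrow(calls))), sex = "U",
                    group = "g", stringsAsFactors = FALSE)
  geno_matrix(calls, snp, ind, ploidy)
}

# freq_panel built directly from a frequency vector (count 100 everywhere)
panel_from_freq <- function(freq, snp = NULL, count = 100L) {
  structure(list(freq = freq, count = rep(count, length(freq)),
                 ok = rep(TRUE, length(freq)), snp = snp, label = "toy",
                 n_ind = count / 2), class = "freq_panel")
}

# ancestry_track built directly from a K matrix (individuals x markers)
track_from_K <- function(K, gpos, chrom = rep("1", length(gpos)),
                         valid = NULL) {
  K <- matrix(K, ncol = length(gpos))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(K), ncol(K))
  kbar <- vapply(seq_len(nrow(K)), function(i) mean(K[i, valid[i, ]]),
                 numeric(1))
  snp <- data.frame(snp_id = paste0("s", seq_along(gpos)), chrom = chrom,
                    gpos = gpos, stringsAsFactors = FALSE)
  structure(list(K = K, valid = valid, kbar = kbar,
                 alpha = rep(0.5, nrow(K)), n_used = rowSums(valid),
                 snp = snp), class = "ancestry_track")
}

# Hudson's two-population FST estimator from haplotype panels
hudson_fst <- function(h1, h2) {
  p1 <- colMeans(h1); p2 <- colMeans(h2)
  n1 <- nrow(h1); n2 <- nrow(h2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# brute-force grid search oracle for the mixture fraction
grid_alpha <- function(dose, pa, pb, grid = seq(0, 1, by = 0.001)) {
  rss <- vapply(grid, function(a) sum((dose - (a * pa + (1 - a) * pb))^2),
                numeric(1))
  grid[which.min(rss)]
}

# simulation conditions used by the recovery experiments: 50,000 markers on
# 22 uniform chromosomes totalling 35 Morgans, alpha = 0.2, fst = 0.15,
# 10 diploid targets, 40 diploid reference individuals per side
recovery_run <- function(t, seed, n_ind = 10, alpha = 0.2,
                         degrade = "none", n_snps = 50000) {
  n_haps <- c(150, ceiling(80 + 1.9 * t))  # per-chromosome copying pools
  panels <- make_source_panels(n_snps, n_haps, fst = 0.15,
                               chrom_lengths = rep(35 / 22, 22), seed = seed)
  sim <- simulate_admixed(panels[[1]], panels[[2]],
                          admixture_spec(alpha, t, n_ind, seed = seed + 1L))
  gm <- sim$genotypes
  if (degrade == "pseudo_haploid") gm <- pseudo_haploidize(gm, seed + 4L)
  if (degrade == "miss30") gm <- mask_missing(gm, 0.3, seed + 5L)
  if (degrade == "miss60") gm <- mask_missing(gm, 0.6, seed + 5L)
  refA <- allele_frequencies(sample_panel_genotypes(panels[[1]], 40, seed = seed + 2L))
  refB <- allele_frequencies(sample_panel_genotypes(panels[[2]], 40, seed = seed + 3L))
  fit <- date_admixture(gm, refA, refB)
  list(fit = fit, sim = sim, est = fit$estimate, lambda = fit$fit$lambda)
}

# pure-source (unadmixed) target run for null calibration
null_run <- function(seed, n_ind = 10, n_snps = 50000) {
  panels <- make_source_panels(n_snps, c(150, 150), fst = 0.15,
                               chrom_lengths = rep(35 / 22, 22), seed = seed)
  sim <- simulate_admixed(panels[[1]], panels[[2]],
                          admixture_spec(1, 50, n_ind, seed = seed + 1L))
  refA <- allele_frequencies(sample_panel_genotypes(panels[[1]], 40, seed = seed + 2L))
  refB <- allele_frequencies(sample_panel_genotypes(panels[[2]], 40, seed = seed + 3L))
  date_admixture(sim$genotypes, refA, refB)
}
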