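#' Synthetic diverged source haplotype panels
#'
#' Draws ancestral allele frequencies uniform on \[0.05, 0.95\], then one
#' frequency per source population from the Balding-Nichols distribution
#' \eqn{\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)} with divergence parameter
#' \code{fst}, and samples haplotypes independently per marker given the
#' population frequency. Marker genetic positions are uniform per
#' chromosome. All panels share one marker table; the per-population
#' frequencies are kept on each panel so fresh reference individuals can be
#' drawn later (\code{\link{sample_panel_genotypes}}).
#'
#' @param n_snps total markers, split across chromosomes proportionally to
#'   length.
#' @param n_haps haplotypes per panel (recycled across panels). Simulating
#'   n admixed diploids needs more than 2n ancestral haplotypes; older
#'   admixture times need far more, since every recombination consumes a
#'   fresh haplotype from the per-chromosome pool.
#' @param fst divergence between each source and the shared ancestor,
#'   in (0, 1).
#' @param chrom_lengths chromosome lengths in Morgans.
#' @param seed RNG seed.
#' @param n_sources number of panels (default 2).
#' @return List of \code{source_panel} objects (haplotype matrix
#'   \code{haps}, marker table \code{snp}, population frequencies
#'   \code{pop_freq}, \code{label}).
#' @export
make_source_panels <- function(n_snps, n_haps, fst, chrom_lengths, seed,
                               n_sources = 2) {
  if (!(fst > 0 && fst < 1)) stop("fst must be in (0, 1)")
  stopifnot(n_snps >= n_sources, all(chrom_lengths > 0))
  set.seed(seed)
  n_haps <- rep_len(n_haps, n_sources)

  n_chr <- length(chrom_lengths)
  per <- floor(n_snps * chrom_lengths / sum(chrom_lengths))
  rem <- n_snps - sum(per)
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1L
  gpos <- unlist(lapply(seq_len(n_chr), function(ci)
    sort(stats::runif(per[ci], 0, chrom_lengths[ci]))))
  chrom <- rep(as.character(seq_len(n_chr)), per)
  snp <- data.frame(snp_id = paste0("snp", seq_len(n_snps)), chrom = chrom,
                    gpos = gpos, ppos = as.integer(round(gpos * 1e8)) + 1L,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)

  p0 <- stats::runif(n_snps, 0.05, 0.95)
  shape <- (1 - fst) / fst
  panels <- vector("list", n_sources)
  for (s in seq_len(n_sources)) {
    p <- stats::rbeta(n_snps, p0 * shape, (1 - p0) * shape)
    haps <- matrix(as.integer(stats::runif(n_haps[s] * n_snps) <
                                rep(p, each = n_haps[s])),
                   nrow = n_haps[s], ncol = n_snps)
    panels[[s]] <- structure(list(haps = haps, snp = snp, pop_freq = p,
                                  label = paste0("source", s),
                                  chrom_lengths = chrom_lengths),
                             class = "source_panel")
  }
  panels
}

#' @export
print.source_panel <- function(x, ...) {
  cat("source_panel '", x$label, "': ", nrow(x$haps), " haplotypes x ",
      ncol(x$haps), " markers on ", length(unique(x$snp$chrom)),
      " chromosomes\n", sep = "")
  invisible(x)
}

#' Fresh diploid genotypes from a source population
#'
#' Draws new individuals as binomial(2, p) calls from the panel's
#' population allele frequencies — a disjoint sample from the same
#' population, suitable as a dating reference that shares no haplotypes
#' with the simulated admixed targets.
#'
#' @param panel a \code{source_panel}.
#' @param n_ind individuals to draw.
#' @param seed RNG seed.
#' @param label group label (default the panel label).
#' @return A diploid \code{\link{geno_matrix}}.
#' @export
sample_panel_genotypes <- function(panel, n_ind, seed, label = panel$label) {
  stopifnot(inherits(panel, "source_panel"), n_ind >= 1)
  set.seed(seed)
  m <- length(panel$pop_freq)
  calls <- matrix(stats::rbinom(n_ind * m, 2, rep(panel$pop_freq, each = n_ind)),
                  nrow = n_ind, ncol = m)
  ind <- data.frame(ind_id = paste0(label, "_", seq_len(n_ind)), sex = "U",
                    group = label, stringsAsFactors = FALSE)
  geno_matrix(calls, panel$snp, ind, "diploid")
}

#' Parameters of one admixture pulse
#'
#' @param alpha fraction of ancestry drawn from the first source, in
#'   \[0, 1\] (boundary values give unadmixed mosaics).
#' @param t integer admixture time in generations, >= 1. Haplotype copying
#'   uses the decay rate \code{lambda_sim = t + 1}: in the first generation
#'   after mixing each offspring carries one intact chromosome per
#'   ancestry, so tracts only begin to break up from the next generation.
#' @param n_individuals diploid individuals to construct.
#' @param seed RNG seed.
#' @export
admixture_spec <- function(alpha, t, n_individuals, seed) {
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must be in [0, 1]")
  if (!(is.numeric(t) && t >= 1 && t == round(t))) stop("t must be an integer >= 1")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  structure(list(alpha = alpha, t = as.integer(t), lambda_sim = t + 1,
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed)),
            class = "admixture_spec")
}

# one haploid chromosome: ancestry/haplotype mosaic over the markers of one
# chromosome; pools drawn without replacement, replenished per chromosome
.copy_haploid_chrom <- function(pos, cols, chrom_len, sources, alpha, lambda) {
  m <- length(pos)
  rec <- if (m > 1) stats::runif(m - 1) < (1 - exp(-lambda * diff(pos))) else logical(0)
  seg <- cumsum(c(TRUE, rec))          # segment id per marker
  nseg <- seg[m]
  anc <- ifelse(stats::runif(nseg) < alpha, 1L, 2L)
  hap <- integer(nseg)
  for (s in seq_along(sources)) {
    k <- which(anc == s)
    if (!length(k)) next
    n_avail <- nrow(sources[[s]]$haps)
    if (length(k) > n_avail)
      stop("haplotype pool exhausted for ", sources[[s]]$label, " (need ",
           length(k), " of ", n_avail, " per chromosome): increase the ",
           "panel size (n_haps)")
    hap[k] <- sample.int(n_avail, length(k))
  }
  alleles <- integer(m)
  for (s in seq_along(sources)) {
    sel <- anc[seg] == s
    if (!any(sel)) next
    alleles[sel] <- sources[[s]]$haps[cbind(hap[seg[sel]], cols[sel])]
  }
  first_marker <- which(!duplicated(seg))
  starts <- c(0, pos[first_marker[-1]])
  list(alleles = alleles,
       track = data.frame(start = starts,
                          end = c(starts[-1], chrom_len),
                          source = vapply(anc, function(a) sources[[a]]$label,
                                          character(1)),
                          hap = hap))
}

# build 2n haploid genomes by the copying algorithm; returns haplotype
# matrix (2n x markers) plus per-haploid truth tracks
.copy_haploids <- function(p1, p2, alpha, lambda, n_haploid) {
  snp <- p1$snp
  chroms <- unique(snp$chrom)
  lens <- p1$chrom_lengths
  if (is.null(lens)) lens <- tapply(snp$gpos, snp$chrom, max)[chroms]
  haps <- matrix(0L, n_haploid, nrow(snp))
  tracks <- vector("list", n_haploid * length(chroms))
  ti <- 0L
  for (h in seq_len(n_haploid)) {
    for (ci in seq_along(chroms)) {
      idx <- which(snp$chrom == chroms[ci])
      res <- .copy_haploid_chrom(snp$gpos[idx], idx, lens[[ci]], list(p1, p2),
                                 alpha, lambda)
      haps[h, idx] <- res$alleles
      ti <- ti + 1L
      tracks[[ti]] <- cbind(data.frame(haploid = h, chrom = chroms[ci]),
                            res$track)
    }
  }
  list(haps = haps, track = do.call(rbind, tracks))
}

#' Simulate admixed diploid genomes by haplotype copying
#'
#' Walks each chromosome marker by marker: the first segment's source is
#' Bernoulli(alpha) between the two panels; between neighbouring markers a
#' recombination occurs with probability \eqn{1 - e^{-(t+1)g}} for gap g
#' Morgans, upon which the ancestry is re-drawn (possibly landing on the
#' same source) and a fresh haplotype is taken from the chosen source's
#' per-chromosome pool without replacement; otherwise the current haplotype
#' keeps being copied. The 2n simulated haploid genomes are paired at
#' random into n diploids. Ground-truth ancestry segments are returned for
#' every haploid chromosome.
#'
#' @param p1,p2 \code{source_panel} objects on the same markers.
#' @param spec an \code{\link{admixture_spec}}.
#' @return List: \code{genotypes} (diploid \code{\link{geno_matrix}}),
#'   \code{truth} (segment table: haploid, chrom, start/end in Morgans,
#'   source label), \code{spec}.
#' @export
simulate_admixed <- function(p1, p2, spec) {
  stopifnot(inherits(p1, "source_panel"), inherits(p2, "source_panel"),
            inherits(spec, "admixture_spec"))
  if (!identical(p1$snp$snp_id, p2$snp$snp_id))
    stop("source panels must share one marker table")
  n <- spec$n_individuals
  if (min(nrow(p1$haps), nrow(p2$haps)) <= 2 * n)
    stop("need more than 2n ancestral haplotypes per source for n diploids")
  set.seed(spec$seed)
  hp <- .copy_haploids(p1, p2, spec$alpha, spec$lambda_sim, 2L * n)
  pairing <- matrix(sample.int(2L * n), nrow = 2)
  calls <- hp$haps[pairing[1, ], , drop = FALSE] +
           hp$haps[pairing[2, ], , drop = FALSE]
  ind <- data.frame(ind_id = paste0("adm", seq_len(n)), sex = "U",
                    group = "admixed", stringsAsFactors = FALSE)
  truth <- hp$track
  hap_to_dip <- integer(2L * n)
  hap_to_dip[pairing[1, ]] <- seq_len(n)
  hap_to_dip[pairing[2, ]] <- seq_len(n)
  truth$diploid <- paste0("adm", hap_to_dip[truth$haploid])
  list(genotypes = geno_matrix(calls, p1$snp, ind, "diploid"),
       truth = truth, spec = spec)
}

#' Iterated multi-way admixture
#'
#' Repeats the haplotype-copying construction for more than two sources:
#' the pulses are applied oldest first, the admixed haplotype pool produced
#' by one pulse acting as the first source of the next, so the final
#' genomes carry tracts of all ancestries. For pulse k, \code{alpha} is the
#' fraction drawn from the existing (older) pool and \code{1 - alpha} the
#' fraction from the newly arriving panel.
#'
#' @param panels list of \code{source_panel}s; pulse k mixes the running
#'   pool (seeded by \code{panels[[1]]} and \code{panels[[2]]}) with
#'   \code{panels[[k + 1]]}.
#' @param events list of \code{\link{admixture_spec}}s ordered oldest
#'   first; intermediate events' \code{n_individuals} sets the size of the
#'   intermediate haploid pool (2n haploids).
#' @return As \code{\link{simulate_admixed}}; truth tracks carry one label
#'   per original panel.
#' @export
simulate_multiway <- function(panels, events) {
  stopifnot(length(panels) >= 2, length(events) >= 1,
            length(panels) == length(events) + 1)
  if (length(events) == 1)
    return(simulate_admixed(panels[[1]], panels[[2]], events[[1]]))
  ev <- events[[1]]
  set.seed(ev$seed)
  pool_n <- 2L * ev$n_individuals
  if (min(nrow(panels[[1]]$haps), nrow(panels[[2]]$haps)) <= pool_n)
    stop("need more than 2n ancestral haplotypes per source for n diploids")
  hp <- .copy_haploids(panels[[1]], panels[[2]], ev$alpha, ev$lambda_sim, pool_n)
  # the intermediate pool becomes a source panel whose "label" is resolved
  # per marker through its own truth track at copy time
  inter <- structure(list(haps = hp$haps, snp = panels[[1]]$snp,
                          pop_freq = colMeans(hp$haps),
                          label = "admixed_pool",
                          chrom_lengths = panels[[1]]$chrom_lengths,
                          track = hp$track),
                     class = "source_panel")
  rest <- c(list(inter), panels[-(1:2)])
  out <- simulate_multiway_pools(rest, events[-1])
  out
}

# internal recursion once the first pulse has produced a pool
simulate_multiway_pools <- function(panels, events) {
  ev <- events[[1]]
  if (length(events) == 1) {
    sim <- simulate_admixed(panels[[1]], panels[[2]], ev)
    sim$truth <- .resolve_pool_labels(sim$truth, panels[[1]])
    return(sim)
  }
  set.seed(ev$seed)
  pool_n <- 2L * ev$n_individuals
  hp <- .copy_haploids(panels[[1]], panels[[2]], ev$alpha, ev$lambda_sim, pool_n)
  track <- .resolve_pool_labels(hp$track, panels[[1]])
  inter <- structure(list(haps = hp$haps, snp = panels[[1]]$snp,
                          pop_freq = colMeans(hp$haps),
                          label = "admixed_pool",
                          chrom_lengths = panels[[1]]$chrom_lengths,
                          track = track),
                     class = "source_panel")
  simulate_multiway_pools(c(list(inter), panels[-(1:2)]), events[-1])
}

# segments copied from an intermediate admixed pool inherit the labels of
# the specific pool haplotype they copied, majority-resolved over the
# copied interval
.resolve_pool_labels <- function(track, pool) {
  if (is.null(pool$track)) return(track)
  pooled <- track$source == pool$label
  if (!any(pooled)) return(track)
  pt <- pool$track
  for (r in which(pooled)) {
    seg <- pt[pt$chrom == track$chrom[r] & pt$haploid == track$hap[r], ]
    ov <- pmin(seg$end, track$end[r]) - pmax(seg$start, track$start[r])
    ov[ov < 0] <- 0
    by_lab <- tapply(ov, seg$source, sum)
    track$source[r] <- names(by_lab)[which.max(by_lab)]
  }
  track
}

#' Pseudo-haploidise diploid genotypes
#'
#' Replaces every heterozygous call by a randomly sampled allele reported
#' as homozygous (0 or 2 with probability one half each), the standard
#' degradation of low-coverage ancient-DNA genotype calls. Homozygous and
#' missing calls are unchanged.
#'
#' @param gm diploid \code{\link{geno_matrix}}.
#' @param seed RNG seed.
#' @return A \code{geno_matrix} with \code{ploidy = "pseudo_haploid"}.
#' @export
pseudo_haploidize <- function(gm, seed) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$ploidy != "diploid") stop("input must be diploid")
  set.seed(seed)
  calls <- gm$calls
  het <- which(calls == 1L)
  calls[het] <- 2L * stats::rbinom(length(het), 1, 0.5)
  geno_matrix(calls, gm$snp, gm$ind, "pseudo_haploid")
}

#' Mask genotype calls at random
#'
#' Sets each non-missing call to missing (9) independently with the given
#' probability, emulating the uneven coverage of ancient genomes.
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param rate missingness probability in \[0, 1).
#' @param seed RNG seed.
#' @export
mask_missing <- function(gm, rate, seed) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!(rate >= 0 && rate < 1)) stop("rate must be in [0, 1)")
  if (rate == 0) return(gm)
  set.seed(seed)
  calls <- gm$calls
  nm <- which(calls != 9L)
  hit <- nm[stats::runif(length(nm)) < rate]
  calls[hit] <- 9L
  geno_matrix(calls, gm$snp, gm$ind, gm$ploidy)
}

#' Write ground-truth ancestry segments as BED-like text
#'
#' Columns: chrom, start_cM, end_cM, source label, haploid id. Coordinates
#' are genetic (cM), not physical base pairs.
#'
#' @param truth segment table from \code{\link{simulate_admixed}}.
#' @param path output file.
#' @export
write_truth_track <- function(truth, path) {
  con <- file(path, "w")
  writeLines(c("# ancestry truth track; coordinates are GENETIC (cM), not bp",
               "# chrom\tstart_cM\tend_cM\tsource\thaploid"), con)
  writeLines(sprintf("%s\t%.6f\t%.6f\t%s\t%d", truth$chrom,
                     truth$start * 100, truth$end * 100, truth$source,
                     truth$haploid), con)
  close(con)
  invisible(path)
}
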