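# Frequency clamp applied before any likelihood computation; avoids
# division by zero at markers monomorphic in a reference panel.
.FREQ_EPS <- 1e-4

.clamp_freq <- function(p) pmin(pmax(p, .FREQ_EPS), 1 - .FREQ_EPS)

#' Estimate the ancestry fraction of one genome by least squares
#'
#' Models the genotype dosage g/2 of an admixed genome as a linear mix
#' \eqn{\alpha p_A + (1-\alpha) p_B} of the two reference allele frequencies
#' and solves the simple linear regression minimising the residual sum of
#' squares. Markers where the target call is missing or either panel is
#' unavailable are excluded; markers with \eqn{p_A = p_B} carry no slope
#' information and are retained. The estimate is clamped to
#' \[1e-4, 1 - 1e-4\].
#'
#' @param g integer genotype vector (codes 0/1/2, 9 missing) for one
#'   individual. Pseudo-haploid 0/2 calls are valid input: dosage 0 or 1.
#' @param ref_a,ref_b \code{freq_panel} objects on the same markers.
#' @param min_markers minimum usable markers (default 100).
#' @param ploidy ploidy of the target calls.
#' @return List with \code{alpha}, \code{beta = 1 - alpha} and
#'   \code{n_markers_used}.
#' @export
estimate_mixture <- function(g, ref_a, ref_b, min_markers = 100,
                             ploidy = c("diploid", "pseudo_haploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(inherits(ref_a, "freq_panel"), inherits(ref_b, "freq_panel"))
  if (length(g) != length(ref_a$freq) || length(g) != length(ref_b$freq))
    stop("genotype vector and panels have different marker counts")
  use <- g != 9L & ref_a$ok & ref_b$ok
  n <- sum(use)
  if (n < min_markers)
    stop("estimate_mixture: only ", n, " usable markers (need >= ", min_markers, ")")
  dose <- g[use] / 2
  pa <- ref_a$freq[use]
  pb <- ref_b$freq[use]
  dd <- pa - pb
  den <- sum(dd^2)
  if (den == 0)
    stop("references indistinguishable: p_A = p_B at every usable marker")
  alpha <- sum((dose - pb) * dd) / den
  alpha <- min(max(alpha, 1e-4), 1 - 1e-4)
  list(alpha = alpha, beta = 1 - alpha, n_markers_used = n)
}

#' Per-site genotype probabilities under each reference
#'
#' For a diploid call the genotype is two Bernoulli draws from the panel
#' frequency, \eqn{a = \binom{2}{g} p^g (1-p)^{2-g}}; for a pseudo-haploid
#' call (one sampled allele reported as homozygous) it is a single draw,
#' \eqn{a = p} for code 2 and \eqn{1-p} for code 0. Frequencies are clamped
#' to \[1e-4, 1-1e-4\] first. Missing calls (9) yield NA, marking the site
#' invalid rather than raising an error.
#'
#' @param g genotype codes.
#' @param p panel allele frequency (recycled against \code{g}).
#' @param ploidy call type.
#' @return Numeric vector of probabilities (NA at missing sites).
#' @export
site_probabilities <- function(g, p, ploidy = c("diploid", "pseudo_haploid")) {
  ploidy <- match.arg(ploidy)
  p <- .clamp_freq(p)
  if (ploidy == "diploid") {
    out <- stats::dbinom(ifelse(g == 9L, NA_integer_, g), 2, p)
  } else {
    out <- ifelse(g == 2L, p, ifelse(g == 0L, 1 - p, NA_real_))
  }
  out[g == 9L] <- NA_real_
  out
}

#' Ancestry-informative site weights for admixed genomes
#'
#' For each individual and marker computes the likelihood
#' \eqn{L_i = \alpha a_i + \beta b_i} of the observed genotype under the
#' mixture and the weight \eqn{K_i = (a_i - b_i)/L_i}, whose sign says which
#' reference better explains the call. The genome-wide mean \eqn{\bar K} per
#' individual is recorded for centering the covariance. A marker is invalid
#' for an individual when the call is missing, either panel is unavailable,
#' or both panel frequencies sit beyond the same clamp boundary (no
#' information survives the clamp).
#'
#' @param gm target \code{\link{geno_matrix}}.
#' @param ref_a,ref_b \code{freq_panel}s on the same markers.
#' @param alpha optional fixed ancestry fraction(s), recycled across
#'   individuals; default estimates \eqn{\alpha} per individual by
#'   \code{\link{estimate_mixture}}.
#' @return Object of class \code{ancestry_track}: \code{K} and \code{valid}
#'   matrices (individuals x markers), per-individual \code{kbar},
#'   \code{alpha} and usable marker counts.
#' @export
ancestry_weights <- function(gm, ref_a, ref_b, alpha = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  n_ind <- nrow(gm$ind)
  n_snp <- nrow(gm$snp)
  if (length(ref_a$freq) != n_snp || length(ref_b$freq) != n_snp)
    stop("panel marker count does not match genotype matrix")
  if (is.null(alpha)) {
    alphas <- vapply(seq_len(n_ind), function(i)
      estimate_mixture(gm$calls[i, ], ref_a, ref_b, ploidy = gm$ploidy)$alpha,
      numeric(1))
  } else {
    alphas <- rep_len(alpha, n_ind)
    if (any(alphas <= 0 | alphas >= 1)) {
      alphas <- pmin(pmax(alphas, 1e-4), 1 - 1e-4)
    }
  }
  # both frequencies clamped onto the same boundary: K would be an artefact
  same_clamp <- (ref_a$freq < .FREQ_EPS & ref_b$freq < .FREQ_EPS) |
                (ref_a$freq > 1 - .FREQ_EPS & ref_b$freq > 1 - .FREQ_EPS)
  same_clamp[is.na(same_clamp)] <- FALSE
  panel_ok <- ref_a$ok & ref_b$ok & !same_clamp

  K <- matrix(NA_real_, n_ind, n_snp, dimnames = dimnames(gm$calls))
  valid <- matrix(FALSE, n_ind, n_snp)
  for (i in seq_len(n_ind)) {
    g <- gm$calls[i, ]
    a <- site_probabilities(g, ref_a$freq, gm$ploidy)
    b <- site_probabilities(g, ref_b$freq, gm$ploidy)
    L <- alphas[i] * a + (1 - alphas[i]) * b
    v <- panel_ok & !is.na(a) & !is.na(b) & L > 0
    K[i, v] <- (a[v] - b[v]) / L[v]
    valid[i, ] <- v
  }
  kbar <- vapply(seq_len(n_ind), function(i) mean(K[i, valid[i, ]]), numeric(1))
  structure(list(K = K, valid = valid, kbar = kbar, alpha = alphas,
                 n_used = rowSums(valid), snp = gm$snp),
            class = "ancestry_track")
}

#' @export
print.ancestry_track <- function(x, ...) {
  cat("ancestry_track:", nrow(x$K), "individuals,", ncol(x$K), "markers\n")
  cat("  alpha:", paste(format(x$alpha, digits = 3), collapse = " "), "\n")
  cat("  valid markers per individual:",
      paste(x$n_used, collapse = " "), "\n")
  invisible(x)
}
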