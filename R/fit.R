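#' Fit an exponential decay with affine term to a covariance curve
#'
#' Fits \eqn{y = A e^{-\lambda d} + c} by unweighted least squares over the
#' populated bin midpoints inside \[lo, hi\]. The decay rate is profiled:
#' for each \eqn{\lambda} on a deterministic multiplicative grid (0.5 to 500
#' generations, step 1.02) the amplitude and affine term have a closed-form
#' solution; the grid optimum is then refined by golden-section search on
#' \eqn{\log\lambda}. Ties break toward the smaller rate. The admixture
#' time is \eqn{t = \lambda - 1} generations: mosaic chromosomes only start
#' forming one generation after the mixture, so the covariance decays at
#' rate t + 1.
#'
#' @param curve a \code{cov_curve}, or a data.frame with columns \code{mid},
#'   \code{A}, \code{count}.
#' @param lo,hi fit range in Morgans (defaults 0.0045 and 1.0).
#' @param min_bins minimum populated bins required (default 10).
#' @param lambda_range search range for the decay rate, generations.
#' @return Object of class \code{exp_fit} with \code{amplitude},
#'   \code{lambda}, \code{c}, \code{t = lambda - 1}, fitted values,
#'   residuals, the bins used and a \code{boundary} flag set when the
#'   optimum sits at the edge of the search range.
#' @export
fit_exp_decay <- function(curve, lo = 0.0045, hi = 1.0, min_bins = 10,
                          lambda_range = c(0.5, 500)) {
  bins <- if (inherits(curve, "cov_curve")) curve$bins else curve
  use <- bins$count > 0 & is.finite(bins$A) & bins$mid >= lo & bins$mid <= hi
  if (sum(use) < min_bins)
    stop("fit_exp_decay: only ", sum(use), " populated bins in [",
         lo, ", ", hi, "] Morgans (need >= ", min_bins, ")")
  d <- bins$mid[use]
  y <- bins$A[use]

  rss_at <- function(lam) .profile_affine(d, y, lam)$rss
  grid <- lambda_range[1] * 1.02^(0:ceiling(log(lambda_range[2] / lambda_range[1]) / log(1.02)))
  grid <- grid[grid <= lambda_range[2] * 1.02]
  rss <- vapply(grid, rss_at, numeric(1))
  k <- which.min(rss)   # first minimum = smaller lambda on ties
  boundary <- k == 1L || k == length(grid)
  loglam <- log(grid[max(k - 1L, 1L)])
  loghi <- log(grid[min(k + 1L, length(grid))])
  lam <- exp(.golden(function(l) rss_at(exp(l)), loglam, loghi, tol = 1e-7))
  sol <- .profile_affine(d, y, lam)

  structure(list(amplitude = sol$A, lambda = lam, c = sol$c, t = lam - 1,
                 lo = lo, hi = hi, d = d, y = y,
                 fitted = sol$A * exp(-lam * d) + sol$c,
                 rss = sol$rss, boundary = boundary,
                 n_bins = length(d)),
            class = "exp_fit")
}

# closed-form (A, c) for fixed lambda: simple regression of y on exp(-lambda d)
.profile_affine <- function(d, y, lam) {
  x <- exp(-lam * d)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx < .Machine$double.eps) {
    A <- 0; c0 <- mean(y)
  } else {
    A <- stats::cov(x, y) / vx
    c0 <- mean(y) - A * mean(x)
  }
  r <- y - (A * x + c0)
  list(A = A, c = c0, rss = sum(r^2))
}

.golden <- function(f, a, b, tol = 1e-7) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f(x2) }
  }
  (a + b) / 2
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("exponential + affine fit over [", x$lo * 100, ",", x$hi * 100,
      "] cM, ", x$n_bins, " bins\n", sep = "")
  cat(sprintf("  A = %.4g, lambda = %.4g, c = %.4g  =>  t = %.2f generations\n",
              x$amplitude, x$lambda, x$c, x$t))
  if (x$boundary) cat("  WARNING: optimum at search boundary\n")
  invisible(x)
}

#' Normalised root-mean-square deviation of a fitted curve
#'
#' \eqn{\mathrm{NRMSD} = \sqrt{\sum (z - \hat z)^2 / N} / (\max\hat z -
#' \min\hat z)}, computed over the fitted bins. Values below 0.7 indicate a
#' clean decay in practice; the ratio is invariant to rescaling both curves.
#'
#' @param z empirical bin values.
#' @param zhat fitted bin values of the same length.
#' @return Non-negative scalar.
#' @export
nrmsd <- function(z, zhat) {
  if (length(z) != length(zhat) || length(z) < 2)
    stop("nrmsd: z and zhat must have equal length >= 2")
  rng <- max(zhat) - min(zhat)
  if (rng <= 0) stop("nrmsd: degenerate fit range (flat fitted curve)")
  sqrt(mean((z - zhat)^2)) / rng
}

#' Weighted leave-one-chromosome-out jackknife for the admixture date
#'
#' Refits the decay after deleting each chromosome's partial sums in turn
#' and combines the delete-one estimates with the weighted delete-one
#' jackknife (Busing et al. 1999), block weights proportional to the number
#' of marker pairs each chromosome contributes inside the fit range.
#' Chromosomes whose delete-one fit fails are dropped with a warning.
#'
#' @param curve a \code{cov_curve} carrying per-chromosome partials.
#' @param lo,hi,min_bins,lambda_range passed to \code{\link{fit_exp_decay}}.
#' @param full optional precomputed full-data fit.
#' @return List with \code{t_mean}, \code{se}, \code{z = t_mean/se} and a
#'   per-block table of delete-one estimates and weights.
#' @export
jackknife_date <- function(curve, lo = 0.0045, hi = 1.0, min_bins = 10,
                           lambda_range = c(0.5, 500), full = NULL) {
  stopifnot(inherits(curve, "cov_curve"))
  if (is.null(full)) full <- fit_exp_decay(curve, lo, hi, min_bins, lambda_range)
  chroms <- curve$chroms
  in_range_bins <- which((seq_len(curve$nbins) - 0.5) * curve$binsize >= lo &
                         (seq_len(curve$nbins) - 0.5) * curve$binsize <= hi)
  w <- vapply(seq_along(chroms), function(ci)
    sum(curve$N[in_range_bins, ci, ]), numeric(1))

  t_del <- rep(NA_real_, length(chroms))
  for (ci in seq_along(chroms)) {
    if (w[ci] == 0) next
    bins_del <- pool_curve(curve, drop_chrom = chroms[ci])
    t_del[ci] <- tryCatch(
      fit_exp_decay(bins_del, lo, hi, min_bins, lambda_range)$t,
      error = function(e) NA_real_)
  }
  usable <- is.finite(t_del) & w > 0
  if (sum(usable) < sum(w > 0))
    warning("dropped ", sum(w > 0) - sum(usable),
            " jackknife block(s) with failed delete-one fits")
  if (sum(usable) < 2) stop("jackknife_date: fewer than 2 usable blocks")

  wj <- w[usable]; tj <- t_del[usable]
  g <- length(wj); W <- sum(wj)
  hj <- W / wj
  theta <- full$t
  t_mean <- g * theta - sum((1 - wj / W) * tj)
  ps <- hj * theta - (hj - 1) * tj   # pseudovalues
  var_j <- mean((ps - t_mean)^2 / (hj - 1))
  se <- sqrt(var_j)

  list(t_mean = t_mean, se = se,
       z = if (se > 0) t_mean / se else Inf,
       t_full = theta,
       blocks = data.frame(chrom = chroms[usable], t_minus = tj, weight = wj))
}
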