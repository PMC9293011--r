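# Guard against floating-point jitter when a pair distance sits exactly on
# a bin edge (positions snapped to the grid must land in the edge's bin).
.BIN_EPS <- 1e-7

#' Binned ancestry covariance against genetic distance
#'
#' For every within-chromosome marker pair at genetic distance d <= maxdis,
#' accumulates the centered product (K1 - Kbar)(K2 - Kbar) into the distance
#' bin floor(d/binsize). With several individuals the default pooling sums
#' numerators and pair counts across individuals within a bin before
#' division; \code{pooling = "mean"} instead averages per-individual curves.
#' Per-chromosome partial sums are retained so the leave-one-chromosome-out
#' jackknife can re-pool without recomputation. Marker pairs never span
#' chromosomes.
#'
#' The \code{"fft"} method aggregates centered weights onto a uniform grid
#' of cell width \code{binsize} per chromosome and obtains all distance-lag
#' sums and pair counts at once by autocorrelation of the sum track and the
#' count track (self-pairs removed), reducing the cost from quadratic to
#' n log n in the marker count. Two markers sharing a grid cell land in the
#' first (lag-0) bin, a discretisation difference from the naive path
#' bounded by one bin width; markers on distinct cells reproduce the naive
#' bins exactly.
#'
#' @param track an \code{\link{ancestry_weights}} result.
#' @param binsize bin width in Morgans (default 0.001 = 0.1 cM).
#' @param maxdis largest pair distance considered, Morgans.
#' @param method \code{"fft"} (default) or \code{"naive"}.
#' @param pooling \code{"pooled"} or \code{"mean"}.
#' @return Object of class \code{cov_curve}: a bin table (midpoint in
#'   Morgans, covariance \code{A}, pair \code{count}) plus per-chromosome,
#'   per-individual partial sum/count arrays for the jackknife.
#' @export
ancestry_covariance <- function(track, binsize = 0.001, maxdis = 1.0,
                                method = c("fft", "naive"),
                                pooling = c("pooled", "mean")) {
  method <- match.arg(method)
  pooling <- match.arg(pooling)
  stopifnot(inherits(track, "ancestry_track"), binsize > 0, maxdis > binsize)
  snp <- track$snp
  chroms <- unique(snp$chrom)
  n_ind <- nrow(track$K)
  nbins <- as.integer(floor(maxdis / binsize + .BIN_EPS))

  S <- array(0, dim = c(nbins, length(chroms), n_ind))
  N <- array(0, dim = c(nbins, length(chroms), n_ind))

  # centered weights, zero at invalid markers; count track carries validity
  Kc <- track$K - track$kbar
  Kc[!track$valid] <- 0
  Vn <- array(as.numeric(track$valid), dim = dim(track$valid))

  for (ci in seq_along(chroms)) {
    idx <- which(snp$chrom == chroms[ci])
    if (length(idx) < 2L) next
    pos <- snp$gpos[idx]
    Y <- t(Kc[, idx, drop = FALSE])   # markers x individuals
    V <- t(Vn[, idx, drop = FALSE])
    part <- if (method == "naive")
      .cov_chrom_naive(pos, Y, V, binsize, maxdis, nbins)
    else
      .cov_chrom_fft(pos, Y, V, binsize, nbins)
    S[, ci, ] <- part$S
    N[, ci, ] <- part$N
  }

  curve <- structure(list(S = S, N = N, binsize = binsize, maxdis = maxdis,
                          nbins = nbins, chroms = chroms, n_ind = n_ind,
                          method = method, pooling = pooling),
                     class = "cov_curve")
  curve$bins <- pool_curve(curve)
  if (all(curve$bins$count == 0)) attr(curve, "empty") <- TRUE
  curve
}

# all pairs, windowed scan over sorted positions; Y/V are markers x ind
.cov_chrom_naive <- function(pos, Y, V, binsize, maxdis, nbins) {
  m <- nrow(Y)
  n_ind <- ncol(Y)
  S <- matrix(0, nbins, n_ind)
  N <- matrix(0, nbins, n_ind)
  jmax <- findInterval(pos + maxdis + binsize * .BIN_EPS, pos)
  for (i in seq_len(m - 1L)) {
    hi <- jmax[i]
    if (hi <= i) next
    j <- (i + 1L):hi
    b <- floor((pos[j] - pos[i]) / binsize + .BIN_EPS) + 1L
    keep <- b <= nbins
    if (!any(keep)) next
    j <- j[keep]; b <- b[keep]
    # column recycling multiplies each individual's K_i into its column
    prod <- Y[j, , drop = FALSE] * rep(Y[i, ], each = length(j))
    cnt <- V[j, , drop = FALSE] * rep(V[i, ], each = length(j))
    S <- S + rowsum_into(prod * cnt, b, nbins)
    N <- N + rowsum_into(cnt, b, nbins)
  }
  list(S = S, N = N)
}

# scatter rows of x (groups g in 1..nb) into an nb-row matrix
rowsum_into <- function(x, g, nb) {
  out <- matrix(0, nb, ncol(x))
  rs <- rowsum(x, group = g)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# grid aggregation + autocorrelation per chromosome; lag l (distance l*binsize)
# maps to bin l+1, the bin the naive path uses for that distance
.cov_chrom_fft <- function(pos, Y, V, binsize, nbins) {
  n_ind <- ncol(Y)
  cell <- floor(pos / binsize + .BIN_EPS) + 1L
  ncell <- max(cell)
  Yg <- rowsum_into(Y * V, cell, ncell)
  Vg <- rowsum_into(V, cell, ncell)
  nfft <- stats::nextn(ncell + nbins + 1L, 2)
  pad <- matrix(0, nfft - ncell, n_ind)
  FY <- stats::mvfft(rbind(Yg, pad))
  FV <- stats::mvfft(rbind(Vg, pad))
  AY <- Re(stats::mvfft(FY * Conj(FY), inverse = TRUE)) / nfft
  AV <- Re(stats::mvfft(FV * Conj(FV), inverse = TRUE)) / nfft
  nlag <- min(nbins, nfft)
  S <- AY[seq_len(nlag), , drop = FALSE]
  N <- AV[seq_len(nlag), , drop = FALSE]
  # lag 0 holds sum_c y_c^2: strip self-pairs, halve the double-counted rest
  self_sq <- colSums((Y * V)^2)
  self_n <- colSums(V)
  S[1, ] <- (S[1, ] - self_sq) / 2
  N[1, ] <- (N[1, ] - self_n) / 2
  if (nlag < nbins) {
    S <- rbind(S, matrix(0, nbins - nlag, n_ind))
    N <- rbind(N, matrix(0, nbins - nlag, n_ind))
  }
  list(S = S, N = round(N))
}

#' Pool a covariance curve, optionally deleting one chromosome
#'
#' @param curve a \code{cov_curve}.
#' @param drop_chrom chromosome label to leave out (for the jackknife), or
#'   NULL for the full curve.
#' @return data.frame with bin midpoints (\code{mid}, Morgans), covariance
#'   \code{A} (NA where no pairs) and pair \code{count}.
#' @export
pool_curve <- function(curve, drop_chrom = NULL) {
  keep <- if (is.null(drop_chrom)) seq_along(curve$chroms) else
    which(curve$chroms != drop_chrom)
  S <- curve$S[, keep, , drop = FALSE]
  N <- curve$N[, keep, , drop = FALSE]
  mid <- (seq_len(curve$nbins) - 0.5) * curve$binsize
  if (curve$pooling == "pooled") {
    s <- rowSums(S, dims = 1)
    n <- rowSums(N, dims = 1)
    A <- ifelse(n > 0, s / pmax(n, 1), NA_real_)
  } else {
    s_i <- apply(S, c(1, 3), sum)   # bins x individuals
    n_i <- apply(N, c(1, 3), sum)
    a_i <- ifelse(n_i > 0, s_i / pmax(n_i, 1), NA_real_)
    A <- rowMeans(a_i, na.rm = TRUE)
    A[is.nan(A)] <- NA_real_
    n <- rowSums(n_i)
  }
  data.frame(bin = seq_len(curve$nbins), mid = mid, A = A, count = n)
}

#' @export
print.cov_curve <- function(x, ...) {
  filled <- sum(x$bins$count > 0)
  cat("cov_curve (", x$method, ", ", x$pooling, "): ", x$nbins, " bins of ",
      x$binsize * 100, " cM, ", filled, " populated; ",
      format(sum(x$bins$count), big.mark = ","), " marker pairs over ",
      length(x$chroms), " chromosomes\n", sep = "")
  invisible(x)
}
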