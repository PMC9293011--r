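#' Date a population admixture event from genotype data
#'
#' End-to-end estimator: per-individual ancestry fractions by least-squares
#' mixture regression, per-site ancestry weights under the two reference
#' panels, binned ancestry covariance against genetic distance, exponential
#' + affine decay fit, leave-one-chromosome-out weighted jackknife, fit
#' quality (NRMSD) and significance gating, and conversion to calendar
#' dates. Works on a single diploid genome; with several target individuals
#' the covariance numerators and pair counts are pooled per bin.
#'
#' An estimate is reported as significant when Z > 2, the decay rate
#' \eqn{\lambda} is below 200 generations, and NRMSD < 0.7 (all strict).
#' Generations convert to years as \code{t * generation_time} plus the mean
#' sampling age of the target individuals; BCE dates use the 1950
#' convention (negative BCE values are CE).
#'
#' @param target \code{\link{geno_matrix}} of the admixed individuals.
#' @param ref_a,ref_b reference panels: \code{freq_panel} objects or
#'   \code{geno_matrix} objects (converted via
#'   \code{\link{allele_frequencies}}), on the same markers as the target.
#' @param binsize covariance bin width, Morgans (default 0.001 = 0.1 cM).
#' @param maxdis largest pair distance, Morgans (default 1 = 100 cM).
#' @param lo,hi fit range, Morgans (defaults 0.0045 and 1.0; the lower
#'   cutoff suppresses background LD at short range).
#' @param generation_time years per generation (default 28).
#' @param ages optional named vector (or \code{ind_id}/age data.frame) of
#'   sampling ages in years BP; default 0 (present-day samples).
#' @param method covariance path, \code{"fft"} (default) or \code{"naive"}.
#' @param pooling combine individuals by pooled sums (default) or by
#'   averaging per-individual curves.
#' @param alpha optional fixed ancestry fraction(s); default estimated per
#'   individual.
#' @return Object of class \code{admix_date}; see
#'   \code{\link{summary.admix_date}}.
#' @examples
#' panels <- make_source_panels(n_snps = 4000, n_haps = c(30, 60), fst = 0.15,
#'                              chrom_lengths = rep(1, 6), seed = 1)
#' sim <- simulate_admixed(panels[[1]], panels[[2]],
#'                         admixture_spec(alpha = 0.2, t = 20,
#'                                        n_individuals = 4, seed = 2))
#' refA <- allele_frequencies(sample_panel_genotypes(panels[[1]], 25, seed = 3))
#' refB <- allele_frequencies(sample_panel_genotypes(panels[[2]], 25, seed = 4))
#' fit <- date_admixture(sim$genotypes, refA, refB)
#' fit
#' @export
date_admixture <- function(target, ref_a, ref_b,
                           binsize = 0.001, maxdis = 1.0,
                           lo = 0.0045, hi = 1.0,
                           generation_time = 28, ages = NULL,
                           method = c("fft", "naive"),
                           pooling = c("pooled", "mean"),
                           alpha = NULL) {
  method <- match.arg(method)
  pooling <- match.arg(pooling)
  stopifnot(inherits(target, "geno_matrix"))
  if (inherits(ref_a, "geno_matrix")) ref_a <- allele_frequencies(ref_a, label = "refA")
  if (inherits(ref_b, "geno_matrix")) ref_b <- allele_frequencies(ref_b, label = "refB")
  if (lo >= hi || hi > maxdis) stop("need lo < hi <= maxdis")

  track <- ancestry_weights(target, ref_a, ref_b, alpha = alpha)
  curve <- ancestry_covariance(track, binsize = binsize, maxdis = maxdis,
                               method = method, pooling = pooling)
  if (isTRUE(attr(curve, "empty")))
    stop("empty covariance curve: no valid marker pairs")
  fit <- fit_exp_decay(curve, lo = lo, hi = hi)
  jack <- jackknife_date(curve, lo = lo, hi = hi, full = fit)
  q <- nrmsd(fit$y, fit$fitted)

  mean_age <- .mean_sampling_age(target, ages)
  cal <- convert_generations(jack$t_mean, generation_time, mean_age)
  est <- list(
    t_gen = fit$t,
    t_gen_jack_mean = jack$t_mean,
    se_gen = jack$se,
    z = jack$z,
    nrmsd = q,
    significant = date_significant(jack$z, fit$lambda, q),
    years_bp = cal$years_bp,
    year_bce = cal$year_bce,
    mean_sampling_age = mean_age,
    generation_time = generation_time)

  structure(list(estimate = est, fit = fit, jackknife = jack, curve = curve,
                 alpha = track$alpha, alpha_pooled = mean(track$alpha),
                 n_individuals = nrow(target$ind),
                 n_snps_used = max(track$n_used),
                 targets = target$ind$ind_id,
                 params = list(binsize = binsize, maxdis = maxdis, lo = lo,
                               hi = hi, method = method, pooling = pooling,
                               generation_time = generation_time),
                 call = match.call()),
            class = "admix_date")
}

#' Convert an admixture time in generations to calendar dates
#'
#' \code{years_bp = t * generation_time + mean_sampling_age};
#' \code{year_bce = years_bp - 1950} (the 1950 convention; negative values
#' are CE).
#'
#' @param t_gen admixture time, generations.
#' @param generation_time years per generation (default 28).
#' @param mean_sampling_age mean sampling age of the target individuals,
#'   years BP (0 for present-day samples).
#' @return List with \code{years_bp} and \code{year_bce}.
#' @export
convert_generations <- function(t_gen, generation_time = 28,
                                mean_sampling_age = 0) {
  years_bp <- t_gen * generation_time + mean_sampling_age
  list(years_bp = years_bp, year_bce = years_bp - 1950)
}

#' Significance gate for an estimated admixture date
#'
#' All three conditions are strict inequalities: Z > 2, decay rate
#' lambda < 200 generations, NRMSD < 0.7.
#'
#' @param z jackknife Z-score.
#' @param lambda fitted decay rate, generations.
#' @param nrmsd normalised root-mean-square deviation of the fit.
#' @return Logical.
#' @export
date_significant <- function(z, lambda, nrmsd) {
  (z > 2) && (lambda < 200) && (nrmsd < 0.7)
}

.mean_sampling_age <- function(target, ages) {
  if (is.null(ages)) return(0)
  if (is.data.frame(ages)) {
    v <- ages[[2]]; names(v) <- as.character(ages[[1]]); ages <- v
  }
  hit <- ages[target$ind$ind_id]
  hit[is.na(hit)] <- 0
  mean(hit)
}

#' @export
print.admix_date <- function(x, ...) {
  e <- x$estimate
  cat("Admixture date from ancestry covariance decay\n")
  cat(sprintf("  %d target individual(s), %d markers; alpha = %.3f\n",
              x$n_individuals, x$n_snps_used, x$alpha_pooled))
  cat(sprintf("  t = %.1f +/- %.1f generations (jackknife), Z = %.2f, NRMSD = %.3f\n",
              e$t_gen_jack_mean, e$se_gen, e$z, e$nrmsd))
  cat(sprintf("  date: %.0f years BP = %.0f %s (generation time %g y, mean sampling age %g BP)\n",
              e$years_bp, abs(e$year_bce), if (e$year_bce >= 0) "BCE" else "CE",
              e$generation_time, e$mean_sampling_age))
  cat("  significant:", if (e$significant) "yes" else
      "no (requires Z > 2, lambda < 200, NRMSD < 0.7)", "\n")
  invisible(x)
}

#' Summarise a fitted admixture date
#'
#' @param object an \code{admix_date}.
#' @param ... unused.
#' @export
summary.admix_date <- function(object, ...) {
  out <- list(estimate = object$estimate, coef = coef(object),
              alpha = object$alpha, blocks = object$jackknife$blocks,
              params = object$params, n_individuals = object$n_individuals,
              boundary = object$fit$boundary)
  class(out) <- "summary.admix_date"
  out
}

#' @export
print.summary.admix_date <- function(x, ...) {
  e <- x$estimate
  cat("Exponential + affine fit: A =", format(x$coef[["amplitude"]], digits = 4),
      " lambda =", format(x$coef[["lambda"]], digits = 5),
      " c =", format(x$coef[["c"]], digits = 4), "\n")
  if (x$boundary) cat("  (decay rate at search boundary)\n")
  cat(sprintf("t (full fit)      : %.2f generations\n", e$t_gen))
  cat(sprintf("t (jackknife mean): %.2f +/- %.2f, Z = %.2f\n",
              e$t_gen_jack_mean, e$se_gen, e$z))
  cat(sprintf("NRMSD             : %.4f\n", e$nrmsd))
  cat(sprintf("calendar          : %.0f years BP (%.0f %s)\n", e$years_bp,
              abs(e$year_bce), if (e$year_bce >= 0) "BCE" else "CE"))
  cat("significant       :", e$significant, "\n")
  cat("per-individual alpha:", paste(format(x$alpha, digits = 3), collapse = " "), "\n")
  cat("\nLeave-one-chromosome-out blocks:\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' @export
coef.admix_date <- function(object, ...) {
  c(amplitude = object$fit$amplitude, lambda = object$fit$lambda,
    c = object$fit$c, t = object$fit$t)
}

#' Predicted covariance at new genetic distances
#'
#' @param object an \code{admix_date}.
#' @param newdata optional numeric vector of genetic distances in Morgans;
#'   defaults to the fitted bin midpoints.
#' @param ... unused.
#' @export
predict.admix_date <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$fit$d else as.numeric(newdata)
  object$fit$amplitude * exp(-object$fit$lambda * d) + object$fit$c
}

#' @export
fitted.admix_date <- function(object, ...) object$fit$fitted

#' @export
residuals.admix_date <- function(object, ...) object$fit$y - object$fit$fitted

#' Plot the ancestry covariance decay and its fit
#'
#' @param x an \code{admix_date}.
#' @param xlim_cM x range in cM (default the fit range).
#' @param ... passed to \code{plot}.
#' @export
plot.admix_date <- function(x, xlim_cM = NULL, ...) {
  bins <- x$curve$bins
  use <- bins$count > 0 & is.finite(bins$A)
  d_cm <- bins$mid[use] * 100
  if (is.null(xlim_cM)) xlim_cM <- c(x$fit$lo, x$fit$hi) * 100
  graphics::plot(d_cm, bins$A[use], pch = 16, cex = 0.4, col = "grey40",
                 xlim = xlim_cM, xlab = "genetic distance (cM)",
                 ylab = "ancestry covariance", ...)
  dd <- seq(x$fit$lo, x$fit$hi, length.out = 400)
  graphics::lines(dd * 100, predict(x, dd), col = "firebrick", lwd = 2)
  graphics::abline(h = x$fit$c, lty = 3)
  graphics::legend("topright", bty = "n", legend = sprintf(
    "t = %.1f ± %.1f gen", x$estimate$t_gen_jack_mean, x$estimate$se_gen))
  invisible(x)
}

#' Parametric bootstrap of the fitted decay curve
#'
#' Draws replicate curves as fitted values plus Gaussian noise with the
#' residual standard deviation, useful for visualising fit uncertainty.
#'
#' @param object an \code{admix_date}.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame of simulated bin values, one column per replicate.
#' @export
simulate.admix_date <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- stats::sd(residuals(object))
  n <- length(object$fit$d)
  out <- as.data.frame(replicate(nsim, object$fit$fitted + stats::rnorm(n, 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(d = object$fit$d, out)
}

#' Write curve, summary and jackknife-block files for a fitted date
#'
#' Emits the whitespace-delimited curve file (bin centre in cM, covariance,
#' pair count, fitted value), a one-row summary TSV and optionally the
#' per-block jackknife estimates, each with a provenance header comment.
#'
#' @param x an \code{admix_date}.
#' @param prefix output path prefix.
#' @param target_label label for the summary row.
#' @param blocks also write per-jackknife-block estimates.
#' @param header_extra extra \code{"# key: value"} comment lines.
#' @return Paths written, invisibly.
#' @export
write_date_outputs <- function(x, prefix, target_label = "target",
                               blocks = TRUE, header_extra = character()) {
  stopifnot(inherits(x, "admix_date"))
  hdr <- c(paste0("# admixtime ", as.character(utils::packageVersion("admixtime"))),
           paste0("# params: ", paste(names(x$params), unlist(x$params),
                                      sep = "=", collapse = " ")),
           header_extra)
  e <- x$estimate
  paths <- c(curve = paste0(prefix, ".curve.txt"),
             summary = paste0(prefix, ".summary.tsv"),
             blocks = paste0(prefix, ".jackknife.tsv"))

  bins <- x$curve$bins
  use <- bins$count > 0 & is.finite(bins$A)
  fit_all <- x$fit$amplitude * exp(-x$fit$lambda * bins$mid) + x$fit$c
  con <- file(paths[["curve"]], "w")
  writeLines(c(hdr, "bin_center_cM A(d) pair_count fitted_value"), con)
  writeLines(sprintf("%.4f %.8g %d %.8g", bins$mid[use] * 100, bins$A[use],
                     as.integer(bins$count[use]), fit_all[use]), con)
  close(con)

  smry <- data.frame(target = target_label, n_individuals = x$n_individuals,
                     n_snps_used = x$n_snps_used,
                     alpha = signif(x$alpha_pooled, 6),
                     t_gen = signif(e$t_gen_jack_mean, 6),
                     se_gen = signif(e$se_gen, 6), Z = signif(e$z, 6),
                     NRMSD = signif(e$nrmsd, 6),
                     mean_age_BP = e$mean_sampling_age,
                     years_BP = signif(e$years_bp, 6),
                     year_BCE = signif(e$year_bce, 6),
                     significant = e$significant)
  con <- file(paths[["summary"]], "w")
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(smry, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)

  if (blocks) {
    con <- file(paths[["blocks"]], "w")
    writeLines(hdr, con)
    suppressWarnings(utils::write.table(x$jackknife$blocks, con, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    close(con)
  } else paths <- paths[1:2]
  invisible(paths)
}
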