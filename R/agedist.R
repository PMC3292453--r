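#' Binned insertion-age distribution
#'
#' Right-open bins `[k w, (k+1) w)` over the qualified ages, with both count
#' and percent representations.
#'
#' @param ages non-negative insertion times (Myr); only qualified estimates
#'   should be supplied.
#' @param bin_width bin width in Myr (> 0).
#' @param scope,genome_id labels carried into the result.
#' @return an object of class `te_age_distribution`: list with `bins` (data
#'   frame `lower`, `upper`, `count`, `percent`), `n_total`, `mean_age`,
#'   `bin_width`, `scope`, `genome_id`.
#' @export
build_age_distribution <- function(ages, bin_width = 0.25, scope = "all",
                                   genome_id = NA_character_) {
  stopifnot(bin_width > 0)
  ages <- ages[!is.na(ages)]
  if (any(ages < 0)) stop("ages must be non-negative")
  if (!length(ages)) {
    warning("no ages supplied; empty distribution")
    bins <- data.frame(lower = numeric(), upper = numeric(),
                       count = integer(), percent = numeric())
    return(structure(list(bins = bins, n_total = 0L, mean_age = NA_real_,
                          bin_width = bin_width, scope = scope,
                          genome_id = genome_id),
                     class = "te_age_distribution"))
  }
  k <- floor(ages / bin_width)
  nb <- max(k) + 1L
  cnt <- tabulate(k + 1L, nbins = nb)
  bins <- data.frame(lower = (seq_len(nb) - 1L) * bin_width,
                     upper = seq_len(nb) * bin_width,
                     count = cnt, percent = 100 * cnt / length(ages))
  structure(list(bins = bins, n_total = length(ages), mean_age = mean(ages),
                 bin_width = bin_width, scope = scope, genome_id = genome_id),
            class = "te_age_distribution")
}

#' @export
print.te_age_distribution <- function(x, ...) {
  cat(sprintf("Age distribution (%s%s): n = %d, mean = %.3f Myr, bin = %g Myr\n",
              x$scope,
              if (is.na(x$genome_id)) "" else paste0(", ", x$genome_id),
              x$n_total, x$mean_age, x$bin_width))
  invisible(x)
}

# mean offset from the window start of an exponential truncated to width D
trunc_exp_mean <- function(lambda, D) {
  if (!is.finite(D)) return(1 / lambda)
  if (abs(lambda * D) < 1e-8) return(D / 2 - lambda * D^2 / 12)
  1 / lambda - D / (exp(lambda * D) - 1)
}

# unnormalised exponential mass over [a, b): integral of exp(-lambda x)
exp_mass <- function(a, b, lambda) {
  if (abs(lambda) < 1e-12) return(b - a)
  (exp(-lambda * a) - exp(-lambda * b)) / lambda
}

#' Maximum-likelihood exponential fit of an age distribution
#'
#' Fits the rate of an exponential distribution truncated to `fit_window` by
#' maximum likelihood (the rate solves the truncated-mean equation), and
#' reports the corresponding half-life `ln 2 / lambda`. For an untruncated
#' window the MLE reduces to `lambda = 1/mean`. Goodness of fit is a
#' chi-square statistic over deciles of the fitted distribution.
#'
#' @param ages insertion times (Myr).
#' @param fit_window interval `[a, b)` of ages used for the fit; `b` may be
#'   `Inf`. Default `c(0, 2)`, where the exponential regime of observed TE age
#'   distributions tends to hold.
#' @param min_n minimum number of ages in the window (default 30).
#' @return an object of class `te_exp_fit` with `rate_lambda`, `half_life`,
#'   `fit_window`, `n_used`, `goodness` (list: `chisq`, `df`, `p_value`), and
#'   `failed`.
#' @export
fit_exponential <- function(ages, fit_window = c(0, 2), min_n = 30L) {
  a <- fit_window[1]; b <- fit_window[2]
  x <- ages[!is.na(ages) & ages >= a & ages < b]
  if (length(x) < min_n)
    stop("need at least ", min_n, " ages inside the fit window; got ",
         length(x))
  if (stats::sd(x) == 0) {
    return(structure(list(rate_lambda = NA_real_, half_life = NA_real_,
                          fit_window = fit_window, n_used = length(x),
                          goodness = NULL, failed = TRUE),
                     class = "te_exp_fit"))
  }
  m <- mean(x - a)
  if (!is.finite(b)) {
    lambda <- 1 / m
  } else {
    D <- b - a
    f <- function(l) trunc_exp_mean(l, D) - m
    # trunc_exp_mean is decreasing in lambda from D (l -> -Inf) to 0 (l -> Inf)
    lo <- -1; hi <- 1
    while (f(lo) < 0 && lo > -1e6) lo <- lo * 2
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
    lambda <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  # chi-square over deciles of the fitted (truncated) distribution
  goodness <- NULL
  if (length(x) >= 50L && is.finite(lambda) && abs(lambda) > 1e-12) {
    D <- if (is.finite(b)) b - a else Inf
    u <- seq(0.1, 0.9, by = 0.1)
    total <- if (is.finite(D)) 1 - exp(-lambda * D) else 1
    qx <- a - log(1 - u * total) / lambda
    br <- c(a, qx, if (is.finite(b)) b else max(x) + 1)
    obs <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                    nbins = length(br) - 1L)
    expd <- rep(length(x) / 10, 10)
    chisq <- sum((obs - expd)^2 / expd)
    goodness <- list(chisq = chisq, df = 8L,
                     p_value = stats::pchisq(chisq, 8L, lower.tail = FALSE))
  }
  structure(list(rate_lambda = lambda, half_life = log(2) / lambda,
                 fit_window = fit_window, n_used = length(x),
                 goodness = goodness, failed = FALSE),
            class = "te_exp_fit")
}

#' @export
print.te_exp_fit <- function(x, ...) {
  if (x$failed) {
    cat("Exponential fit failed (degenerate ages)\n")
    return(invisible(x))
  }
  cat(sprintf("Exponential age fit on [%g, %g) Myr, n = %d\n",
              x$fit_window[1], x$fit_window[2], x$n_used))
  cat(sprintf("  rate lambda = %.4f /Myr; half-life = %.4f Myr (%.0f yr)\n",
              x$rate_lambda, x$half_life, x$half_life * 1e6))
  if (!is.null(x$goodness))
    cat(sprintf("  decile chi-square = %.2f (df = %d, p = %.3g)\n",
                x$goodness$chisq, x$goodness$df, x$goodness$p_value))
  invisible(x)
}

#' Test for a recent deficit of insertions
#'
#' Fits an exponential to ages outside the tested window (by default on
#' `[w, 2w + 2]` Myr for a window ending at `w`, to avoid circularity),
#' extrapolates the expected count inside the window, and compares it with the
#' observed count via an exact Poisson ratio test. A drop is declared when the
#' 95% interval on observed/expected lies entirely below 1.
#'
#' @param ages qualified insertion times (Myr).
#' @param window tested interval in Myr (default `c(0, 0.5)`, the most recent
#'   tenth of a 5-Myr divergence time).
#' @param fit_window interval used for the fit; default `c(window[2],
#'   2 * window[2] + 2)`.
#' @param conf_level confidence level of the Poisson interval.
#' @return an object of class `te_drop_report`: `window`, `observed`,
#'   `expected`, `ratio`, `poisson_interval`, `p_value`, `drop`,
#'   `low_power` (flagged when `expected < 5`), and the underlying `fit`.
#' @export
detect_drop <- function(ages, window = c(0, 0.5), fit_window = NULL,
                        conf_level = 0.95) {
  if (is.null(fit_window)) fit_window <- c(window[2], 2 * window[2] + 2)
  if (fit_window[1] < window[2])
    stop("fit window must not overlap the tested window")
  fit <- fit_exponential(ages, fit_window)
  if (fit$failed) stop("exponential fit failed; cannot extrapolate")
  lambda <- fit$rate_lambda
  mass_w <- exp_mass(window[1], window[2], lambda)
  mass_f <- exp_mass(fit_window[1], fit_window[2], lambda)
  expected <- fit$n_used * mass_w / mass_f
  observed <- sum(ages >= window[1] & ages < window[2], na.rm = TRUE)
  ratio <- observed / expected
  # Interval on the observed/expected ratio. The expectation is itself
  # estimated (Poisson count in the fit window AND the fitted rate), so a bare
  # Poisson interval on the observed count under-covers; propagate all three
  # components on the log scale:
  #   var(log ratio) = 1/observed + 1/n_fit + c^2 var(lambda_hat),
  # with c = d log(mass_w/mass_f)/d lambda = mean_f - mean_w (truncated means)
  # and var(lambda_hat) = 1/(n_fit * Var(x - a)) from the truncated-exponential
  # Fisher information.
  tmean <- function(a, b, l) {
    if (abs(l) < 1e-8) return((a + b) / 2)
    a + trunc_exp_mean(l, b - a)
  }
  x_fit <- ages[!is.na(ages) & ages >= fit_window[1] & ages < fit_window[2]]
  var_lambda <- 1 / (fit$n_used * stats::var(x_fit - fit_window[1]))
  cc <- tmean(fit_window[1], fit_window[2], lambda) -
        tmean(window[1], window[2], lambda)
  v_lr <- 1 / max(observed, 0.5) + 1 / fit$n_used + cc^2 * var_lambda
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- ratio * exp(c(-1, 1) * z * sqrt(v_lr))
  p_value <- if (observed == 0) NA_real_ else
    2 * stats::pnorm(-abs(log(ratio)) / sqrt(v_lr))
  structure(list(window = window, observed = observed, expected = expected,
                 ratio = ratio,
                 poisson_interval = ci,
                 p_value = p_value,
                 drop = ci[2] < 1,
                 low_power = expected < 5, fit = fit),
            class = "te_drop_report")
}

#' @export
print.te_drop_report <- function(x, ...) {
  cat(sprintf("Recent-insertion deficit test on [%g, %g) Myr\n",
              x$window[1], x$window[2]))
  cat(sprintf("  observed %d vs expected %.1f (ratio %.3f, %s interval [%.3f, %.3f])\n",
              x$observed, x$expected, x$ratio, "Poisson",
              x$poisson_interval[1], x$poisson_interval[2]))
  cat(sprintf("  drop declared: %s%s\n", x$drop,
              if (x$low_power) " (LOW POWER: expected < 5)" else ""))
  invisible(x)
}

#' Sensitivity of the drop window to the substitution rate
#'
#' Re-runs [detect_drop()] for each candidate substitution rate. Divergences
#' (not times) are supplied so ages can be recomputed per rate; the tested and
#' fit windows, defined at the reference rate, rescale by `r_ref / r` exactly
#' as `T = K/(2r)` rescales the ages.
#'
#' @param ages_K nearest-neighbour divergences K (substitutions/site).
#' @param r_values substitution rates to try (all > 0).
#' @param r_ref reference rate at which `window` is defined (default 0.015).
#' @param window tested window at the reference rate (Myr).
#' @param fit_window fit window at the reference rate (Myr); default
#'   `c(window[2], 2 * window[2] + 2)`.
#' @return data frame with one row per rate: `r`, `window_lo`, `window_hi`,
#'   `observed`, `expected`, `ratio`, `ci_lo`, `ci_hi`, `drop`.
#' @export
rate_sensitivity <- function(ages_K, r_values, r_ref = 0.015,
                             window = c(0, 0.5), fit_window = NULL) {
  if (any(r_values <= 0)) stop("substitution rates must be positive")
  if (is.null(fit_window)) fit_window <- c(window[2], 2 * window[2] + 2)
  rows <- lapply(r_values, function(r) {
    s <- r_ref / r
    ages <- ages_K / (2 * r)
    rep <- detect_drop(ages, window = window * s, fit_window = fit_window * s)
    data.frame(r = r, window_lo = rep$window[1], window_hi = rep$window[2],
               observed = rep$observed, expected = rep$expected,
               ratio = rep$ratio, ci_lo = rep$poisson_interval[1],
               ci_hi = rep$poisson_interval[2], drop = rep$drop)
  })
  do.call(rbind, rows)
}
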