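# EMSA binding analysis: Hill isotherm fitting and replicate combination.

#' Hill binding isotherm
#'
#' `theta = (a - b) / (1 + (K_d_app / conc)^n) + b`, the fraction of RNA
#' bound at a protein concentration `conc`. At `conc = K_d_app` with
#' `a = 1, b = 0` the isotherm equals 0.5 for any `n`.
#'
#' @param conc protein concentration (molar), positive.
#' @param K_d_app apparent dissociation constant (molar).
#' @param n Hill coefficient.
#' @param a,b upper and lower baselines.
#' @export
hill_theta <- function(conc, K_d_app, n = 1, a = 1, b = 0) {
  (a - b) / (1 + (K_d_app / conc)^n) + b
}

#' Fraction bound from integrated gel band signals
#' @param bound_signal,unbound_signal integrated band intensities, both
#'   non-negative and not both zero.
#' @export
compute_fraction_bound <- function(bound_signal, unbound_signal) {
  if (any(bound_signal < 0) || any(unbound_signal < 0))
    stop("band signals must be non-negative", call. = FALSE)
  total <- bound_signal + unbound_signal
  if (any(total == 0))
    stop("bound and unbound signals are both zero: fraction bound undefined",
         call. = FALSE)
  bound_signal / total
}

#' Fit the Hill isotherm to one titration
#'
#' Nonlinear least squares (Levenberg-Marquardt) with bounds
#' `K_d_app > 0`, `n` in (0.3, 6), `a` in (0.5, 1.5), `b` in (-0.2, 0.5).
#' `K_d_app` is fitted on a log10 scale for conditioning, with five
#' log-spaced multi-starts spanning the titrated concentration range; the
#' best-residual start wins. `fix_n` holds the Hill coefficient at a given
#' value (used for titrations reported with a bare coefficient of 1).
#'
#' @param series data.frame with columns `concentration_M`,
#'   `fraction_bound` (one replicate; >= 6 points).
#' @param fix_n optional fixed Hill coefficient.
#' @param fix_baselines optionally fix `a = 1, b = 0`.
#' @return object of class `hill_fit`: `params` ([hill_params()]),
#'   `se` (named standard errors), `rss`, `n_fixed`, `out_of_range`
#'   (TRUE when the fitted K_d falls more than 10x outside the titrated
#'   range).
#' @export
fit_hill <- function(series, fix_n = NULL, fix_baselines = FALSE) {
  stopifnot(all(c("concentration_M", "fraction_bound") %in% names(series)))
  conc <- series$concentration_M
  y <- series$fraction_bound
  if (length(conc) < 6L) .stop_config("a titration needs >= 6 points")
  if (any(conc <= 0)) .stop_config("concentrations must be strictly positive")
  if (any(!is.finite(y))) .stop_config("fraction bound must be finite")

  free_n <- is.null(fix_n)
  free_ab <- !fix_baselines
  model <- function(p) {
    lK <- p[["lK"]]
    n <- if (free_n) p[["n"]] else fix_n
    a <- if (free_ab) p[["a"]] else 1
    b <- if (free_ab) p[["b"]] else 0
    hill_theta(conc, 10^lK, n, a, b)
  }
  lower <- c(lK = log10(min(conc)) - 4)
  upper <- c(lK = log10(max(conc)) + 4)
  start0 <- c(lK = NA_real_)
  if (free_n) { lower <- c(lower, n = 0.3); upper <- c(upper, n = 6); start0 <- c(start0, n = 1) }
  if (free_ab) {
    lower <- c(lower, a = 0.5, b = -0.2); upper <- c(upper, a = 1.5, b = 0.5)
    start0 <- c(start0, a = 1, b = 0)
  }
  seeds <- seq(log10(min(conc)), log10(max(conc)), length.out = 5)
  best <- NULL
  for (s in seeds) {
    start <- start0
    start[["lK"]] <- s
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = function(p) model(p) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              ftol = 1e-12,
                                                              ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("Hill fit failed to converge from all starts", call. = FALSE)
  p <- best$par
  K <- 10^p[["lK"]]
  nhat <- if (free_n) p[["n"]] else fix_n
  ahat <- if (free_ab) p[["a"]] else 1
  bhat <- if (free_ab) p[["b"]] else 0
  se_raw <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, length(p)))
  names(se_raw) <- names(p)
  se <- c(K_d_app = unname(K * log(10) * se_raw[["lK"]]),
          n = if (free_n) unname(se_raw[["n"]]) else 0,
          a = if (free_ab) unname(se_raw[["a"]]) else 0,
          b = if (free_ab) unname(se_raw[["b"]]) else 0)
  out_of_range <- K < min(conc) / 10 || K > max(conc) * 10
  if (out_of_range)
    warning(sprintf("fitted K_d,app (%.3g M) lies >10x outside the titrated range", K))
  structure(list(params = hill_params(K, nhat, ahat, bhat),
                 se = se,
                 rss = best$deviance,
                 n_fixed = !free_n,
                 out_of_range = out_of_range),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<hill_fit: K_d,app = %.3g M +/- %.2g, n = %.2f%s, a = %.2f, b = %.2f, rss = %.3g>\n",
              p$K_d_app, x$se[["K_d_app"]], p$n, if (x$n_fixed) " (fixed)" else "",
              p$a, p$b, x$rss))
  invisible(x)
}

#' Combine replicate Hill fits into a single apparent affinity
#'
#' Inverse-variance weighted mean of `K_d_app` (and of `n` when it was
#' free), with the reported spread being the weighted standard deviation of
#' the replicate estimates. If any fit carries a (near-)zero standard
#' error the combination falls back to an unweighted mean and is flagged.
#'
#' @param fits list of `hill_fit` objects (>= 2).
#' @return object of class `combined_affinity` with `K_d_app_mean`,
#'   `K_d_app_sd`, `n_mean`, `n_sd`, `n_replicates`, `weighted`.
#' @export
combine_replicates <- function(fits) {
  stopifnot(length(fits) >= 2L)
  K <- vapply(fits, function(f) f$params$K_d_app, numeric(1))
  seK <- vapply(fits, function(f) f$se[["K_d_app"]], numeric(1))
  n_free <- !vapply(fits, `[[`, logical(1), "n_fixed")
  nv <- vapply(fits, function(f) f$params$n, numeric(1))
  sen <- vapply(fits, function(f) f$se[["n"]], numeric(1))

  weighted <- all(is.finite(seK)) && all(seK > abs(K) * 1e-10)
  wmean_wsd <- function(x, se, use_weights) {
    w <- if (use_weights) 1 / se^2 else rep(1, length(x))
    m <- sum(w * x) / sum(w)
    s <- sqrt(sum(w * (x - m)^2) / sum(w) * length(x) / (length(x) - 1))
    c(mean = m, sd = s)
  }
  kk <- wmean_wsd(K, seK, weighted)
  if (any(n_free)) {
    use_w <- weighted && all(sen[n_free] > abs(nv[n_free]) * 1e-10)
    nn <- wmean_wsd(nv[n_free], sen[n_free], use_w && sum(n_free) > 1)
    if (sum(n_free) < 2L) nn <- c(mean = nv[n_free][1], sd = NA_real_)
  } else {
    nn <- c(mean = nv[1], sd = 0)
  }
  structure(list(K_d_app_mean = unname(kk["mean"]),
                 K_d_app_sd = unname(kk["sd"]),
                 n_mean = unname(nn["mean"]),
                 n_sd = unname(nn["sd"]),
                 n_replicates = length(fits),
                 weighted = weighted),
            class = "combined_affinity")
}

#' @export
print.combined_affinity <- function(x, ...) {
  cat(sprintf("<combined_affinity: K_d,app = %.3g +/- %.2g M (n_rep=%d, %s)>\n",
              x$K_d_app_mean, x$K_d_app_sd, x$n_replicates,
              if (x$weighted) "inverse-variance weighted" else "unweighted"))
  invisible(x)
}

#' Published apparent affinities for stepwise U4/U6 di-snRNP assembly
#'
#' Reference table of EMSA-derived apparent dissociation constants and Hill
#' coefficients for each protein (or sub-complex) titrated against each
#' pre-assembled U4/U6 snRNA complex. Rows whose Hill coefficient is
#' reported as a bare 1 (no uncertainty) are flagged `n_fixed`, meaning the
#' coefficient was held at 1 during fitting. Used as simulation ground
#' truths by the titration fixtures.
#'
#' @return data.frame with columns `complex`, `titrated`, `kd_nM`,
#'   `kd_err_nM`, `hill_n`, `hill_n_err`, `n_fixed`.
#' @export
reference_affinities <- function() {
  data.frame(
    complex = c("U4/U6", "U4/U6", "U4/U6", "U4/U6", "U4/U6",
                "U4/U6/Snu13", "U4/U6/Snu13", "U4/U6/Snu13", "U4/U6/Snu13",
                "U4/U6/Snu13/Prp31", "U4/U6/Snu13/Prp31", "U4/U6/Snu13/Prp31",
                "U4/U6/Snu13/Prp31/Sm", "U4/U6/Snu13/Prp31/Sm",
                "U4/U6/Snu13/Prp31/Sm/LSm"),
    titrated = c("Snu13", "Prp31", "Sm", "LSm", "Prp3/4",
                 "Prp31", "Sm", "LSm", "Prp3/4",
                 "Sm", "LSm", "Prp3/4",
                 "LSm", "Prp3/4",
                 "Prp3/4"),
    kd_nM = c(17, 243, 89, 5, 57, 50, 92, 26, 88, 108, 98, 417, 154, 557, 20),
    kd_err_nM = c(1, 16, 4, 0.2, 2, 4, 9, 1, 8, 9, 34, 43, 15, 75, 1),
    hill_n = c(1, 1.9, 3.5, 1.7, 2.6, 2.9, 2.2, 3.3, 3.4, 2.3, 1, 1.5, 1, 1, 1.6),
    hill_n_err = c(NA, 0.2, 0.4, 0.1, 0.3, 0.5, 0.4, 0.3, 1.0, 0.4, NA, 0.2, NA, NA, 0.1),
    n_fixed = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}
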