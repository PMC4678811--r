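# Ensemble population analysis: time-binned FRET histograms, Gaussian
# mixture fits by nonlinear least squares, per-molecule population
# assignment with bootstrap uncertainties, and condition comparisons.

#' Build a time-binned FRET histogram from QC-passed traces
#'
#' Pools all valid pre-bleach frames of every QC-passed trace (optionally
#' the per-molecule mean FRET values instead) and density-normalizes over
#' fixed bins.
#'
#' @param fts list of `fret_trace` objects (see [qc_select()]).
#' @param bin_width bin width in FRET units (default 0.02, resolving peaks
#'   0.1 apart with five bins between means).
#' @param range histogram support; apparent FRET can undershoot 0 or
#'   overshoot 1 through channel noise, hence the padded default.
#' @param source `"frames"` pools frames (default); `"means"` uses one
#'   value per molecule.
#' @return object of class `fret_histogram` with `bin_edges`, `mids`,
#'   `density`, `counts`, `n_molecules`, `n_frames`, and the pooled
#'   `values`.
#' @export
build_histogram <- function(fts, bin_width = 0.02, range = c(-0.2, 1.2),
                            source = c("frames", "means")) {
  source <- match.arg(source)
  passed <- Filter(function(ft) isTRUE(ft$qc_pass), fts)
  if (length(passed) == 0L)
    stop("no QC-passed traces to histogram", call. = FALSE)
  values <- if (source == "frames") {
    unlist(lapply(passed, function(ft) {
      pre <- seq_len(ft$bleach_frame - 1L)
      ft$fret[pre][ft$valid[pre]]
    }), use.names = FALSE)
  } else {
    vapply(passed, `[[`, numeric(1), "mean_fret")
  }
  inside <- values >= range[1] & values <= range[2]
  # a few extreme-noise frames beyond the padded support are routine;
  # warn only when a non-negligible share of the mass is clipped
  if (mean(!inside) > 0.01)
    warning(sprintf("%d FRET values (%.1f%%) outside [%g, %g] dropped",
                    sum(!inside), 100 * mean(!inside), range[1], range[2]))
  values <- values[inside]
  edges <- seq(range[1], range[2], by = bin_width)
  if (max(edges) < range[2]) edges <- c(edges, max(edges) + bin_width)
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  density <- counts / (sum(counts) * bin_width)
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 density = density,
                 counts = counts,
                 bin_width = bin_width,
                 n_molecules = length(passed),
                 n_frames = length(values),
                 values = values),
            class = "fret_histogram")
}

.gauss_sum <- function(x, mu, sigma, amp) {
  y <- numeric(length(x))
  for (j in seq_along(mu)) y <- y + amp[j] * dnorm(x, mu[j], sigma[j])
  y
}

#' Fit a sum of Gaussians to a FRET histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt with bounds) of a
#' k-component Gaussian sum to the bin densities. When `init_means` is
#' given it seeds, but does not constrain, the component means; otherwise
#' seeds come from the k largest well-separated local maxima of the
#' histogram (quantiles as fallback). Components are returned in ascending
#' order of mean with weights normalized to sum to 1.
#'
#' @param hist a `fret_histogram`.
#' @param k number of components.
#' @param init_means optional numeric seeds for the means.
#' @param init_sigma initial component width.
#' @param fix_means optional length-k vector holding the component means
#'   fixed while widths and amplitudes are fitted; this is how the
#'   two-stage procedure anchors the overall-histogram fit, since with
#'   peaks ~2 sigma apart a fully free mixture fit is ill-determined.
#' @return object of class `mixture_model`: `components` data.frame
#'   (`mean`, `sigma`, `weight`, `se_mean`), `fit_residual` (RSS),
#'   `degenerate` flag (coincident means or a weight < 0.05).
#' @export
fit_mixture <- function(hist, k, init_means = NULL, init_sigma = 0.05,
                        fix_means = NULL) {
  stopifnot(inherits(hist, "fret_histogram"), k >= 1L)
  nonempty <- sum(hist$counts > 0)
  if (nonempty < 5L * 3L * k)
    warning(sprintf("only %d non-empty bins for %d parameters; fit may be unstable",
                    nonempty, 3L * k))
  x <- hist$mids
  y <- hist$density
  fixed <- !is.null(fix_means)
  if (fixed) {
    if (length(fix_means) != k) stop("fix_means must have length k", call. = FALSE)
    init_means <- sort(fix_means)
  }
  if (is.null(init_means)) init_means <- .peak_seeds(hist, k)
  if (length(init_means) != k) stop("init_means must have length k", call. = FALSE)
  mu0 <- sort(init_means)

  amp0 <- log(max(max(y), 1e-3) * init_sigma * sqrt(2 * pi) / k)
  if (fixed) {
    par0 <- c(rep(log(init_sigma), k), rep(amp0, k))
    lower <- c(rep(log(5e-3), k), rep(log(1e-10), k))
    upper <- c(rep(log(0.5), k), rep(log(1e3), k))
    unpack <- function(p) list(mu = mu0, sigma = exp(p[1:k]),
                               amp = exp(p[(k + 1):(2 * k)]))
  } else {
    par0 <- c(mu0, rep(log(init_sigma), k), rep(amp0, k))
    lower <- c(rep(min(x), k), rep(log(5e-3), k), rep(log(1e-10), k))
    upper <- c(rep(max(x), k), rep(log(0.5), k), rep(log(1e3), k))
    unpack <- function(p) list(mu = p[1:k], sigma = exp(p[(k + 1):(2 * k)]),
                               amp = exp(p[(2 * k + 1):(3 * k)]))
  }
  resid_fn <- function(p) {
    u <- unpack(p)
    .gauss_sum(x, u$mu, u$sigma, u$amp) - y
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 9))
    stop(sprintf("mixture fit did not converge (info=%d, residual=%g)",
                 fit$info, fit$deviance), call. = FALSE)
  u <- unpack(fit$par)
  mu <- u$mu; sigma <- u$sigma; amp <- u$amp
  se_mu <- rep(NA_real_, k)
  if (!fixed) {
    se_all <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                       error = function(e) NULL)
    if (!is.null(se_all)) se_mu <- se_all[1:k]
  }
  ord <- order(mu)
  mu <- mu[ord]; sigma <- sigma[ord]; amp <- amp[ord]; se_mu <- se_mu[ord]
  w <- amp * sigma * sqrt(2 * pi)
  w <- w / sum(w)
  degenerate <- (k > 1L && min(diff(mu)) < 0.01) || any(w < 0.05)
  structure(list(components = data.frame(mean = mu, sigma = sigma, weight = w,
                                         se_mean = se_mu),
                 fit_residual = fit$deviance,
                 degenerate = degenerate),
            class = "mixture_model")
}

.peak_seeds <- function(hist, k) {
  d <- hist$density
  x <- hist$mids
  # local maxima, strongest first, enforcing >= 2 bins separation
  is_peak <- which(d > c(-Inf, head(d, -1)) & d >= c(d[-1], -Inf) & d > 0)
  is_peak <- is_peak[order(d[is_peak], decreasing = TRUE)]
  sel <- integer(0)
  for (i in is_peak) {
    if (all(abs(i - sel) > 2)) sel <- c(sel, i)
    if (length(sel) == k) break
  }
  if (length(sel) < k) {
    q <- quantile(hist$values, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    return(sort(q))
  }
  sort(x[sel])
}

#' Two-stage mixture fit (per-population means, then overall histogram)
#'
#' First separates molecules into k groups by their mean FRET (k-means on
#' per-molecule means, deterministically initialized from quantiles), fits a
#' single Gaussian to each group's pooled-frame histogram, and then uses
#' those means to seed a k-component fit of the overall histogram.
#'
#' @inheritParams fit_mixture
#' @param fts list of `fret_trace` objects (QC-passed ones are used).
#' @param bin_width,range passed to [build_histogram()].
#' @return a `mixture_model` for the overall histogram.
#' @export
fit_mixture_two_stage <- function(fts, k, bin_width = 0.02, range = c(-0.2, 1.2)) {
  passed <- Filter(function(ft) isTRUE(ft$qc_pass) && !isFALSE(ft$is_static), fts)
  means <- vapply(passed, `[[`, numeric(1), "mean_fret")
  # seed the molecule grouping from the peaks of the per-molecule-mean
  # histogram: molecule means scatter far less than frames, so discrete
  # states show up as sharp, well-separated modes even when the pooled
  # frame histogram overlaps
  h_means <- build_histogram(passed, bin_width, range, source = "means")
  centers <- .peak_seeds(h_means, k)
  if (k > 1L && min(diff(centers)) < 1e-6)
    centers <- centers + seq(0, 1e-4, length.out = k)
  grp <- if (k == 1L) rep(1L, length(means)) else {
    km <- kmeans(means, centers = matrix(centers, ncol = 1), iter.max = 100)
    km$cluster
  }
  stage1 <- lapply(seq_len(k), function(j) {
    sub <- passed[grp == j]
    if (length(sub) == 0L) return(c(mean = centers[j], se = NA_real_))
    h <- build_histogram(sub, bin_width, range)
    fit <- tryCatch(suppressWarnings(fit_mixture(h, 1L, init_means = mean(h$values))),
                    error = function(e) NULL)
    if (is.null(fit)) c(mean = mean(h$values), se = NA_real_)
    else c(mean = fit$components$mean[1], se = fit$components$se_mean[1])
  })
  mu1 <- vapply(stage1, `[[`, numeric(1), "mean")
  se1 <- vapply(stage1, `[[`, numeric(1), "se")[order(mu1)]
  overall <- build_histogram(passed, bin_width, range)
  out <- suppressWarnings(fit_mixture(overall, k, fix_means = mu1))
  out$components$se_mean <- se1
  out
}

#' Assign molecules to mixture components and estimate fractions
#'
#' Each QC-passed, static molecule is assigned to the component whose
#' Gaussian density is highest at the molecule's mean FRET (ties broken
#' toward the lower-mean component). Molecules more than 3 component sigmas
#' from every mean go to an "unassigned" bucket and are excluded from the
#' fractions, which are computed over assigned molecules and sum to 1.
#' Uncertainties are bootstrap standard errors over molecules.
#'
#' @param fts list of `fret_trace` objects.
#' @param model a `mixture_model`.
#' @param condition label for the experimental condition.
#' @param n_boot bootstrap resamples (molecule-level).
#' @param seed seed for the bootstrap.
#' @return object of class `population_summary`: `fractions` data.frame
#'   (`component`, `mean_fret`, `fraction`, `se`, `n`), `n_molecules`
#'   (assigned), `n_unassigned`, `condition`, `assignments`.
#' @export
assign_molecules <- function(fts, model, condition = "condition",
                             n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(model, "mixture_model"))
  usable <- Filter(function(ft) isTRUE(ft$qc_pass) && !isFALSE(ft$is_static), fts)
  if (length(usable) == 0L) stop("no usable molecules to assign", call. = FALSE)
  m <- vapply(usable, `[[`, numeric(1), "mean_fret")
  mu <- model$components$mean
  sigma <- model$components$sigma
  k <- length(mu)
  dens <- vapply(seq_len(k), function(j) dnorm(m, mu[j], sigma[j]), numeric(length(m)))
  dens <- matrix(dens, nrow = length(m))
  z <- vapply(seq_len(k), function(j) abs(m - mu[j]) / sigma[j], numeric(length(m)))
  z <- matrix(z, nrow = length(m))
  unassigned <- apply(z, 1, min) > 3
  comp <- apply(dens, 1, function(d) which(d == max(d))[1])  # tie -> lower mean
  comp[unassigned] <- NA_integer_
  assigned <- comp[!is.na(comp)]
  n_assigned <- length(assigned)
  counts <- tabulate(assigned, nbins = k)
  fractions <- counts / n_assigned
  set.seed(seed)
  boot <- matrix(0, nrow = n_boot, ncol = k)
  for (b in seq_len(n_boot)) {
    res <- assigned[sample.int(n_assigned, replace = TRUE)]
    boot[b, ] <- tabulate(res, nbins = k) / n_assigned
  }
  se <- apply(boot, 2, sd)
  structure(list(fractions = data.frame(component = seq_len(k),
                                        mean_fret = mu,
                                        fraction = fractions,
                                        se = se,
                                        n = counts),
                 n_molecules = n_assigned,
                 n_unassigned = sum(unassigned),
                 condition = condition,
                 assignments = data.frame(
                   molecule_id = vapply(usable, `[[`, character(1), "molecule_id"),
                   mean_fret = m, component = comp, stringsAsFactors = FALSE)),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary '%s': %d molecules (%d unassigned)>\n",
              x$condition, x$n_molecules, x$n_unassigned))
  f <- x$fractions
  for (i in seq_len(nrow(f)))
    cat(sprintf("  component %d  FRET %.3f  %5.1f%% +/- %.1f%%  (n=%d)\n",
                f$component[i], f$mean_fret[i], 100 * f$fraction[i],
                100 * f$se[i], f$n[i]))
  invisible(x)
}

.stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare a population fraction between two conditions
#'
#' Two-sample Welch t-test on per-replicate fraction estimates of one
#' component, with significance stars at the 0.05 / 0.01 / 0.001
#' thresholds.
#'
#' @param a,b numeric vectors of per-replicate fractions (length >= 2
#'   each).
#' @param condition_a,condition_b labels.
#' @param component_index which mixture component the fractions refer to.
#' @return object of class `condition_comparison` with `p_value`,
#'   `t_statistic`, `stars`, group means.
#' @export
compare_conditions <- function(a, b, condition_a = "A", condition_b = "B",
                               component_index = 1L) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 replicate fraction estimates per condition; ",
         "with a single ensemble, form bootstrap pseudo-replicates first",
         call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(a, b)
  }
  p <- unname(tt$p.value)
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 component_index = as.integer(component_index),
                 mean_a = mean(a), mean_b = mean(b),
                 t_statistic = unname(tt$statistic),
                 p_value = p, stars = .stars(p)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<comparison %s vs %s, component %d: %.1f%% vs %.1f%%, p=%.3g %s>\n",
              x$condition_a, x$condition_b, x$component_index,
              100 * x$mean_a, 100 * x$mean_b, x$p_value, x$stars))
  invisible(x)
}
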