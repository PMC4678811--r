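# Orchestration: end-to-end pipelines over synthetic fixtures and
# one-command reproduction of the bundled study fixtures.

#' Bundled smFRET ensemble fixtures
#'
#' Ground-truth definitions of the synthetic ensembles used throughout the
#' package: for each labeled construct and protein condition, the static
#' FRET state means, the ground-truth population proportions, the ensemble
#' size, and which mixture component corresponds to "population 1" (the
#' conformer with the 5' stem-loop nearer stem I) for that construct's
#' labeling geometry.
#'
#' Constructs: `"stemI-stemII"` reports the relative orientation of stems I
#' and II (single 0.2 FRET state); `"stemII-5SL"` reports the 5' stem-loop
#' against stem II (states 0.2/0.3/0.4, population 1 = 0.2 since the
#' stem-I-proximal conformer is far from the stem II label);
#' `"stemI-5SL"` reports the 5' stem-loop against stem I (states
#' 0.3/0.4/0.5, population 1 = 0.4). Population 3 is a minor, putatively
#' misfolded species whose proportion stays constant across conditions.
#'
#' @return data.frame with one row per (construct, condition).
#' @export
fret_fixtures <- function() {
  rows <- list(
    list("stemI-stemII", "naked",          108L, c(0.2), c(1), NA_integer_),
    list("stemII-5SL",   "naked",          102L, c(0.2, 0.3, 0.4), c(0.44, 0.45, 0.11), 1L),
    list("stemII-5SL",   "+Snu13",         106L, c(0.2, 0.3, 0.4), c(0.44, 0.45, 0.11), 1L),
    list("stemII-5SL",   "+Prp31",         107L, c(0.2, 0.3, 0.4), c(0.28, 0.61, 0.11), 1L),
    list("stemII-5SL",   "+Prp3/4",        105L, c(0.2, 0.3, 0.4), c(0.58, 0.31, 0.11), 1L),
    list("stemII-5SL",   "+Snu13+Prp31",   103L, c(0.2, 0.3, 0.4), c(0.32, 0.57, 0.11), 1L),
    list("stemI-5SL",    "naked",          105L, c(0.3, 0.4, 0.5), c(0.41, 0.51, 0.08), 2L)
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(construct = r[[1]], condition = r[[2]], n_molecules = r[[3]],
               state_means = I(list(r[[4]])), weights = I(list(r[[5]])),
               population1_component = r[[6]], stringsAsFactors = FALSE)
  }))
}

#' Build a trace-simulation config for a bundled fixture
#' @param construct,condition row selector for [fret_fixtures()].
#' @param seed simulation seed.
#' @param n_molecules override of the fixture's ensemble size.
#' @param ... further overrides passed to [trace_sim_config()].
#' @export
fixture_config <- function(construct, condition = "naked", seed = 1L,
                           n_molecules = NULL, ...) {
  fx <- fret_fixtures()
  row <- fx[fx$construct == construct & fx$condition == condition, ]
  if (nrow(row) != 1L)
    stop(sprintf("unknown fixture %s / %s; see fret_fixtures()", construct, condition),
         call. = FALSE)
  trace_sim_config(states = data.frame(fret_mean = row$state_means[[1]],
                                       weight = row$weights[[1]]),
                   n_molecules = n_molecules %||% row$n_molecules,
                   seed = seed, ...)
}

#' Run the full trace-to-populations analysis on an ensemble
#'
#' QC selection, static/dynamic classification, two-stage Gaussian mixture
#' fit of the pooled FRET histogram, per-molecule assignment, and
#' Forster-distance estimates per component.
#'
#' @param traces tidy trace data.frame (simulated or read from CSV).
#' @param k number of mixture components.
#' @param condition condition label carried into the summary.
#' @param policy a [qc_policy()].
#' @param forster a [forster_params()].
#' @param seed seed for the assignment bootstrap.
#' @return list: `summary` (`population_summary`), `model`
#'   (`mixture_model`), `distances`, `qc` (per-molecule table),
#'   `reason_tally`.
#' @export
analyze_ensemble <- function(traces, k, condition = "condition",
                             policy = qc_policy(), forster = forster_params(),
                             seed = 1L) {
  fts <- qc_select(traces, policy)
  fts <- classify_static_ensemble(fts)
  model <- fit_mixture_two_stage(fts, k)
  summary <- assign_molecules(fts, model, condition = condition, seed = seed)
  list(summary = summary,
       model = model,
       distances = estimate_distances(model, forster),
       qc = qc_table(fts),
       reason_tally = attr(fts, "reason_tally"))
}

#' Run the configured pipeline stages
#'
#' Executes, in dependency order, whichever stages the config describes:
#' a smFRET branch (`trace_sim` -> QC -> populations -> geometry) and/or a
#' binding branch (`titration_sim` -> Hill fits -> combined affinity). All
#' randomness flows from the stage configs' seeds; outputs are
#' deterministic and, when `out_dir` is given, written as CSV/JSON.
#'
#' @param config list with optional elements `trace_sim`
#'   ([trace_sim_config()]), `k` (components; default number of configured
#'   states), `condition`, `qc` ([qc_policy()]), `forster`
#'   ([forster_params()]), `assignment` (state-assignment mode for the
#'   simulator), `titration_sim` ([titration_sim_config()]), `fix_n`
#'   (passed to [fit_hill()]), `out_dir`.
#' @return object of class `run_report`: per-stage summary tables plus the
#'   config and package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  report <- list(version = as.character(utils::packageVersion("fret3wj")),
                 config = config, stages = character(0))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  if (!is.null(config$trace_sim)) {
    sim <- config$trace_sim
    if (!inherits(sim, "trace_sim_config"))
      stop("stage 'trace_sim' failed: config$trace_sim is not a trace_sim_config",
           call. = FALSE)
    ens <- simulate_ensemble(sim, assignment = config$assignment %||% "multinomial")
    k <- config$k %||% nrow(sim$states)
    ana <- tryCatch(
      analyze_ensemble(ens$traces, k,
                       condition = config$condition %||% "condition",
                       policy = config$qc %||% qc_policy(),
                       forster = config$forster %||% forster_params(),
                       seed = sim$seed),
      error = function(e) stop(sprintf("stage 'trace_analysis' failed: %s",
                                       conditionMessage(e)), call. = FALSE))
    report$populations <- ana$summary$fractions
    report$condition <- ana$summary$condition
    report$n_molecules <- ana$summary$n_molecules
    report$mixture <- ana$model$components
    report$distances <- ana$distances
    report$qc_tally <- as.list(ana$reason_tally)
    report$ground_truth_weights <- sim$states$weight
    report$stages <- c(report$stages, "simulate", "trace_analysis",
                       "population_analysis", "junction_geometry")
    if (!is.null(out_dir)) {
      write_traces(ens, file.path(out_dir, "traces.csv"))
      write.csv(ana$qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
      write.csv(ana$summary$fractions, file.path(out_dir, "populations.csv"),
                row.names = FALSE)
      write.csv(ana$model$components, file.path(out_dir, "mixture.csv"),
                row.names = FALSE)
      write.csv(ana$distances, file.path(out_dir, "distances.csv"),
                row.names = FALSE)
    }
  }

  if (!is.null(config$titration_sim)) {
    tsim <- config$titration_sim
    if (!inherits(tsim, "titration_sim_config"))
      stop("stage 'titration_sim' failed: config$titration_sim is not a titration_sim_config",
           call. = FALSE)
    tt <- simulate_titration(tsim)
    fits <- lapply(split(tt, tt$replicate_id), fit_hill, fix_n = config$fix_n)
    report$hill_fits <- do.call(rbind, lapply(names(fits), function(id) {
      f <- fits[[id]]
      data.frame(replicate_id = id, K_d_app_M = f$params$K_d_app,
                 se_K_d_app_M = f$se[["K_d_app"]], n = f$params$n,
                 a = f$params$a, b = f$params$b, rss = f$rss,
                 stringsAsFactors = FALSE)
    }))
    if (length(fits) >= 2L) {
      comb <- combine_replicates(fits)
      report$combined_affinity <- data.frame(K_d_app_M = comb$K_d_app_mean,
                                             K_d_app_sd_M = comb$K_d_app_sd,
                                             n_mean = comb$n_mean, n_sd = comb$n_sd,
                                             n_replicates = comb$n_replicates)
    }
    report$stages <- c(report$stages, "titration_sim", "binding_analysis")
    if (!is.null(out_dir)) {
      write_titration(tt, file.path(out_dir, "titration.csv"))
      write.csv(report$hill_fits, file.path(out_dir, "hill_fits.csv"),
                row.names = FALSE)
    }
  }

  if (length(report$stages) == 0L)
    stop("config describes no runnable stage (need trace_sim and/or titration_sim)",
         call. = FALSE)
  class(report) <- "run_report"
  if (!is.null(out_dir))
    jsonlite::write_json(unclass(report)[setdiff(names(report), "config")],
                         file.path(out_dir, "report.json"),
                         dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report v%s: stages %s>\n", x$version,
              paste(x$stages, collapse = " -> ")))
  if (!is.null(x$populations)) {
    cat(sprintf("condition '%s' (%d molecules):\n", x$condition, x$n_molecules))
    print(x$populations)
  }
  if (!is.null(x$comparison)) print(x$comparison)
  if (!is.null(x$combined_affinity)) print(x$combined_affinity)
  invisible(x)
}

#' Reproduce a bundled study fixture end-to-end
#'
#' Runs the matching synthetic fixture through the full pipeline and emits
#' a side-by-side table of reference (ground-truth) values against the
#' recovered values. The smFRET fixtures use proportional state assignment
#' so the simulated ensemble embodies the advertised population
#' percentages exactly (see [simulate_ensemble()]).
#'
#' Cases: `"figure2"` (stems I/II single 0.2-FRET state; recovered mean
#' FRET and Forster distance vs the 76 A coaxial-stacking prediction),
#' `"figure3"` (stem II / 5' stem-loop three-state ensembles under all
#' protein conditions), `"figure4"` (stem I / 5' stem-loop naked
#' ensemble), `"table1"` (noiseless Hill-fit recovery of every reference
#' affinity row).
#'
#' @param case one of `"figure2"`, `"figure3"`, `"figure4"`, `"table1"`.
#' @param seed integer seed.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return a `run_report` with a `comparison_table` of reference vs
#'   recovered values.
#' @export
repro <- function(case = c("figure2", "figure3", "figure4", "table1"),
                  seed = 1L, out_dir = NULL) {
  case <- tryCatch(match.arg(case), error = function(e)
    stop("unknown case; available: figure2, figure3, figure4, table1",
         call. = FALSE))
  fx <- fret_fixtures()

  if (case == "figure2") {
    rep_ <- run_pipeline(list(
      trace_sim = fixture_config("stemI-stemII", "naked", seed = seed),
      assignment = "proportional", k = 1L, condition = "stems I+II naked",
      out_dir = out_dir))
    arms <- list(helix_arm("stem I", 10), helix_arm("stem II", 17),
                 helix_arm("5' stem-loop", 8))
    meas <- data.frame(arm_a = "stem I", arm_b = "stem II",
                       distance = rep_$distances$distance_A[1])
    rep_$hypotheses <- rank_stacking_models(arms, meas)
    rep_$comparison_table <- data.frame(
      quantity = c("FRET peak", "inter-label distance (A)",
                   "stem I + stem II contour length (A)"),
      reference = c(0.2, 76, 76),
      recovered = c(rep_$mixture$mean[1], rep_$distances$distance_A[1],
                    rep_$hypotheses$predicted_label_distance[1]))
    return(rep_)
  }

  if (case %in% c("figure3", "figure4")) {
    construct <- if (case == "figure3") "stemII-5SL" else "stemI-5SL"
    rows <- fx[fx$construct == construct, ]
    if (case == "figure4") rows <- rows[rows$condition == "naked", ]
    tables <- lapply(seq_len(nrow(rows)), function(i) {
      rr <- run_pipeline(list(
        trace_sim = fixture_config(construct, rows$condition[i],
                                   seed = seed + i - 1L),
        assignment = "proportional", condition = rows$condition[i],
        out_dir = if (is.null(out_dir)) NULL
                  else file.path(out_dir, gsub("[^A-Za-z0-9]+", "_", rows$condition[i]))))
      data.frame(construct = construct, condition = rows$condition[i],
                 component = rr$populations$component,
                 mean_fret = rr$populations$mean_fret,
                 reference_pct = 100 * rows$weights[[i]],
                 recovered_pct = 100 * rr$populations$fraction,
                 se_pct = 100 * rr$populations$se)
    })
    rep_ <- structure(list(version = as.character(utils::packageVersion("fret3wj")),
                           stages = c("simulate", "trace_analysis",
                                      "population_analysis"),
                           comparison_table = do.call(rbind, tables)),
                      class = "run_report")
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write.csv(rep_$comparison_table,
                file.path(out_dir, paste0(case, "_comparison.csv")),
                row.names = FALSE)
    }
    return(rep_)
  }

  # table1: noiseless round-trip of every reference affinity row
  ref <- reference_affinities()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    truth <- hill_params(ref$kd_nM[i] * 1e-9, ref$hill_n[i])
    tt <- simulate_titration(titration_sim_config(truth, noise_sigma = 0,
                                                  n_replicates = 1L,
                                                  seed = seed + i))
    fit <- fit_hill(tt, fix_n = if (ref$n_fixed[i]) ref$hill_n[i] else NULL)
    data.frame(complex = ref$complex[i], titrated = ref$titrated[i],
               reference_kd_nM = ref$kd_nM[i],
               recovered_kd_nM = fit$params$K_d_app * 1e9,
               reference_n = ref$hill_n[i], recovered_n = fit$params$n,
               n_fixed = ref$n_fixed[i], stringsAsFactors = FALSE)
  })
  rep_ <- structure(list(version = as.character(utils::packageVersion("fret3wj")),
                         stages = c("titration_sim", "binding_analysis"),
                         comparison_table = do.call(rbind, rows)),
                    class = "run_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(rep_$comparison_table, file.path(out_dir, "table1_comparison.csv"),
              row.names = FALSE)
  }
  rep_
}

#' Simulate pseudo-replicate ensembles and compare a population fraction
#'
#' Convenience wrapper for condition-level statistics: simulates `n_rep`
#' independent ensembles per condition (multinomial state assignment, so
#' replicate fractions vary as real movie-level subsets would), analyzes
#' each end-to-end, and Welch-tests the chosen component's fractions.
#'
#' @param construct,condition_a,condition_b fixture selectors (see
#'   [fret_fixtures()]).
#' @param n_rep replicates per condition.
#' @param n_molecules molecules per replicate ensemble.
#' @param component mixture component to compare (default: the construct's
#'   population-1 component).
#' @param seed base seed; replicate r of condition c uses
#'   `seed + 1000 * c + r`.
#' @return list with `comparison` (`condition_comparison`), `fractions_a`,
#'   `fractions_b`.
#' @export
compare_fixture_conditions <- function(construct, condition_a, condition_b,
                                       n_rep = 6L, n_molecules = 100L,
                                       component = NULL, seed = 1L) {
  fx <- fret_fixtures()
  comp <- component %||%
    fx$population1_component[fx$construct == construct & fx$condition == condition_a]
  one <- function(cond, c_idx) {
    vapply(seq_len(n_rep), function(r) {
      cfg <- fixture_config(construct, cond, seed = seed + 1000L * c_idx + r,
                            n_molecules = n_molecules)
      rr <- run_pipeline(list(trace_sim = cfg, assignment = "multinomial",
                              condition = cond))
      rr$populations$fraction[comp]
    }, numeric(1))
  }
  fa <- one(condition_a, 1L)
  fb <- one(condition_b, 2L)
  list(comparison = compare_conditions(fa, fb, condition_a, condition_b, comp),
       fractions_a = fa, fractions_b = fb)
}
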