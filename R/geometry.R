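# Junction geometry: Forster-equation distance conversion, A-form helix
# contour lengths, and ranking of coaxial-stacking hypotheses for a
# three-way junction.

#' Forster parameters for a dye pair
#' @param R0 Forster radius in Angstrom (60 for Cy3/Cy5).
#' @export
forster_params <- function(R0 = 60) {
  if (R0 <= 0) .stop_config("R0 must be positive")
  structure(list(R0 = R0), class = "forster_params")
}

#' Convert apparent FRET efficiency to an inter-fluorophore distance
#'
#' `R = R0 * ((1 - E) / E)^(1/6)`.
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param params a [forster_params()].
#' @return distance in Angstrom.
#' @export
fret_to_distance <- function(E, params = forster_params()) {
  if (any(E <= 0 | E >= 1))
    stop("E must lie strictly inside (0, 1): the Forster distance diverges at the endpoints",
         call. = FALSE)
  params$R0 * ((1 - E) / E)^(1 / 6)
}

#' Convert a distance to FRET efficiency (inverse Forster relation)
#'
#' `E = 1 / (1 + (R / R0)^6)`; strictly decreasing in `R`.
#'
#' @param R distance in Angstrom, positive.
#' @inheritParams fret_to_distance
#' @export
distance_to_fret <- function(R, params = forster_params()) {
  if (any(R <= 0)) stop("R must be positive", call. = FALSE)
  1 / (1 + (R / params$R0)^6)
}

#' Define a helical arm of the junction
#' @param name arm label, e.g. `"stem I"`, `"stem II"`, `"5' stem-loop"`.
#' @param length_bp number of base pairs.
#' @param rise_per_bp helical rise per base pair in Angstrom; the A-form
#'   default of 2.8 gives 28 A for a 10 bp stem.
#' @export
helix_arm <- function(name, length_bp, rise_per_bp = 2.8) {
  if (length_bp < 0) .stop_config("length_bp must be >= 0")
  if (rise_per_bp <= 2.0 || rise_per_bp >= 3.5)
    .stop_config("rise_per_bp must lie in (2.0, 3.5) Angstrom")
  structure(list(name = name, length_bp = length_bp, rise_per_bp = rise_per_bp),
            class = "helix_arm")
}

#' Contour length of a helical arm
#' @param arm a [helix_arm()].
#' @return length in Angstrom (`length_bp * rise_per_bp`).
#' @export
helix_contour_length <- function(arm) {
  stopifnot(inherits(arm, "helix_arm"))
  arm$length_bp * arm$rise_per_bp
}

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = " + ")

#' Default mapping from stacked arm pair to junction family
#'
#' Three-way junctions with two coaxially stacked helices fall into
#' families A/B/C by which pair stacks; this mapping encodes the convention
#' used for the U4/U6 junction (stems I+II stacked = family A, stem I with
#' the 5' stem-loop = family B) and is configuration, not a hard-coded
#' conclusion.
#' @export
default_family_map <- function() {
  c("stem I + stem II" = "A",
    "5' stem-loop + stem I" = "B",
    "5' stem-loop + stem II" = "C")
}

#' Predicted label distance for two arms meeting at a given angle
#'
#' Law of cosines on the junction: `angle_deg = 180` is collinear
#' (coaxial stacking) and the prediction reduces to the sum of the contour
#' lengths.
#' @param L1,L2 contour lengths in Angstrom.
#' @param angle_deg inter-arm angle in degrees (0-180).
#' @export
predict_label_distance <- function(L1, L2, angle_deg = 180) {
  theta <- angle_deg * pi / 180
  sqrt(pmax(L1^2 + L2^2 - 2 * L1 * L2 * cos(theta), 0))
}

#' Rank coaxial-stacking hypotheses against measured distances
#'
#' For each unordered pair of arms the collinear (coaxially stacked) model
#' predicts an end-to-end label distance equal to the sum of the two
#' contour lengths; its residual is the summed absolute deviation from the
#' measurements involving that pair. With `include_bent = TRUE` a bent
#' alternative per pair is added, with the inter-arm angle chosen to
#' minimize the same residual. Hypotheses are returned sorted by residual
#' (pairs with no matching measurement sort last, residual `NA`).
#'
#' @param arms list of three [helix_arm()] objects with distinct names.
#' @param measurements data.frame with columns `arm_a`, `arm_b`,
#'   `distance` (Angstrom) giving measured inter-label distances between
#'   the outer ends of two arms.
#' @param family_map named character vector mapping `"<arm> + <arm>"`
#'   (alphabetical) to family labels; see [default_family_map()].
#' @param include_bent also rank best-fit bent geometries.
#' @return data.frame of hypotheses: `stacked_pair`, `geometry`,
#'   `angle_deg`, `predicted_label_distance`, `residual`, `family`,
#'   `n_measurements`.
#' @export
rank_stacking_models <- function(arms, measurements,
                                 family_map = default_family_map(),
                                 include_bent = FALSE) {
  stopifnot(length(arms) == 3L, nrow(measurements) >= 1L)
  nm <- vapply(arms, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("arm names must be distinct", call. = FALSE)
  bad <- !(measurements$arm_a %in% nm) | !(measurements$arm_b %in% nm)
  if (any(bad))
    stop(sprintf("measurement references unknown arm(s): %s",
                 paste(unique(c(measurements$arm_a[bad], measurements$arm_b[bad])),
                       collapse = ", ")), call. = FALSE)
  L <- setNames(vapply(arms, helix_contour_length, numeric(1)), nm)
  pairs <- utils::combn(sort(nm), 2, simplify = FALSE)
  meas_key <- mapply(.pair_key, measurements$arm_a, measurements$arm_b)

  rows <- lapply(pairs, function(pr) {
    key <- .pair_key(pr[1], pr[2])
    d <- measurements$distance[meas_key == key]
    fam <- if (key %in% names(family_map)) unname(family_map[key]) else NA_character_
    pred_lin <- L[[pr[1]]] + L[[pr[2]]]
    out <- data.frame(stacked_pair = key, geometry = "coaxial", angle_deg = 180,
                      predicted_label_distance = pred_lin,
                      residual = if (length(d)) sum(abs(pred_lin - d)) else NA_real_,
                      family = fam, n_measurements = length(d),
                      stringsAsFactors = FALSE)
    if (include_bent && length(d)) {
      obj <- function(theta) sum(abs(predict_label_distance(L[[pr[1]]], L[[pr[2]]], theta) - d))
      opt <- optimize(obj, interval = c(0, 180))
      out <- rbind(out, data.frame(
        stacked_pair = key, geometry = "bent", angle_deg = opt$minimum,
        predicted_label_distance = predict_label_distance(L[[pr[1]]], L[[pr[2]]], opt$minimum),
        residual = opt$objective, family = NA_character_,
        n_measurements = length(d), stringsAsFactors = FALSE))
    }
    out
  })
  res <- do.call(rbind, rows)
  # sort by residual ascending, NA (unmeasured pairs) last; ties broken by
  # pair name for order-invariance
  res <- res[order(is.na(res$residual), res$residual, res$stacked_pair,
                   res$geometry), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Convert fitted mixture components to distances with propagated errors
#'
#' Applies the Forster relation to each component mean and propagates the
#' mean's standard error to first order:
#' `se_R = |dR/dE| * se_E` with `dR/dE = -R0/(6 E^2) * ((1-E)/E)^(-5/6)`.
#' Components whose mean lies outside (0, 1) are flagged and their distance
#' omitted.
#'
#' @param model a `mixture_model` (components carry `se_mean` when the fit
#'   provided one).
#' @param params a [forster_params()].
#' @return data.frame `component`, `mean_fret`, `se_fret`, `distance_A`,
#'   `se_distance_A`, `flagged`.
#' @export
estimate_distances <- function(model, params = forster_params()) {
  stopifnot(inherits(model, "mixture_model"))
  comp <- model$components
  out <- data.frame(component = seq_len(nrow(comp)),
                    mean_fret = comp$mean,
                    se_fret = comp$se_mean,
                    distance_A = NA_real_,
                    se_distance_A = NA_real_,
                    flagged = comp$mean <= 0 | comp$mean >= 1)
  ok <- !out$flagged
  E <- comp$mean[ok]
  out$distance_A[ok] <- fret_to_distance(E, params)
  dRdE <- params$R0 / 6 * ((1 - E) / E)^(-5 / 6) / E^2
  se <- comp$se_mean[ok]
  out$se_distance_A[ok] <- ifelse(is.na(se), NA_real_, abs(dRdE) * se)
  out
}
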