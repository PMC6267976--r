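#' Fit a smooth CWM trait-environment model
#'
#' Models one community-weighted mean trait as an additive smooth function of
#' soil pH and pine basal area,
#' \deqn{CWM = \beta_0 + f_1(pH) + f_2(BA) + \varepsilon,\quad
#'       \varepsilon \sim N(0, \sigma^2),}
#' with penalized cubic regression splines per predictor (basis dimension
#' k = 10, the "maximum smoothing" setting of [mgcv::gam()]) and smoothness
#' selected by generalized cross-validation. Samples with missing CWM
#' (flagged all-zero quadrats) are dropped before fitting.
#'
#' @param cwm a `cwm_table` with a column named `trait_name`.
#' @param env an `environment_table` whose `sample_id`s match `cwm$unit_id`.
#' @param trait_name name of the trait column to model.
#' @param k basis dimension per smooth term (default 10).
#' @param sp optional fixed smoothing parameters (length 2); by default
#'   smoothness is selected by generalized cross-validation. Very large
#'   values penalize the smooths to the ordinary least-squares plane.
#' @return a `cwm_fit` object: the underlying [mgcv::gam()] fit plus trait
#'   name, adjusted R-squared, approximate per-term tests, training ranges
#'   of both predictors, and the training data (kept so fits can be
#'   serialized and reconstructed exactly).
#' @seealso [predict_cwm()], [write_cwm_fit()]
#' @export
fit_cwm_model <- function(cwm, env, trait_name, k = 10, sp = NULL) {
  if (!trait_name %in% names(cwm)) {
    stop("trait '", trait_name, "' not found in CWM table", call. = FALSE)
  }
  idx <- match(cwm$unit_id, env$sample_id)
  if (anyNA(idx)) {
    stop("CWM units missing from environment table: ",
         paste(utils::head(cwm$unit_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  dat <- data.frame(
    y = cwm[[trait_name]],
    soil_ph = env$soil_ph[idx],
    pine_ba = env$pine_ba[idx]
  )
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 20) {
    stop("need at least 20 samples with non-missing CWM; got ", n, call. = FALSE)
  }
  if (stats::var(dat$soil_ph) == 0 || stats::var(dat$pine_ba) == 0) {
    stop("degenerate design: an environmental predictor is constant", call. = FALSE)
  }
  degenerate_response <- stats::var(dat$y) == 0
  if (n <= 2 * k) {
    stop("fewer samples (", n, ") than total basis size (", 2 * k, ")", call. = FALSE)
  }
  fit <- mgcv::gam(
    y ~ s(soil_ph, bs = "cr", k = k) + s(pine_ba, bs = "cr", k = k),
    data = dat, family = stats::gaussian(), method = "GCV.Cp", sp = sp
  )
  sm <- summary(fit)
  structure(list(
    trait_name = trait_name,
    gam = fit,
    basis_dim = k,
    smoothing_params = as.numeric(fit$sp),
    coefficients = stats::coef(fit),
    adj_r2 = if (degenerate_response) 0 else as.numeric(sm$r.sq),
    term_tests = data.frame(
      term = rownames(sm$s.table),
      edf = sm$s.table[, "edf"],
      f = sm$s.table[, "F"],
      p_value = sm$s.table[, "p-value"],
      row.names = NULL
    ),
    training_ranges = list(
      soil_ph = range(dat$soil_ph),
      pine_ba = range(dat$pine_ba)
    ),
    degenerate = degenerate_response,
    n = n,
    training_data = dat
  ), class = "cwm_fit")
}

#' @export
print.cwm_fit <- function(x, ...) {
  cat("CWM trait-environment model: ", x$trait_name, "\n", sep = "")
  cat("  n = ", x$n, ", basis k = ", x$basis_dim,
      ", adj. R-squared = ", formatC(x$adj_r2, digits = 3, format = "f"),
      if (x$degenerate) " (degenerate: constant response)", "\n", sep = "")
  cat("  approximate term tests:\n")
  print(x$term_tests, digits = 3)
  invisible(x)
}

#' Predict a CWM trait value for a new environment
#'
#' Evaluates the fitted additive surface at the given soil pH and pine basal
#' area. Predictions outside the training range of either predictor are
#' returned but flagged, because the spline extrapolates linearly there;
#' the sun treatment (BA = 0) sits at the edge of typical field gradients,
#' so extrapolation is allowed rather than refused.
#'
#' @param fit a `cwm_fit` from [fit_cwm_model()].
#' @param ph soil pH value(s).
#' @param ba pine basal area value(s), m^2 ha^-1.
#' @return data frame with columns `soil_ph`, `pine_ba`, `cwm` (the
#'   prediction) and `extrapolated` (logical flag).
#' @export
predict_cwm <- function(fit, ph, ba) {
  stopifnot(inherits(fit, "cwm_fit"))
  if (length(ph) != length(ba)) {
    n <- max(length(ph), length(ba))
    ph <- rep_len(ph, n); ba <- rep_len(ba, n)
  }
  if (anyNA(ph) || anyNA(ba) || any(!is.finite(ph)) || any(!is.finite(ba))) {
    stop("prediction environments must be finite", call. = FALSE)
  }
  newdata <- data.frame(soil_ph = ph, pine_ba = ba)
  pred <- as.numeric(mgcv::predict.gam(fit$gam, newdata = newdata))
  rng <- fit$training_ranges
  extrap <- ph < rng$soil_ph[1] | ph > rng$soil_ph[2] |
    ba < rng$pine_ba[1] | ba > rng$pine_ba[2]
  if (any(extrap)) {
    warning("prediction outside training range for ", sum(extrap),
            " environment(s); spline extrapolates linearly", call. = FALSE)
  }
  data.frame(soil_ph = ph, pine_ba = ba, cwm = pred, extrapolated = extrap)
}

#' Predict the full CWM constraint table for a set of treatments
#'
#' Convenience wrapper: evaluates one fitted model per trait at each
#' treatment's environment, producing the constraint table consumed by
#' [solve_maxent()].
#'
#' @param fits named list of `cwm_fit` objects (one per trait).
#' @param treatments data frame with columns `treatment`, `soil_ph`, `pine_ba`.
#' @return a `cwm_table` with `unit_id` = treatment labels and one column per
#'   trait, plus an `extrapolated` attribute (logical matrix).
#' @export
predict_cwm_table <- function(fits, treatments) {
  stopifnot(all(c("treatment", "soil_ph", "pine_ba") %in% names(treatments)))
  preds <- lapply(fits, function(f) {
    predict_cwm(f, treatments$soil_ph, treatments$pine_ba)
  })
  out <- data.frame(unit_id = as.character(treatments$treatment))
  extrap <- matrix(FALSE, nrow(treatments), length(fits),
                   dimnames = list(out$unit_id, names(fits)))
  for (nm in names(fits)) {
    out[[fits[[nm]]$trait_name]] <- preds[[nm]]$cwm
    extrap[, nm] <- preds[[nm]]$extrapolated
  }
  attr(out, "extrapolated") <- extrap
  class(out) <- c("cwm_table", "data.frame")
  out
}

#' Serialize a CWM fit to JSON
#'
#' Writes the trait name, basis dimension, selected smoothing parameters,
#' coefficients, adjusted R-squared, training ranges and the training data.
#' [read_cwm_fit()] reconstructs the fit by refitting the same spline bases
#' to the stored data with the smoothing parameters fixed, which reproduces
#' the original coefficients and predictions; calibration and prediction can
#' therefore run as separate steps.
#'
#' @param fit a `cwm_fit`
#' @param path output JSON path
#' @return `path`, invisibly.
#' @export
write_cwm_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cwm_fit"))
  doc <- list(
    trait_name = fit$trait_name,
    basis_dim = fit$basis_dim,
    smoothing_params = fit$smoothing_params,
    coefficients = as.list(fit$coefficients),
    adj_r2 = fit$adj_r2,
    training_ranges = fit$training_ranges,
    degenerate = fit$degenerate,
    n = fit$n,
    training_data = fit$training_data
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reconstruct a CWM fit from JSON
#' @param path JSON file written by [write_cwm_fit()]
#' @return a `cwm_fit` equivalent to the serialized one.
#' @export
read_cwm_fit <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dat <- as.data.frame(doc$training_data)
  k <- doc$basis_dim
  fit <- mgcv::gam(
    y ~ s(soil_ph, bs = "cr", k = k) + s(pine_ba, bs = "cr", k = k),
    data = dat, family = stats::gaussian(),
    sp = as.numeric(doc$smoothing_params)
  )
  sm <- summary(fit)
  structure(list(
    trait_name = doc$trait_name,
    gam = fit,
    basis_dim = k,
    smoothing_params = as.numeric(fit$sp),
    coefficients = stats::coef(fit),
    adj_r2 = if (isTRUE(doc$degenerate)) 0 else as.numeric(sm$r.sq),
    term_tests = data.frame(
      term = rownames(sm$s.table),
      edf = sm$s.table[, "edf"],
      f = sm$s.table[, "F"],
      p_value = sm$s.table[, "p-value"],
      row.names = NULL
    ),
    training_ranges = list(
      soil_ph = as.numeric(doc$training_ranges$soil_ph),
      pine_ba = as.numeric(doc$training_ranges$pine_ba)
    ),
    degenerate = isTRUE(doc$degenerate),
    n = nrow(dat),
    training_data = dat
  ), class = "cwm_fit")
}
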