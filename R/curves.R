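#' Specification of a synthetic assay curve
#'
#' @param model "hill" (EMSA-style protein titration; params `K_D`, `n`),
#'   "isotherm_1to1" (MST-style ligand titration at fixed protein; params
#'   `K_D`, `protein_total`, same units as x) or "growth_lag_exp" (lag then
#'   exponential OD curve; params `od0`, `lag_h`, `doubling_h`, `plateau`).
#' @param true_params named list of the generating parameters.
#' @param x_values strictly increasing non-negative series (concentration or
#'   time).
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @param seed integer RNG seed.
#' @param x_unit,y_unit unit tags carried through to the data.
#' @return object of class `CurveSpec`.
#' @export
curve_spec <- function(model = c("hill", "isotherm_1to1", "growth_lag_exp"),
                       true_params, x_values, noise_cv = 0.05, seed = 1L,
                       x_unit = NULL, y_unit = NULL) {
  model <- match.arg(model)
  assert_that(is.numeric(x_values) && all(x_values >= 0),
              "x_values must be non-negative")
  assert_that(all(diff(x_values) > 0), "x_values must be strictly increasing")
  assert_that(noise_cv >= 0, "noise_cv must be >= 0")
  need <- switch(model,
                 hill = c("K_D", "n"),
                 isotherm_1to1 = c("K_D", "protein_total"),
                 growth_lag_exp = c("od0", "lag_h", "doubling_h", "plateau"))
  assert_that(all(need %in% names(true_params)),
              paste("true_params must contain",
                    paste(need, collapse = ", "), "for model", model))
  x_unit <- x_unit %||% switch(model, hill = "nM", isotherm_1to1 = "uM",
                               growth_lag_exp = "h")
  y_unit <- y_unit %||% switch(model, hill = "fraction",
                               isotherm_1to1 = "fraction",
                               growth_lag_exp = "OD")
  structure(list(model = model, true_params = true_params,
                 x_values = x_values, noise_cv = noise_cv,
                 seed = as.integer(seed), x_unit = x_unit, y_unit = y_unit),
            class = "CurveSpec")
}

# noiseless model evaluation for a CurveSpec
eval_curve_model <- function(cspec) {
  p <- cspec$true_params
  x <- cspec$x_values
  switch(cspec$model,
         hill = hill_model(x, p$K_D, p$n),
         isotherm_1to1 = isotherm_model(p$protein_total, x, p$K_D),
         growth_lag_exp = growth_lag_exp_model(x, p$od0, p$lag_h,
                                               p$doubling_h, p$plateau))
}

#' Lag + exponential growth model
#'
#' OD stays at `od0` until `lag_h`, then doubles every `doubling_h` hours
#' until capped at `plateau`.
#'
#' @param t time, hours.
#' @param od0 initial optical density.
#' @param lag_h lag duration, hours.
#' @param doubling_h doubling time in the exponential window, hours.
#' @param plateau carrying-capacity OD.
#' @return OD values.
#' @export
growth_lag_exp_model <- function(t, od0, lag_h, doubling_h, plateau) {
  assert_that(od0 > 0 && doubling_h > 0 && plateau >= od0 && lag_h >= 0,
              "invalid growth parameters")
  pmin(od0 * 2^(pmax(0, t - lag_h) / doubling_h), plateau)
}

#' Generate a noisy synthetic assay curve
#'
#' `y = model(x; true_params) * (1 + eps)` with `eps ~ Normal(0, noise_cv)`,
#' seeded. Responses are positive, so the noise is multiplicative.
#'
#' @param cspec a [curve_spec()].
#' @return object of class `CurveData`: list with `x`, `y`, `y_true`,
#'   `model`, `true_params`, `x_unit`, `y_unit`, `spec`.
#' @export
generate_curve <- function(cspec) {
  assert_that(inherits(cspec, "CurveSpec"), "cspec must be a CurveSpec")
  y_true <- eval_curve_model(cspec)
  set.seed(cspec$seed)
  eps <- stats::rnorm(length(cspec$x_values), 0, cspec$noise_cv)
  structure(list(x = cspec$x_values, y = y_true * (1 + eps), y_true = y_true,
                 model = cspec$model, true_params = cspec$true_params,
                 x_unit = cspec$x_unit, y_unit = cspec$y_unit, spec = cspec),
            class = "CurveData")
}

#' Read/write assay curves as CSV
#'
#' @param curve a `CurveData` (or data.frame with x, y).
#' @param path CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(x = curve$x, y = curve$y), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param x_unit,y_unit unit tags to attach.
#' @export
read_curve_csv <- function(path, x_unit = NA_character_,
                           y_unit = NA_character_) {
  df <- utils::read.csv(path)
  assert_that(all(c("x", "y") %in% names(df)), "CSV must have columns x, y")
  structure(list(x = df$x, y = df$y, y_true = NULL, model = NA_character_,
                 true_params = NULL, x_unit = x_unit, y_unit = y_unit),
            class = "CurveData")
}
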