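#' Hill binding model
#'
#' Fraction of probe bound at protein concentration `P`:
#' `f = P^n / (K_D^n + P^n)`. Half-saturation at `P = K_D`; `n` is the Hill
#' coefficient. This is the model used to extract apparent K_D values from
#' EMSA titrations of repressor against labelled operator DNA.
#'
#' @param P protein concentration(s), >= 0.
#' @param K_D apparent dissociation constant, > 0 (same units as P).
#' @param n Hill coefficient, > 0.
#' @return bound fraction in [0, 1).
#' @export
hill_model <- function(P, K_D, n = 1) {
  assert_that(all(P >= 0), "P must be >= 0")
  assert_that(K_D > 0, "K_D must be > 0")
  assert_that(n > 0, "n must be > 0")
  Pn <- P^n
  Pn / (K_D^n + Pn)
}

#' Exact 1:1 binding isotherm
#'
#' Fraction of protein in complex at total ligand `L_total` and total
#' protein `P_total`, from the quadratic solution of the 1:1 equilibrium:
#' `complex = ((P + L + K_D) - sqrt((P + L + K_D)^2 - 4 P L)) / 2`,
#' `f = complex / P_total`. Used for MST ligand titrations at fixed protein;
#' reduces to the simple isotherm `L / (K_D + L)` as `P_total -> 0`.
#'
#' @param P_total total protein concentration, > 0.
#' @param L_total total ligand concentration(s), >= 0.
#' @param K_D dissociation constant, >= 0 (all same units).
#' @return bound protein fraction in [0, 1].
#' @export
isotherm_model <- function(P_total, L_total, K_D) {
  assert_that(P_total > 0, "P_total must be > 0")
  assert_that(all(L_total >= 0), "L_total must be >= 0")
  assert_that(K_D >= 0, "K_D must be >= 0")
  s <- P_total + L_total + K_D
  complex <- (s - sqrt(pmax(s^2 - 4 * P_total * L_total, 0))) / 2
  pmin(pmax(complex / P_total, 0), 1)
}

#' Fit a binding curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) with a deterministic
#' initialization: `K_D` starts at the x value whose response is closest to
#' 0.5 and the Hill coefficient at 1. Standard errors come from the fit
#' Jacobian; non-convergence is flagged, never silent.
#'
#' @param curve a `CurveData` (or list/data.frame with `x`, `y`).
#' @param model "hill" or "isotherm_1to1".
#' @param protein_total fixed total protein for the isotherm model; defaults
#'   to the generator truth carried in `curve` when present.
#' @return object of class `BindingFit`: `model`, `K_D`, `K_D_se`, `hill_n`,
#'   `hill_n_se` (hill only), `residual_norm`, `converged`, `fit`.
#' @export
fit_binding <- function(curve, model = c("hill", "isotherm_1to1"),
                        protein_total = NULL) {
  model <- match.arg(model)
  x <- curve$x; y <- curve$y
  assert_that(length(x) >= 5, "need at least 5 titration points")
  if (max(y) - min(y) < sqrt(.Machine$double.eps))
    stop("degenerate data: all responses are equal", call. = FALSE)
  k0 <- x[which.min(abs(y - 0.5))]
  if (k0 <= 0) k0 <- min(x[x > 0])
  df <- data.frame(x = x, y = y)
  if (model == "hill") {
    fit <- minpack.lm::nlsLM(y ~ x^n / (K^n + x^n), data = df,
                             start = list(K = k0, n = 1),
                             lower = c(K = .Machine$double.eps, n = 1e-3),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    P <- protein_total %||% curve$true_params$protein_total
    assert_that(!is.null(P) && P > 0,
                "isotherm fit needs protein_total (> 0)")
    fit <- minpack.lm::nlsLM(y ~ isotherm_model(P, x, K), data = df,
                             start = list(K = k0),
                             lower = c(K = .Machine$double.eps),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  co <- summary(fit)$coefficients
  converged <- isTRUE(fit$convInfo$isConv)
  if (!converged)
    warning("binding fit did not converge", call. = FALSE)
  structure(
    list(model = model,
         K_D = unname(co["K", "Estimate"]),
         K_D_se = unname(co["K", "Std. Error"]),
         hill_n = if (model == "hill") unname(co["n", "Estimate"]) else NA_real_,
         hill_n_se = if (model == "hill") unname(co["n", "Std. Error"]) else NA_real_,
         residual_norm = sqrt(sum(stats::residuals(fit)^2)),
         converged = converged,
         x_unit = curve$x_unit %||% NA_character_,
         fit = fit),
    class = "BindingFit"
  )
}

#' @export
print.BindingFit <- function(x, ...) {
  cat("BindingFit (", x$model, "): K_D = ", signif(x$K_D, 4), " +/- ",
      signif(x$K_D_se, 3), " ", x$x_unit,
      if (x$model == "hill") paste0(", n = ", signif(x$hill_n, 3)) else "",
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' Affinity fold ratio
#'
#' `ratio = K_a / K_b` with the nearest integer fold, e.g. 1945/494 nM gives
#' 3.94 ("approximately fourfold") and 32.9/10.3 uM gives 3.19
#' ("approximately threefold").
#'
#' @param K_a,K_b dissociation constants, > 0.
#' @param units_a,units_b unit tags; must match.
#' @return list with `ratio` and `fold` (= round(ratio)).
#' @export
fold_ratio <- function(K_a, K_b, units_a = "nM", units_b = units_a) {
  assert_that(K_a > 0 && K_b > 0, "dissociation constants must be > 0")
  if (!identical(units_a, units_b))
    stop("unit mismatch: ", units_a, " vs ", units_b, call. = FALSE)
  ratio <- K_a / K_b
  list(ratio = ratio, fold = round(ratio))
}

#' Effector-release titration call
#'
#' Given bound fraction versus effector concentration (a nonincreasing
#' series within noise), returns the smallest tested concentration at which
#' the bound fraction has dropped to at most `threshold` — the package's
#' quantitative reading of "complete release" in gel-based titrations.
#'
#' @param curve a `CurveData` (or list with `x`, `y`): x = effector
#'   concentration (increasing), y = bound fraction.
#' @param threshold bound fraction regarded as fully released (default 0.05).
#' @return list with `released` (logical), `concentration` (NA when never
#'   released) and `threshold`.
#' @export
release_titration <- function(curve, threshold = 0.05) {
  x <- curve$x; y <- curve$y
  assert_that(length(x) == length(y) && length(x) >= 2,
              "need matched x/y series of length >= 2")
  if (y[length(y)] > y[1] + 1e-9)
    warning("series is increasing overall; not a release titration?",
            call. = FALSE)
  idx <- which(y <= threshold)
  if (length(idx) == 0)
    return(list(released = FALSE, concentration = NA_real_,
                threshold = threshold))
  list(released = TRUE, concentration = x[min(idx)], threshold = threshold)
}

#' Fit growth kinetics from an OD time series
#'
#' The growth rate is the slope of `ln(OD)` over the sliding window (default
#' 5 points) maximizing R^2 among positive-slope windows; doubling time is
#' `ln(2) / rate`. Lag time is, by default, the first time the smoothed OD
#' exceeds twice its initial value ("threshold" method, robust to plate
#' noise); a tangent-intercept estimate (where the exponential-window line
#' crosses the initial log-OD) is also available.
#'
#' @param curve a `CurveData` (or list with `x` = time in hours, `y` = OD).
#' @param window sliding-window width in points (default 5).
#' @param lag_method "threshold" (default) or "tangent".
#' @param smooth_k moving-average width for the lag threshold (default 3).
#' @return object of class `GrowthFit`: `doubling_time`, `growth_rate`,
#'   `lag_time` (hours), `window` (t_start, t_end), `r_squared`,
#'   `degenerate`.
#' @export
fit_growth <- function(curve, window = 5L,
                       lag_method = c("threshold", "tangent"),
                       smooth_k = 3L) {
  lag_method <- match.arg(lag_method)
  t <- curve$x; od <- curve$y
  assert_that(length(t) >= 8, "need at least 8 time points")
  if (any(od <= 0)) stop("non-positive OD values", call. = FALSE)
  ln_od <- log(od)
  n <- length(t)
  best <- list(r2 = -Inf, slope = NA_real_, icpt = NA_real_, i = NA_integer_)
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    tt <- t[idx]; yy <- ln_od[idx]
    sxx <- sum((tt - mean(tt))^2)
    if (sxx == 0) next
    slope <- sum((tt - mean(tt)) * (yy - mean(yy))) / sxx
    icpt <- mean(yy) - slope * mean(tt)
    ss_tot <- sum((yy - mean(yy))^2)
    if (ss_tot < .Machine$double.eps) next
    r2 <- 1 - sum((yy - (icpt + slope * tt))^2) / ss_tot
    if (slope > 0 && r2 > best$r2)
      best <- list(r2 = r2, slope = slope, icpt = icpt, i = i)
  }
  if (!is.finite(best$r2) || is.na(best$slope) || best$slope <= 0) {
    return(structure(list(doubling_time = NA_real_, growth_rate = NA_real_,
                          lag_time = NA_real_, window = c(NA_real_, NA_real_),
                          r_squared = NA_real_, degenerate = TRUE),
                     class = "GrowthFit"))
  }
  rate <- best$slope
  # centered moving average, shrinking at the edges
  half <- (smooth_k - 1L) %/% 2L
  smoothed <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(od[lo:hi])
  }, numeric(1))
  lag <- switch(lag_method,
                threshold = {
                  hit <- which(smoothed >= 2 * smoothed[1])
                  if (length(hit)) t[hit[1]] else NA_real_
                },
                tangent = (log(smoothed[1]) - best$icpt) / best$slope)
  structure(
    list(doubling_time = log(2) / rate, growth_rate = rate, lag_time = lag,
         window = c(t[best$i], t[best$i + window - 1L]),
         r_squared = best$r2, degenerate = FALSE),
    class = "GrowthFit"
  )
}

#' @export
print.GrowthFit <- function(x, ...) {
  if (x$degenerate) {
    cat("GrowthFit: degenerate (no positive-slope exponential window)\n")
  } else {
    cat("GrowthFit: doubling", round(x$doubling_time, 3), "h, lag",
        round(x$lag_time, 2), "h, window [",
        paste(round(x$window, 2), collapse = ", "), "] h, R^2 =",
        round(x$r_squared, 4), "\n")
  }
  invisible(x)
}

#' Normalize fluorescence to culture density
#'
#' Elementwise `(F - background) / OD`, the standard per-cell expression
#' readout for plate-reader reporter assays.
#'
#' @param fluorescence raw fluorescence values (a.u.).
#' @param od optical density values, > 0 pointwise.
#' @param background optional background fluorescence (scalar or vector,
#'   e.g. a promoterless-reporter strain) subtracted before dividing.
#' @return normalized series.
#' @export
normalize_fluorescence <- function(fluorescence, od, background = NULL) {
  assert_that(length(fluorescence) == length(od),
              "fluorescence and od lengths differ")
  if (any(od <= 0)) stop("OD must be > 0 pointwise", call. = FALSE)
  f <- fluorescence
  if (!is.null(background)) f <- f - background
  f / od
}
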