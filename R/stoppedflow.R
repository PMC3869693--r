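#' Cell and channel parameters for permeability conversion
#'
#' Geometric and compositional parameters of the cell or vesicle
#' preparation, needed to convert an exponential rate constant into a
#' permeability coefficient.  The molar volume of water is fixed at
#' 18 cm^3/mol.
#'
#' @param V_over_S Volume-to-surface ratio, cm.  For spherical
#'   vesicles this is r/3; supply `radius` instead to use that form.
#' @param radius Optional sphere radius, cm (sets `V_over_S = r/3`).
#' @param surface_area Membrane area per cell, cm^2.  The default
#'   1.0e-6 cm^2 is a reconstruction back-solved from published
#'   control-vs-null permeability differences and channel copy
#'   numbers, not a measured value; override it when the true area is
#'   known.
#' @param C_out Total extracellular solute concentration after
#'   mixing, mol/cm^3.  The default 7e-4 corresponds to an isotonic
#'   ~300 mosM medium plus a 400 mosM post-mixing osmotic gradient;
#'   this convention is the one validated by back-solving V/S from
#'   published paired rate-constant/permeability data (see the
#'   methods vignette).  Override it to match the gradient actually
#'   applied.
#' @param copy_numbers Named vector: channel copies per cell.
#' @param temperature K.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(V_over_S = 5.4e-5, radius = NULL,
                        surface_area = NULL, C_out = 7e-4,
                        copy_numbers = c(`UT-B` = 13910, AQP1 = 175000),
                        temperature = 288.15) {
  if (!is.null(radius)) {
    if (radius <= 0) stop("radius must be positive")
    V_over_S <- radius / 3
  }
  if (is.null(V_over_S) || V_over_S <= 0)
    stop("V_over_S (or radius) must be positive")
  area_source <- if (is.null(surface_area)) "reconstructed-default" else "user"
  if (is.null(surface_area)) surface_area <- 1.0e-6
  if (surface_area <= 0) stop("surface_area must be positive")
  if (C_out <= 0) stop("C_out must be positive")
  if (any(copy_numbers <= 0)) stop("copy numbers must be positive")
  structure(list(V_over_S = V_over_S, surface_area = surface_area,
                 area_source = area_source, V_W = .V_W, C_out = C_out,
                 copy_numbers = copy_numbers, temperature = temperature),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("Cell parameters: V/S = %.3g cm, area = %.3g cm^2 (%s), C_out = %.3g mol/cm^3, T = %.2f K\n",
              x$V_over_S, x$surface_area, x$area_source, x$C_out,
              x$temperature))
  cat("  copies/cell:",
      paste(names(x$copy_numbers), format(x$copy_numbers), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

perm_record <- function(kind, value, se, k, params, species = NULL) {
  structure(list(kind = kind, value = value, se = se, k = k,
                 params = params, species = species,
                 temperature = params$temperature),
            class = "permeability_record")
}

#' @export
print.permeability_record <- function(x, ...) {
  lab <- if (is.null(x$species)) x$kind else paste0(x$kind, "(", x$species, ")")
  cat(sprintf("%s = %.4g cm/s", lab, x$value))
  if (is.finite(x$se)) cat(sprintf(" +/- %.2g", x$se))
  cat(sprintf("  (k = %.4g /s, T = %.2f K)\n", x$k, x$temperature))
  invisible(x)
}

#' Fit exponential relaxation to a stopped-flow trace
#'
#' Nonlinear least-squares fit of
#' `signal(t) = baseline + sum_i A_i exp(-k_i t)` with one or two
#' exponentials, initialized from a log-linearized fit to the decay.
#' Rate standard errors come from the covariance of the residuals.
#' For two exponentials the phases are considered resolved only when
#' the rate ratio exceeds 3; otherwise a degeneracy warning is
#' issued.  Non-convergence raises an error, never silent defaults.
#'
#' @param trace A `stopped_flow_trace`.
#' @param n_exponentials 1 or 2.
#' @return An object of class `sf_fit` with `rates` (1/s, decreasing),
#'   `rate_se`, `amplitudes`, `baseline`, `rms` and the underlying
#'   `nls` fit.
#' @export
fit_exponential <- function(trace, n_exponentials = 1) {
  n_exponentials <- as.integer(n_exponentials)
  if (!n_exponentials %in% c(1L, 2L))
    stop("n_exponentials must be 1 or 2")
  t <- trace$times
  y <- trace$signal
  if (length(t) < 5 * n_exponentials + 1)
    stop("too few samples for the requested number of exponentials")
  if (var(y) == 0 || diff(range(y)) < 1e-12 * max(abs(y), 1))
    stop("no decay detected: signal is constant")

  # log-linearized initialization on the dominant relaxation
  b0 <- mean(y[t >= max(t) * 0.9])
  a0 <- y[1] - b0
  if (abs(a0) < 1e-12) a0 <- diff(range(y)) * sign(y[1] - b0 + 1e-30)
  resid0 <- (y - b0) / a0
  use <- resid0 > 0.02
  k0 <- if (sum(use) >= 3) {
    max(1e-8, -unname(coef(lm(log(resid0[use]) ~ t[use]))[2]))
  } else 1 / (max(t) / 3)

  df <- data.frame(t = t, y = y)
  if (n_exponentials == 1L) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + A * exp(-k * t), data = df,
                        start = list(b = b0, A = a0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("exponential fit did not converge: ",
                               conditionMessage(e)))
    cf <- coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    rates <- unname(cf["k"]); rate_se <- unname(se["k"])
    amps <- unname(cf["A"]); base <- unname(cf["b"])
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + A1 * exp(-k1 * t) + A2 * exp(-k2 * t),
                        data = df,
                        start = list(b = b0, A1 = a0 / 2, A2 = a0 / 2,
                                     k1 = k0 * 4, k2 = k0 / 2),
                        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) stop("exponential fit did not converge: ",
                               conditionMessage(e)))
    cf <- coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    ord <- order(c(cf["k1"], cf["k2"]), decreasing = TRUE)
    rates <- unname(c(cf["k1"], cf["k2"]))[ord]
    rate_se <- unname(c(se["k1"], se["k2"]))[ord]
    amps <- unname(c(cf["A1"], cf["A2"]))[ord]
    base <- unname(cf["b"])
    if (rates[1] / rates[2] < 3)
      warning("rate ratio < 3: the two phases are poorly resolved")
  }
  if (any(rates <= 0)) stop("fit returned a non-positive rate constant")
  structure(list(rates = rates, rate_se = rate_se, amplitudes = amps,
                 baseline = base, n_exponentials = n_exponentials,
                 rms = sqrt(mean(residuals(fit)^2)), fit = fit,
                 trace = trace),
            class = "sf_fit")
}

#' @export
print.sf_fit <- function(x, ...) {
  cat(sprintf("Stopped-flow %d-exponential fit:\n", x$n_exponentials))
  for (i in seq_along(x$rates))
    cat(sprintf("  k%d = %.5g +/- %.2g /s  (A%d = %.4g)\n", i, x$rates[i],
                x$rate_se[i], i, x$amplitudes[i]))
  cat(sprintf("  baseline = %.4g, residual RMS = %.3g\n", x$baseline, x$rms))
  invisible(x)
}

#' @export
summary.sf_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  trace: %s, %d samples, T = %.2f K\n",
              object$trace$condition, length(object$trace$times),
              object$trace$temperature))
  invisible(object)
}

#' @export
coef.sf_fit <- function(object, ...) {
  out <- c(object$rates, object$amplitudes, object$baseline)
  names(out) <- c(paste0("k", seq_along(object$rates)),
                  paste0("A", seq_along(object$amplitudes)), "baseline")
  out
}

#' @export
predict.sf_fit <- function(object, times = object$trace$times, ...) {
  y <- rep(object$baseline, length(times))
  for (i in seq_along(object$rates))
    y <- y + object$amplitudes[i] * exp(-object$rates[i] * times)
  y
}

#' @export
residuals.sf_fit <- function(object, ...) {
  object$trace$signal - predict(object)
}

#' @export
plot.sf_fit <- function(x, ...) {
  plot(x$trace$times, x$trace$signal, pch = ".", xlab = "time (s)",
       ylab = "signal (a.u.)", ...)
  lines(x$trace$times, predict(x), col = 2, lwd = 2)
  invisible(x)
}

#' Osmotic water permeability from a shrink/swell rate constant
#'
#' `Pf = k (V/S) / (V_W C_out)` with V/S the cell volume-to-surface
#' ratio (cm), V_W the molar volume of water (18 cm^3/mol) and C_out
#' the total post-mixing extracellular solute concentration
#' (mol/cm^3).
#'
#' @param k Exponential rate constant, 1/s (or an `sf_fit`, whose
#'   dominant rate is used).
#' @param params A [cell_params()].
#' @param k_se Optional SE of `k`, propagated linearly.
#' @return A `permeability_record` of kind `"Pf"` (cm/s).
#' @export
osmotic_Pf <- function(k, params, k_se = NA_real_) {
  if (inherits(k, "sf_fit")) { k_se <- k$rate_se[1]; k <- k$rates[1] }
  if (k <= 0) stop("rate constant must be positive")
  fac <- params$V_over_S / (params$V_W * params$C_out)
  perm_record("Pf", k * fac, k_se * fac, k, params)
}

#' Diffusional water permeability from an exchange rate constant
#'
#' `Pd = k (V/S)`, with V/S = r/3 for spherical ghosts.
#'
#' @inheritParams osmotic_Pf
#' @return A `permeability_record` of kind `"Pd"` (cm/s).
#' @export
diffusional_Pd <- function(k, params, k_se = NA_real_) {
  if (inherits(k, "sf_fit")) { k_se <- k$rate_se[1]; k <- k$rates[1] }
  if (k <= 0) stop("rate constant must be positive")
  perm_record("Pd", k * params$V_over_S, k_se * params$V_over_S, k, params)
}

#' Apparent solute permeability (NH3 or H+)
#'
#' Simplified conversion `P = c k (V/S)` from a fluorescence rate
#' constant.  The multiplicative correction factor (default 1) is an
#' explicit hook for buffer-capacity effects in proton uptake, whose
#' exact treatment varies between laboratories.
#'
#' @inheritParams osmotic_Pf
#' @param species `"NH3"` or `"H"`.
#' @param correction Multiplicative correction factor.
#' @return A `permeability_record` (cm/s) with the species recorded.
#' @export
solute_permeability <- function(k, params, species = c("NH3", "H"),
                                correction = 1, k_se = NA_real_) {
  species <- match.arg(species)
  if (inherits(k, "sf_fit")) { k_se <- k$rate_se[1]; k <- k$rates[1] }
  if (k <= 0) stop("rate constant must be positive")
  fac <- params$V_over_S * correction
  perm_record("P_solute", k * fac, k_se * fac, k, params, species = species)
}

#' Single-channel unit permeability from a control/null difference
#'
#' Attributes the permeability difference between control cells and
#' channel-null cells entirely to the missing channel:
#' `p_unit = (P_control - P_null) * surface_area / copies`.
#'
#' @param P_control,P_null Macroscopic permeabilities, cm/s (numbers
#'   or `permeability_record`s).
#' @param params A [cell_params()] carrying `surface_area` and
#'   `copy_numbers`.
#' @param channel Channel name, matched against `params$copy_numbers`.
#' @return List of class `unit_permeability`: `p_unit` (cm^3/s) plus
#'   the inputs.
#' @export
unit_permeability <- function(P_control, P_null, params, channel = "UT-B") {
  if (inherits(P_control, "permeability_record")) P_control <- P_control$value
  if (inherits(P_null, "permeability_record")) P_null <- P_null$value
  if (P_control < P_null)
    stop("P_control < P_null: control/null measurements are inconsistent")
  if (!channel %in% names(params$copy_numbers))
    stop("unknown channel: ", channel)
  copies <- unname(params$copy_numbers[channel])
  if (params$area_source == "reconstructed-default")
    message("note: surface area ", format(params$surface_area),
            " cm^2 is a reconstructed default, not a measured value")
  p_unit <- (P_control - P_null) * params$surface_area / copies
  structure(list(channel = channel, p_unit = p_unit,
                 P_control = P_control, P_null = P_null,
                 surface_area = params$surface_area, copies = copies),
            class = "unit_permeability")
}

#' @export
print.unit_permeability <- function(x, ...) {
  cat(sprintf("Unit permeability (%s): %.4g cm^3/s  (%.3g x 1e-14)\n",
              x$channel, x$p_unit, x$p_unit / 1e-14))
  invisible(x)
}

#' Single-file water count from the Pf/Pd ratio
#'
#' For single-file transport the osmotic-to-diffusional permeability
#' ratio counts the water molecules in the file: `N = Pf/Pd - 1`.
#' Reported raw, rounded to one decimal, and as the nearest integer.
#'
#' @param p_f,p_d Permeabilities in matching units (macroscopic cm/s
#'   or single-channel cm^3/s).
#' @return List with `N`, `N_1dp`, `N_int` and the `ratio`.
#' @export
single_file_N <- function(p_f, p_d) {
  if (inherits(p_f, "permeability_record")) p_f <- p_f$value
  if (inherits(p_d, "permeability_record")) p_d <- p_d$value
  if (inherits(p_f, "permeability_estimate")) p_f <- p_f$value
  if (inherits(p_d, "permeability_estimate")) p_d <- p_d$value
  if (p_d <= 0) stop("p_d must be positive")
  N <- p_f / p_d - 1
  list(N = N, N_1dp = round(N, 1), N_int = round(N), ratio = p_f / p_d)
}

#' Arrhenius activation energy from a temperature series
#'
#' Least-squares line through `(1/T, ln value)`; the activation energy
#' is `Ea = -slope * R` with R = 0.0019872 kcal/(mol K).  Low Ea
#' (~5 kcal/mol) is the signature of channel-mediated water flow; high
#' Ea (~15-20 kcal/mol) indicates diffusion through the lipid phase.
#'
#' @param series Data frame with columns `temperature` (K) and `rate`
#'   (or any positive temperature-dependent quantity in its second
#'   column).
#' @return An object of class `arrhenius_fit` with `Ea` (kcal/mol),
#'   `Ea_se`, `prefactor` and the underlying linear model.
#' @export
fit_arrhenius <- function(series) {
  temperature <- series$temperature
  value <- if ("rate" %in% names(series)) series$rate else series[[2]]
  if (length(unique(temperature)) < 2)
    stop("at least two distinct temperatures are required")
  if (any(value <= 0)) stop("values must be positive for the log transform")
  invT <- 1 / temperature
  fit <- lm(log(value) ~ invT)
  slope <- unname(coef(fit)[2])
  # noiseless series fit exactly; the perfect-fit warning is expected
  se <- if (length(temperature) > 2)
    suppressWarnings(summary(fit)$coefficients[2, 2]) else NA_real_
  structure(list(Ea = -slope * .kB, Ea_se = se * .kB,
                 prefactor = exp(unname(coef(fit)[1])), fit = fit,
                 series = data.frame(temperature = temperature,
                                     value = value)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.4g kcal/mol", x$Ea))
  if (is.finite(x$Ea_se)) cat(sprintf(" +/- %.2g", x$Ea_se))
  cat(sprintf(", prefactor = %.4g /s (%d temperatures)\n", x$prefactor,
              nrow(x$series)))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(Ea = object$Ea, prefactor = object$prefactor)
}

#' @export
predict.arrhenius_fit <- function(object, temperature, ...) {
  object$prefactor * exp(-object$Ea / (.kB * temperature))
}

#' @export
plot.arrhenius_fit <- function(x, ...) {
  plot(1 / x$series$temperature, log(x$series$value),
       xlab = "1/T (1/K)", ylab = "ln(rate)", ...)
  abline(x$fit, col = 2)
  invisible(x)
}

#' Back-solve the volume-to-surface ratio from a k/P pair
#'
#' Inverts the permeability conversion formulas to recover the V/S
#' that a reported (rate constant, permeability) pair implies:
#' `V/S = P V_W C_out / k` for osmotic data and `V/S = P / k` for
#' exchange or solute data.  Comparing the implied V/S across
#' measurement modes is a self-consistency check on the reconstructed
#' formulas.
#'
#' @param k Rate constant, 1/s.
#' @param P Permeability, cm/s.
#' @param mode `"osmotic"` or `"exchange"`.
#' @param C_out mol/cm^3 (osmotic mode).
#' @param V_W Molar water volume, cm^3/mol.
#' @return Implied V/S in cm.
#' @export
backsolve_V_over_S <- function(k, P, mode = c("osmotic", "exchange"),
                               C_out = 7e-4, V_W = .V_W) {
  mode <- match.arg(mode)
  if (k <= 0) stop("k must be positive")
  if (mode == "osmotic") P * V_W * C_out / k else P / k
}
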