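#' ITC injection schedule
#'
#' Describes the perfusion-cell geometry and injection protocol of an ITC
#' experiment. The default volumes follow the common fragment protocol of one
#' 0.4 uL pre-injection followed by 18 injections of 2 uL.
#'
#' @param syringe_conc Titrant concentration in the syringe, molar.
#' @param cell_protein_conc Protein concentration in the cell before the
#'   first injection, molar.
#' @param cell_preload_conc Concentration of a weak ligand preloaded in the
#'   cell (0 for a direct titration), molar.
#' @param injection_volumes Injection volumes in litres; default
#'   `c(0.4e-6, rep(2e-6, 18))`.
#' @param cell_volume Active cell volume in litres; default 200 uL, typical
#'   for automated microcalorimeters of this class. Normalized heats are
#'   insensitive to it at fixed concentrations.
#' @param temperature Kelvin; default 298.15.
#'
#' @return An `injection_schedule` object.
#' @examples
#' injection_schedule(syringe_conc = 300e-6, cell_protein_conc = 20e-6,
#'                    cell_preload_conc = 4.2e-3)
#' @export
injection_schedule <- function(syringe_conc, cell_protein_conc,
                               cell_preload_conc = 0,
                               injection_volumes = c(0.4e-6, rep(2e-6, 18)),
                               cell_volume = 200e-6,
                               temperature = 298.15) {
  stopifnot(length(injection_volumes) >= 1L)
  if (any(!is.finite(injection_volumes) | injection_volumes <= 0)) {
    stop("all injection volumes must be positive")
  }
  if (!is.finite(cell_volume) || cell_volume <= 0) stop("`cell_volume` must be > 0")
  if (syringe_conc < 0 || cell_protein_conc < 0 || cell_preload_conc < 0) {
    stop("concentrations must be >= 0")
  }
  structure(list(cell_volume = cell_volume,
                 injection_volumes = injection_volumes,
                 syringe_conc = syringe_conc,
                 cell_protein_conc = cell_protein_conc,
                 cell_preload_conc = cell_preload_conc,
                 temperature = temperature),
            class = "injection_schedule")
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat(sprintf("<injection_schedule> %d injections (%.3g uL total) into %.0f uL cell\n",
              length(x$injection_volumes), sum(x$injection_volumes) * 1e6,
              x$cell_volume * 1e6))
  cat(sprintf("  syringe %.4g M, cell protein %.4g M, preload %.4g M, T %.2f K\n",
              x$syringe_conc, x$cell_protein_conc, x$cell_preload_conc,
              x$temperature))
  invisible(x)
}

# Per-injection cell composition under the overfill model: after injecting
# dV, pre-existing contents are scaled by (1 - dV/V0) and the injected
# material is fully mixed. Returns a data.frame of post-injection totals and
# the dilution factor applied to the pre-injection contents.
cell_composition <- function(schedule) {
  v0 <- schedule$cell_volume
  n_inj <- length(schedule$injection_volumes)
  p <- schedule$cell_protein_conc
  b <- schedule$cell_preload_conc
  a <- 0  # titrant
  out <- data.frame(injection = seq_len(n_inj),
                    volume = schedule$injection_volumes,
                    dilution = NA_real_, protein = NA_real_,
                    titrant = NA_real_, preload = NA_real_)
  for (i in seq_len(n_inj)) {
    dv <- schedule$injection_volumes[i]
    f <- 1 - dv / v0
    if (f <= 0) stop("injection volume exceeds cell volume")
    p <- p * f
    b <- b * f
    a <- a * f + schedule$syringe_conc * dv / v0
    out$dilution[i] <- f
    out$protein[i] <- p
    out$titrant[i] <- a
    out$preload[i] <- b
  }
  out
}

new_thermogram <- function(heats_uJ, schedule, noise_sd = 0) {
  dv <- schedule$injection_volumes
  stopifnot(length(heats_uJ) == length(dv))
  # uJ -> kJ, per mol of injectant
  normalized <- (heats_uJ * 1e-9) / (schedule$syringe_conc * dv)
  structure(list(heats = heats_uJ, normalized = normalized,
                 schedule = schedule, noise_sd = noise_sd),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d injections, total heat %.3g uJ%s\n",
              length(x$heats), sum(x$heats),
              if (x$noise_sd > 0) sprintf(", noise sd %.3g uJ", x$noise_sd) else ""))
  invisible(x)
}

#' @export
as.data.frame.thermogram <- function(x, ...) {
  data.frame(injection_index = seq_along(x$heats),
             volume_uL = x$schedule$injection_volumes * 1e6,
             heat_uJ = x$heats,
             normalized_kJ_per_mol = x$normalized)
}

#' Simulate a direct ITC titration
#'
#' Integrated-heat simulation of a one-site direct titration. After each
#' injection the cell composition is updated under the overfill model (see
#' [injection_schedule()]), the single-site equilibrium is re-solved at the
#' post-injection totals, and the heat of injection i is
#' \deqn{q_i = \Delta H \, V_0 \, (c_i - c_{i-1} f_i),}
#' where \eqn{c_i} is the complex concentration after injection i and
#' \eqn{f_i} the dilution factor, so heat is credited only for newly formed
#' complex, not for complex expelled from the active volume. Stoichiometry
#' enters as a binding-site concentration `n * [P]`.
#'
#' @param params A [binding_parameters()] for the titrant.
#' @param schedule An [injection_schedule()] with `cell_preload_conc = 0`.
#'
#' @return A `thermogram` with per-injection heats (uJ) and normalized heats
#'   (kJ per mol of injectant). Noiseless and deterministic.
#' @examples
#' sch <- injection_schedule(syringe_conc = 300e-6, cell_protein_conc = 20e-6)
#' simulate_direct(binding_parameters(kd = 2.9e-7, dh = -50, n = 0.9), sch)
#' @export
simulate_direct <- function(params, schedule) {
  stopifnot(inherits(params, "binding_parameters"),
            inherits(schedule, "injection_schedule"))
  if (schedule$cell_preload_conc != 0) {
    stop("direct titration requires `cell_preload_conc = 0`; use simulate_displacement()")
  }
  comp <- cell_composition(schedule)
  v0 <- schedule$cell_volume
  complex_prev <- 0
  heats <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    sites <- params$n * comp$protein[i]
    cx <- if (sites > 0 && comp$titrant[i] > 0) {
      solve_single_site(sites, comp$titrant[i], params$kd)$complex
    } else 0
    heats[i] <- params$dh * v0 * (cx - complex_prev * comp$dilution[i]) * 1e9
    complex_prev <- cx
  }
  new_thermogram(heats, schedule)
}

#' Simulate a displacement ITC titration
#'
#' The cell holds protein preloaded with a weak ligand; a strong ligand is
#' titrated in and displaces it. Each post-injection composition is solved
#' with the competitive equilibrium ([solve_competitive()]) and both
#' complexes' enthalpy changes are credited:
#' \deqn{q_i = V_0 \left[\Delta H_A (c^A_i - c^A_{i-1} f_i) +
#'   \Delta H_B (c^B_i - c^B_{i-1} f_i)\right].}
#' With zero preload (or an inert weak ligand: `dh = 0`, `kd = Inf`) this
#' reduces exactly to [simulate_direct()].
#'
#' @param params_strong [binding_parameters()] of the titrated strong ligand.
#' @param params_weak [binding_parameters()] of the preloaded weak fragment
#'   (its `n` is ignored; the site concentration uses `params_strong$n`).
#' @param schedule An [injection_schedule()]; `cell_preload_conc` is the weak
#'   fragment's concentration.
#'
#' @return A `thermogram`.
#' @examples
#' sch <- injection_schedule(syringe_conc = 300e-6, cell_protein_conc = 20e-6,
#'                           cell_preload_conc = 4.2e-3)
#' simulate_displacement(binding_parameters(2.9e-7, dh = -50),
#'                       binding_parameters(1e-3, dh = -5), sch)
#' @export
simulate_displacement <- function(params_strong, params_weak, schedule) {
  stopifnot(inherits(params_strong, "binding_parameters"),
            inherits(params_weak, "binding_parameters"),
            inherits(schedule, "injection_schedule"))
  comp <- cell_composition(schedule)
  v0 <- schedule$cell_volume
  ca_prev <- 0
  cb_prev <- if (schedule$cell_preload_conc > 0 && is.finite(params_weak$kd)) {
    solve_single_site(params_strong$n * schedule$cell_protein_conc,
                      schedule$cell_preload_conc, params_weak$kd)$complex
  } else 0
  heats <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    sites <- params_strong$n * comp$protein[i]
    if (comp$preload[i] > 0) {
      st <- solve_competitive(sites, comp$titrant[i], comp$preload[i],
                              params_strong$kd, params_weak$kd)
      ca <- st$complex[1]
      cb <- st$complex[2]
    } else {
      ca <- if (comp$titrant[i] > 0) {
        solve_single_site(sites, comp$titrant[i], params_strong$kd)$complex
      } else 0
      cb <- 0
    }
    f <- comp$dilution[i]
    heats[i] <- v0 * 1e9 * (params_strong$dh * (ca - ca_prev * f) +
                            params_weak$dh * (cb - cb_prev * f))
    ca_prev <- ca
    cb_prev <- cb
  }
  new_thermogram(heats, schedule)
}

# Predicted normalized heats for a (n, kd, dh) triple under a schedule.
predict_normalized <- function(n, kd, dh, schedule) {
  simulate_direct(binding_parameters(kd = kd, dh = dh, n = n), schedule)$normalized
}

#' Fit one-site binding parameters to a thermogram
#'
#' Nonlinear least squares over (N, Kd, dH), minimizing squared residuals of
#' the normalized heats against the direct-titration model. Kd and N are
#' fitted on the log scale to enforce positivity. To avoid local minima the
#' optimiser is started from 5 deterministic points spanning four orders of
#' magnitude in Kd around the cell protein concentration, and the best
#' converged fit is kept. The first injection (the small pre-injection) is
#' excluded by default, as in standard ITC practice.
#'
#' @param thermogram A `thermogram` (its schedule supplies the
#'   concentrations).
#' @param drop_first Exclude the first injection from the fit (default TRUE).
#' @param fit_offset Also fit a constant per-injection heat-of-dilution
#'   offset (kJ/mol of injectant); default FALSE.
#'
#' @return A list of class `itc_fit` with `params`
#'   ([binding_parameters()]), `se` (named standard errors), `offset`,
#'   `residual_ss`, `converged`, and `c_value` (with a reliability warning
#'   issued when c falls outside the 1-1000 window).
#' @examples
#' sch <- injection_schedule(syringe_conc = 300e-6, cell_protein_conc = 20e-6)
#' tg <- simulate_direct(binding_parameters(kd = 2.9e-7, dh = -50, n = 0.9), sch)
#' fit_one_site(tg)$params
#' @export
fit_one_site <- function(thermogram, drop_first = TRUE, fit_offset = FALSE) {
  stopifnot(inherits(thermogram, "thermogram"))
  schedule <- thermogram$schedule
  # apparent one-site fit: any preloaded competitor is absorbed into the
  # apparent Kd, so the model curve is always the direct-titration one
  schedule$cell_preload_conc <- 0
  keep <- seq_along(thermogram$normalized)
  if (drop_first && length(keep) > 5) keep <- keep[-1]
  if (length(keep) < 5) stop("need at least 5 injections to fit")
  obs <- thermogram$normalized[keep]

  # deterministic starts: kd spanning 4 orders of magnitude around [P]
  p0 <- schedule$cell_protein_conc
  kd_starts <- p0 * 10^seq(-2, 2, length.out = 5)
  dh0 <- obs[which.max(abs(obs))]
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1

  resid_fn <- function(par) {
    pred <- predict_normalized(exp(par[["log_n"]]), exp(par[["log_kd"]]),
                               par[["dh"]], schedule)[keep]
    if (fit_offset) pred <- pred + par[["offset"]]
    obs - pred
  }

  best <- NULL
  for (kd0 in kd_starts) {
    par0 <- list(log_n = 0, log_kd = log(kd0), dh = dh0)
    if (fit_offset) par0$offset <- 0
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, se = NULL, offset = NA_real_,
                          residual_ss = NA_real_, converged = FALSE,
                          c_value = NA_real_),
                     class = "itc_fit"))
  }
  fit <- best$fit
  cf <- coef(fit)
  n_hat <- exp(cf[["log_n"]])
  kd_hat <- exp(cf[["log_kd"]])
  dh_hat <- cf[["dh"]]
  converged <- fit$info %in% 1:4

  # delta-method standard errors on the natural scale
  se <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    c(n = n_hat * s[["log_n"]], kd = kd_hat * s[["log_kd"]], dh = s[["dh"]])
  }, error = function(e) c(n = NA_real_, kd = NA_real_, dh = NA_real_))

  cval <- c_value(p0, kd_hat, n_hat)
  if (converged && !c_value_in_window(cval)) {
    warning(sprintf("c value %.3g outside the reliable 1-1000 window; Kd is poorly determined", cval))
  }
  structure(list(
    params = binding_parameters(kd = kd_hat, dh = dh_hat, n = n_hat,
                                temperature = schedule$temperature),
    se = se,
    offset = if (fit_offset) cf[["offset"]] else 0,
    residual_ss = best$rss,
    converged = converged,
    c_value = as.numeric(cval)), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<itc_fit> NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("<itc_fit> N = %.3f (se %.2g), Kd = %.4g M (se %.2g), dH = %.4g kJ/mol (se %.2g)\n",
              x$params$n, x$se[["n"]], x$params$kd, x$se[["kd"]],
              x$params$dh, x$se[["dh"]]))
  cat(sprintf("  RSS %.4g, c = %.3g%s\n", x$residual_ss, x$c_value,
              if (c_value_in_window(x$c_value)) "" else " (outside 1-1000 window)"))
  invisible(x)
}

#' Dilution-corrected mean fragment concentration in the cell
#'
#' During a displacement titration the preloaded fragment is progressively
#' diluted by the injections, so inverting the displacement relation with the
#' preload concentration biases the recovered fragment Kd. This helper
#' returns the in-cell fragment concentration averaged over the fitted
#' injections; when the thermogram is supplied, injections are weighted by
#' their absolute normalized heats, concentrating the average where the
#' isotherm (and hence the apparent Kd) is actually determined.
#'
#' @param schedule An [injection_schedule()] with a nonzero preload.
#' @param drop_first Match the fit's exclusion of the first injection.
#' @param weights Optional `thermogram` (or numeric vector, one value per
#'   injection) supplying per-injection weights; `NULL` gives the unweighted
#'   mean.
#'
#' @return Effective fragment concentration, molar.
#' @export
mean_fragment_conc <- function(schedule, drop_first = TRUE, weights = NULL) {
  stopifnot(inherits(schedule, "injection_schedule"))
  if (schedule$cell_preload_conc <= 0) stop("schedule has no preloaded fragment")
  comp <- cell_composition(schedule)
  keep <- seq_len(nrow(comp))
  if (drop_first && length(keep) > 5) keep <- keep[-1]
  if (is.null(weights)) return(mean(comp$preload[keep]))
  w <- if (inherits(weights, "thermogram")) abs(weights$normalized) else abs(weights)
  if (length(w) != nrow(comp)) stop("`weights` must supply one value per injection")
  sum(w[keep] * comp$preload[keep]) / sum(w[keep])
}
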