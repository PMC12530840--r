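#' A titratable group in a solution of given pH
#'
#' @param pka Acid dissociation constant on the log scale.
#' @param ph Solution pH.
#' @param label Optional free-text description, e.g.
#'   `"benzoic acid, soaking buffer"`.
#'
#' @return An object of class `acid_base_state`.
#' @examples
#' acid_base_state(pka = 4.1, ph = 5.3, label = "benzoic acid, soaking buffer")
#' @export
acid_base_state <- function(pka, ph, label = "") {
  stopifnot(is.numeric(pka), is.numeric(ph), length(pka) == 1L, length(ph) == 1L)
  if (!is.finite(pka) || !is.finite(ph)) stop("`pka` and `ph` must be finite")
  if (pka < 0 || pka > 14) warning(sprintf("pKa %.2f outside the usual 0-14 range", pka))
  if (ph < 0 || ph > 14) warning(sprintf("pH %.2f outside the usual 0-14 range", ph))
  structure(list(pka = pka, ph = ph, label = as.character(label)),
            class = "acid_base_state")
}

#' @export
print.acid_base_state <- function(x, ...) {
  cat(sprintf("<acid_base_state> pKa %.2f at pH %.2f%s: %.2f%% protonated\n",
              x$pka, x$ph, if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              100 * protonated_fraction(x)))
  invisible(x)
}

#' Henderson-Hasselbalch protonated fraction
#'
#' Fraction of an acid in the protonated (neutral, for a carboxylic acid)
#' form: \eqn{f_{HA} = 1 / (1 + 10^{pH - pK_a})}. Monotonically decreasing in
#' pH; exactly 0.5 at pH = pKa. The deprotonated fraction is `1 - f`.
#'
#' @param state An [acid_base_state()], or a numeric pKa when `ph` is given.
#' @param ph Solution pH (only when `state` is a bare pKa).
#'
#' @return Protonated fraction in `[0, 1]`.
#' @examples
#' protonated_fraction(acid_base_state(4.1, 5.3))  # ~0.059 in soaking buffer
#' protonated_fraction(4.2, ph = 6.9)              # ~0.002 in ITC buffer
#' @export
protonated_fraction <- function(state, ph = NULL) {
  if (inherits(state, "acid_base_state")) {
    pka <- state$pka
    ph <- state$ph
  } else {
    if (is.null(ph)) stop("supply an acid_base_state, or both `state` (pKa) and `ph`")
    pka <- state
  }
  1 / (1 + 10^(ph - pka))
}

#' pKa shift between free and protein-bound ligand
#'
#' @param pka_free pKa of the unbound ligand.
#' @param pka_bound pKa of the protein-bound ligand.
#'
#' @return A `pka_shift` object with fields `pka_free`, `pka_bound` and
#'   `delta = pka_bound - pka_free`. A positive `delta` means binding
#'   stabilises the protonated form.
#' @examples
#' pka_shift(4.2, 5.4)  # delta = 1.2
#' @export
pka_shift <- function(pka_free, pka_bound) {
  stopifnot(is.numeric(pka_free), is.numeric(pka_bound))
  if (!is.finite(pka_free) || !is.finite(pka_bound)) stop("pKa values must be finite")
  structure(list(pka_free = pka_free, pka_bound = pka_bound,
                 delta = pka_bound - pka_free),
            class = "pka_shift")
}

#' @export
print.pka_shift <- function(x, ...) {
  cat(sprintf("<pka_shift> %.2f (free) -> %.2f (bound), delta = %+.2f\n",
              x$pka_free, x$pka_bound, x$delta))
  invisible(x)
}

#' Linkage free energy of a binding-induced pKa shift
#'
#' Thermodynamic linkage: if binding shifts the ligand's pKa by
#' \eqn{\Delta pK_a}, the protonated form binds more favourably than the
#' deprotonated form by \deqn{\Delta\Delta G = RT \ln(10) \, \Delta pK_a.}
#' Positive `delta` (pKa up on binding) gives a positive value, i.e. an
#' advantage for the protonated species; the relation is linear in both
#' `delta` and temperature.
#'
#' @param shift A [pka_shift()], or a bare numeric `delta`.
#' @param temperature Kelvin; default 298.15.
#'
#' @return kJ/mol.
#' @examples
#' ddg_from_dpka(pka_shift(4.2, 5.4))  # ~6.85 kJ/mol at 25 C
#' @export
ddg_from_dpka <- function(shift, temperature = 298.15) {
  delta <- if (inherits(shift, "pka_shift")) shift$delta else shift
  if (!is.finite(temperature) || temperature <= 0) stop("`temperature` must be > 0")
  .RGAS * temperature * log(10) * delta
}

#' Construct a pH titration curve
#'
#' @param ph_points Strictly increasing pH values.
#' @param fraction_deprotonated Observed deprotonated fraction at each pH,
#'   each in `[0, 1]`.
#' @param replicate_id Free-text replicate label.
#'
#' @return A `titration_curve` object.
#' @export
titration_curve <- function(ph_points, fraction_deprotonated,
                            replicate_id = "r1") {
  ph_points <- as.numeric(ph_points)
  fraction_deprotonated <- as.numeric(fraction_deprotonated)
  if (length(ph_points) != length(fraction_deprotonated)) {
    stop("`ph_points` and `fraction_deprotonated` must have equal length")
  }
  if (any(diff(ph_points) <= 0)) stop("`ph_points` must be strictly increasing")
  if (any(fraction_deprotonated < 0 | fraction_deprotonated > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  structure(list(ph_points = ph_points,
                 fraction_deprotonated = fraction_deprotonated,
                 replicate_id = as.character(replicate_id)),
            class = "titration_curve")
}

#' Fit a pKa from a titration curve
#'
#' Least-squares fit of the one-proton sigmoid
#' \eqn{f_{A^-}(pH) = 1/(1 + 10^{pK_a - pH})} (Hill coefficient fixed at 1)
#' to observed deprotonated fractions, via Levenberg-Marquardt. A curve that
#' never crosses the transition (all fractions below 0.1 or above 0.9) yields
#' a `fit-unreliable` warning; the point estimate is still returned.
#'
#' @param curve A [titration_curve()], or a list of them (replicates); with
#'   replicates each curve is fitted separately and the reported pKa is the
#'   mean of the single fits, its standard error the standard error of that
#'   mean.
#'
#' @return A list with `pka`, `se`, `residual_ss`, `converged`, and
#'   `replicates` (per-curve estimates when fitted from a list).
#' @examples
#' ph <- seq(2, 7, by = 0.25)
#' crv <- titration_curve(ph, 1 / (1 + 10^(4.1 - ph)))
#' fit_pka(crv)$pka  # 4.1, exact on noiseless data
#' @export
fit_pka <- function(curve) {
  if (inherits(curve, "titration_curve")) curves <- list(curve)
  else if (is.list(curve) && all(vapply(curve, inherits, TRUE, "titration_curve"))) curves <- curve
  else stop("`curve` must be a titration_curve or a list of them")

  fit_one <- function(crv) {
    ph <- crv$ph_points
    fr <- crv$fraction_deprotonated
    if (length(ph) < 4) stop("need at least 4 titration points")
    if (all(fr < 0.1) || all(fr > 0.9)) {
      warning(sprintf("fit-unreliable: curve '%s' does not span the transition (no fractions between 0.1 and 0.9)",
                      crv$replicate_id))
    }
    # start at the pH where the curve is closest to half-deprotonation
    start <- ph[which.min(abs(fr - 0.5))]
    res_fn <- function(p) fr - 1 / (1 + 10^(p[["pka"]] - ph))
    fit <- minpack.lm::nls.lm(par = list(pka = start), fn = res_fn,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-15, ptol = 1e-15, maxiter = 200))
    rss <- sum(fit$fvec^2)
    dof <- length(ph) - 1L
    se <- tryCatch({
      cov <- solve(fit$hessian) * 2 * rss / max(dof, 1L)
      sqrt(abs(cov[1, 1]))
    }, error = function(e) NA_real_)
    list(pka = unname(coef(fit)[["pka"]]), se = se, residual_ss = rss,
         converged = fit$info %in% 1:4)
  }

  fits <- lapply(curves, fit_one)
  if (length(fits) == 1L) {
    out <- fits[[1]]
    out$replicates <- NULL
    return(out)
  }
  pkas <- vapply(fits, `[[`, 0, "pka")
  list(pka = mean(pkas),
       se = stats::sd(pkas) / sqrt(length(pkas)),
       residual_ss = sum(vapply(fits, `[[`, 0, "residual_ss")),
       converged = all(vapply(fits, `[[`, TRUE, "converged")),
       replicates = pkas)
}
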