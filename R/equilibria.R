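# Gas constant, kJ mol^-1 K^-1 (CODATA)
.RGAS <- 8.31446261815324e-3

#' Thermodynamic description of one binding event
#'
#' Bundles the parameters of a single-site binding equilibrium: dissociation
#' constant, binding enthalpy, stoichiometry and temperature.
#'
#' @param kd Dissociation constant, molar. Must be > 0.
#' @param dh Binding enthalpy, kJ per mol of complex formed (negative =
#'   exothermic).
#' @param n Stoichiometry (binding sites per protein molecule). Must be > 0.
#' @param temperature Absolute temperature in kelvin. Defaults to 298.15 K
#'   (25 degrees C).
#'
#' @return An object of class `binding_parameters`.
#' @examples
#' binding_parameters(kd = 1e-3, dh = -40)
#' @export
binding_parameters <- function(kd, dh = 0, n = 1, temperature = 298.15) {
  stopifnot(is.numeric(kd), is.numeric(dh), is.numeric(n),
            is.numeric(temperature), length(kd) == 1L, length(dh) == 1L,
            length(n) == 1L, length(temperature) == 1L)
  if (is.nan(kd) || kd <= 0) stop("`kd` must be a positive molar concentration")
  # kd = Inf is admitted as the inert-ligand limit
  if (!is.finite(n) || n <= 0) stop("`n` must be a finite positive stoichiometry")
  if (!is.finite(temperature) || temperature <= 0) stop("`temperature` must be positive (kelvin)")
  structure(list(kd = kd, dh = dh, n = n, temperature = temperature),
            class = "binding_parameters")
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat(sprintf("<binding_parameters> Kd = %.4g M, dH = %.4g kJ/mol, N = %.4g, T = %.2f K\n",
              x$kd, x$dh, x$n, x$temperature))
  invisible(x)
}

new_equilibrium_state <- function(p_free, ligand_free, complex, p_total,
                                  l_total) {
  saturation <- sum(complex) / p_total
  st <- structure(list(p_free = p_free, ligand_free = ligand_free,
                       complex = complex, saturation = saturation,
                       p_total = p_total, l_total = l_total),
                  class = "equilibrium_state")
  check_equilibrium_state(st)
  st
}

check_equilibrium_state <- function(st, rtol = 1e-9) {
  if (any(c(st$p_free, st$ligand_free, st$complex) < -1e-15)) {
    stop("negative concentration in equilibrium state")
  }
  p_err <- abs(st$p_free + sum(st$complex) - st$p_total) /
    max(st$p_total, .Machine$double.xmin)
  if (p_err > rtol) stop(sprintf("protein mass balance violated (rel. err %.3g)", p_err))
  for (i in seq_along(st$l_total)) {
    if (st$l_total[i] == 0) next
    l_err <- abs(st$ligand_free[i] + st$complex[i] - st$l_total[i]) / st$l_total[i]
    if (l_err > rtol) stop(sprintf("ligand %d mass balance violated (rel. err %.3g)", i, l_err))
  }
  invisible(st)
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> free protein %.4g M, saturation %.1f%%\n",
              x$p_free, 100 * x$saturation))
  for (i in seq_along(x$complex)) {
    cat(sprintf("  ligand %d: free %.4g M, complex %.4g M\n",
                i, x$ligand_free[i], x$complex[i]))
  }
  invisible(x)
}

#' Single-site binding equilibrium
#'
#' Solves the mass balance for one protein binding site and one ligand,
#' \deqn{PL = P_{free} L_{free} / K_d,} taking the physically meaningful
#' (smaller) root of the quadratic
#' \eqn{x^2 - (P + L + K_d)x + PL = 0} in the complex concentration, in the
#' numerically stable form that avoids catastrophic cancellation.
#'
#' @param p_total Total protein (site) concentration, molar, > 0.
#' @param l_total Total ligand concentration, molar, >= 0.
#' @param kd Dissociation constant, molar, > 0.
#'
#' @return An `equilibrium_state` with fields `p_free`, `ligand_free`,
#'   `complex` (length-1) and `saturation` = complex / p_total.
#' @examples
#' # ~80% saturation of 20 uM protein by a 4.2 mM fragment with Kd = 1 mM
#' solve_single_site(20e-6, 4.2e-3, 1e-3)$saturation
#' @export
solve_single_site <- function(p_total, l_total, kd) {
  if (!is.finite(p_total) || p_total <= 0) stop("`p_total` must be > 0")
  if (!is.finite(l_total) || l_total < 0) stop("`l_total` must be >= 0")
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be > 0")
  b <- p_total + l_total + kd
  disc <- b * b - 4 * p_total * l_total
  # larger root via the stable branch, smaller root from the product of roots
  big <- (b + sqrt(max(disc, 0))) / 2
  complex <- p_total * l_total / big
  complex <- min(complex, p_total, l_total)
  new_equilibrium_state(p_free = p_total - complex,
                        ligand_free = l_total - complex,
                        complex = complex,
                        p_total = p_total, l_total = l_total)
}

#' Fragment concentration required for a target saturation
#'
#' Experiment-design formula for displacement ITC: the total fragment
#' concentration that must be loaded into the cell so the protein reaches a
#' target fractional saturation \eqn{D_{sat}},
#' \deqn{[frag]_{cell} = \frac{D_{sat} K_d}{1 - D_{sat}} + D_{sat}[P].}
#'
#' @param p_total Total protein concentration in the cell, molar.
#' @param target_saturation Target fractional saturation, in (0, 1).
#' @param kd_fragment Assumed fragment dissociation constant, molar.
#'
#' @return Required total fragment concentration, molar. Round-trips:
#'   `solve_single_site(p_total, result, kd_fragment)$saturation`
#'   equals `target_saturation` to high precision.
#' @examples
#' required_fragment_conc(20e-6, 0.8, 1e-3)  # 4.016 mM
#' @export
required_fragment_conc <- function(p_total, target_saturation, kd_fragment) {
  if (!is.finite(p_total) || p_total <= 0) stop("`p_total` must be > 0")
  if (!is.finite(kd_fragment) || kd_fragment <= 0) stop("`kd_fragment` must be > 0")
  if (!is.finite(target_saturation) || target_saturation <= 0 ||
      target_saturation >= 1) {
    stop("`target_saturation` must lie strictly between 0 and 1 (saturation of 1 requires infinite ligand)")
  }
  target_saturation * kd_fragment / (1 - target_saturation) +
    target_saturation * p_total
}

#' Wiseman c value
#'
#' The dimensionless c value of an ITC experiment, \eqn{c = n [P] / K_d}.
#' Isotherms are reliably fittable roughly when 1 <= c <= 1000; outside this
#' window the dissociation constant is poorly determined.
#'
#' @inheritParams solve_single_site
#' @param n Stoichiometry; the classic definition is the n = 1 case.
#'
#' @return Numeric c value, with attribute `in_window` (logical, TRUE when
#'   1 <= c <= 1000). See [c_value_in_window()].
#' @examples
#' c_value(140e-6, 1e-3)  # 0.14 -- below the reliable window
#' @export
c_value <- function(p_total, kd, n = 1) {
  if (!is.finite(p_total) || p_total <= 0) stop("`p_total` must be > 0")
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be > 0")
  if (!is.finite(n) || n <= 0) stop("`n` must be > 0")
  c <- n * p_total / kd
  attr(c, "in_window") <- c_value_in_window(c)
  c
}

#' @rdname c_value
#' @param c A c value (plain number or output of [c_value()]).
#' @export
c_value_in_window <- function(c) {
  c <- as.numeric(c)
  # tolerance so that ratios like 1e-3/1e-6 sit on, not over, the boundary
  c >= 1 * (1 - 1e-9) & c <= 1000 * (1 + 1e-9)
}

#' Competitive binding equilibrium for two ligands sharing one site
#'
#' Simultaneous mass balance for one protein site and two mutually exclusive
#' ligands A and B. Given free protein \eqn{P_f}, each complex is
#' \eqn{[PX] = X_{tot} P_f / (K_d^X + P_f)}, so the protein balance
#' \deqn{g(P_f) = P_f\left(1 + \frac{A_{tot}}{K_A + P_f} +
#'   \frac{B_{tot}}{K_B + P_f}\right) - P_{tot}}
#' is strictly increasing in \eqn{P_f}; the unique root is found by bisection
#' refined to near machine precision (no root-selection ambiguity, unlike the
#' closed-form cubic).
#'
#' @param p_total,a_total,b_total Total protein and ligand concentrations,
#'   molar. `b_total = 0` is allowed and reduces to [solve_single_site()].
#' @param kd_a,kd_b Dissociation constants of the two ligands, molar.
#'
#' @return An `equilibrium_state` whose `ligand_free` and `complex` have two
#'   entries (A then B); `saturation` counts both complexes.
#' @examples
#' # fasudil displacing a weak fragment from a kinase
#' solve_competitive(20e-6, 10e-6, 4.2e-3, kd_a = 0.3e-6, kd_b = 1e-3)
#' @export
solve_competitive <- function(p_total, a_total, b_total, kd_a, kd_b) {
  if (!is.finite(p_total) || p_total <= 0) stop("`p_total` must be > 0")
  if (!is.finite(a_total) || a_total < 0) stop("`a_total` must be >= 0")
  if (!is.finite(b_total) || b_total < 0) stop("`b_total` must be >= 0")
  if (!is.finite(kd_a) || kd_a <= 0) stop("`kd_a` must be > 0")
  if (kd_b <= 0) stop("`kd_b` must be > 0")  # Inf allowed: inert ligand

  resid <- function(pf) {
    pf * (1 + a_total / (kd_a + pf) + b_total / (kd_b + pf)) - p_total
  }
  lo <- 0
  hi <- p_total
  # residual is monotone increasing; resid(0) = -p_total < 0, resid(P) >= 0
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break  # interval at machine resolution
    if (resid(mid) < 0) lo <- mid else hi <- mid
  }
  pf <- (lo + hi) / 2
  if (abs(resid(pf)) > 1e-9 * p_total) {
    stop(sprintf("competitive solver failed to converge: residual %.3g M at free protein %.3g M",
                 resid(pf), pf))
  }
  ca <- a_total * pf / (kd_a + pf)
  cb <- if (is.infinite(kd_b)) 0 else b_total * pf / (kd_b + pf)
  # enforce exact protein closure; bisection already puts the error ~eps
  pf <- p_total - ca - cb
  new_equilibrium_state(p_free = pf,
                        ligand_free = c(a_total - ca, b_total - cb),
                        complex = c(ca, cb),
                        p_total = p_total, l_total = c(a_total, b_total))
}

#' Fragment affinity from a displacement titration
#'
#' Inverts the displacement relation between the reference association
#' constant of the strong ligand (titrated into protein alone), the apparent
#' association constant observed when the cell is preloaded with the weak
#' fragment, and the fragment concentration:
#' \deqn{K_a^{frag} = \left(\frac{K_{ref}}{K_{obs}} - 1\right)
#'   \frac{1}{[frag]_{cell}}.}
#' Inputs and the return value are expressed as dissociation constants; the
#' association-constant arithmetic happens internally.
#'
#' @param kd_ref Dissociation constant of the strong ligand alone, molar.
#' @param kd_obs Apparent dissociation constant in the displacement
#'   experiment, molar. Must be >= `kd_ref` (competition can only weaken the
#'   apparent affinity).
#' @param fragment_cell Fragment concentration in the cell, molar. For a real
#'   titration use the dilution-corrected mean over the fitted injections
#'   (see the methods vignette).
#'
#' @return Fragment dissociation constant, molar; `Inf` (no detectable
#'   affinity) when `kd_obs == kd_ref`.
#' @examples
#' kd_from_displacement(1e-7, 5e-7, 4.2e-3)
#' @export
kd_from_displacement <- function(kd_ref, kd_obs, fragment_cell) {
  if (!is.finite(kd_ref) || kd_ref <= 0) stop("`kd_ref` must be > 0")
  if (!is.finite(kd_obs) || kd_obs <= 0) stop("`kd_obs` must be > 0")
  if (!is.finite(fragment_cell) || fragment_cell <= 0) stop("`fragment_cell` must be > 0")
  k_ref <- 1 / kd_ref
  k_obs <- 1 / kd_obs
  if (k_obs > k_ref * (1 + 1e-12)) {
    stop("apparent affinity exceeds the reference affinity; displacement cannot sharpen binding")
  }
  ka_frag <- max(k_ref / k_obs - 1, 0) / fragment_cell
  if (ka_frag == 0) return(Inf)
  1 / ka_frag
}

#' Convert between dissociation constant and binding free energy
#'
#' Standard-state conversion \eqn{\Delta G = RT \ln(K_d / 1\,M)} (so a
#' sub-molar Kd gives a negative, favourable free energy) and its exact
#' inverse.
#'
#' @param kd Dissociation constant, molar.
#' @param dg Binding free energy, kJ/mol.
#' @param temperature Kelvin; default 298.15 (25 degrees C).
#'
#' @return `dg_from_kd`: kJ/mol. `kd_from_dg`: molar.
#' @examples
#' kd_from_dg(-37.3)          # ~2.9e-7 M
#' dg_from_kd(kd_from_dg(-37.3))  # -37.3, exact round trip
#' @export
dg_from_kd <- function(kd, temperature = 298.15) {
  if (any(!is.finite(kd) | kd <= 0)) stop("`kd` must be > 0")
  if (!is.finite(temperature) || temperature <= 0) stop("`temperature` must be > 0")
  .RGAS * temperature * log(kd)
}

#' @rdname dg_from_kd
#' @export
kd_from_dg <- function(dg, temperature = 298.15) {
  if (any(!is.finite(dg))) stop("`dg` must be finite")
  if (!is.finite(temperature) || temperature <= 0) stop("`temperature` must be > 0")
  exp(dg / (.RGAS * temperature))
}
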