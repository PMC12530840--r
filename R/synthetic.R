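#' Two-state contact kinetics
#'
#' Parameters of a first-order Markov (telegraph) model of a donor-acceptor
#' contact that switches between a bound state (short distance) and an
#' unbound state (long distance), with Gaussian jitter around each state
#' mean. The stationary bound fraction is
#' \deqn{\pi_b = \frac{1 - p_{uu}}{(1 - p_{bb}) + (1 - p_{uu})}.}
#'
#' @param p_stay_bound,p_stay_unbound Per-frame self-transition
#'   probabilities, each in (0, 1).
#' @param bound_mean,unbound_mean State mean distances, angstrom;
#'   `unbound_mean > bound_mean > 0`.
#' @param jitter_sd Gaussian jitter around the state mean, angstrom.
#'
#' @return A `two_state_kinetics` object; `$stationary_bound` holds the
#'   stationary bound fraction.
#' @examples
#' two_state_kinetics(0.999, 0.98)$stationary_bound  # ~0.95
#' @export
two_state_kinetics <- function(p_stay_bound, p_stay_unbound,
                               bound_mean = 2.9, unbound_mean = 6.0,
                               jitter_sd = 0.25) {
  for (p in c(p_stay_bound, p_stay_unbound)) {
    if (!is.finite(p) || p <= 0 || p >= 1) {
      stop("self-transition probabilities must lie strictly in (0, 1)")
    }
  }
  if (!(unbound_mean > bound_mean && bound_mean > 0)) {
    stop("need unbound_mean > bound_mean > 0")
  }
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  pb <- (1 - p_stay_unbound) /
    ((1 - p_stay_bound) + (1 - p_stay_unbound))
  structure(list(p_stay_bound = p_stay_bound,
                 p_stay_unbound = p_stay_unbound,
                 bound_mean = bound_mean, unbound_mean = unbound_mean,
                 jitter_sd = jitter_sd, stationary_bound = pb),
            class = "two_state_kinetics")
}

#' Simulated thermogram with measurement noise
#'
#' Runs the ideal integrated-heat simulation ([simulate_direct()] or, when
#' the schedule carries a preload and weak-ligand parameters are given,
#' [simulate_displacement()]) and adds i.i.d. Gaussian noise to the
#' per-injection heats. A fixed seed gives bitwise-identical output; the
#' caller's RNG state is untouched.
#'
#' @param params [binding_parameters()] of the titrant.
#' @param schedule An [injection_schedule()].
#' @param noise_sd Heat noise standard deviation, uJ. 0 returns the ideal
#'   simulation exactly.
#' @param seed Integer seed.
#' @param params_weak Optional [binding_parameters()] of a preloaded weak
#'   ligand (displacement mode).
#'
#' @return A `thermogram`; normalized heats are recomputed from the noisy
#'   heats.
#' @export
gen_thermogram <- function(params, schedule, noise_sd = 0, seed = 1,
                           params_weak = NULL) {
  ideal <- if (!is.null(params_weak)) {
    simulate_displacement(params, params_weak, schedule)
  } else {
    simulate_direct(params, schedule)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (noise_sd == 0) return(ideal)
  heats <- withr::with_seed(seed, {
    ideal$heats + stats::rnorm(length(ideal$heats), sd = noise_sd)
  })
  new_thermogram(heats, schedule, noise_sd = noise_sd)
}

#' Simulated two-state donor-acceptor distance series
#'
#' First-order Markov chain over bound/unbound states with Gaussian jitter
#' around the state mean distances. The initial state is drawn from the
#' stationary distribution so that occupancy estimates are unbiased at any
#' length. Jittered distances are truncated below at 0.5 angstrom to keep
#' them physical.
#'
#' @param kin A [two_state_kinetics()].
#' @param n_frames Number of frames, >= 1.
#' @param frame_interval ns per frame.
#' @param seed Integer seed.
#' @param start Optional fixed initial state (`"bound"` or `"unbound"`)
#'   instead of a stationary draw.
#'
#' @return A list: `series` (a `distance_series`) and `states` (the
#'   ground-truth logical bound sequence) so downstream tests never have to
#'   re-derive truth from the fixture.
#' @export
gen_distance_series <- function(kin, n_frames, frame_interval = 0.1,
                                seed = 1, start = NULL) {
  stopifnot(inherits(kin, "two_state_kinetics"), n_frames >= 1)
  out <- withr::with_seed(seed, {
    bound <- logical(n_frames)
    bound[1] <- if (is.null(start)) {
      stats::runif(1) < kin$stationary_bound
    } else {
      identical(start, "bound")
    }
    if (n_frames > 1) {
      u <- stats::runif(n_frames - 1)
      for (i in 2:n_frames) {
        bound[i] <- if (bound[i - 1]) u[i - 1] < kin$p_stay_bound
                    else u[i - 1] >= kin$p_stay_unbound
      }
    }
    mu <- ifelse(bound, kin$bound_mean, kin$unbound_mean)
    d <- pmax(mu + stats::rnorm(n_frames, sd = kin$jitter_sd), 0.5)
    list(d = d, bound = bound)
  })
  list(series = new_distance_series(out$d, frame_interval),
       states = out$bound)
}

#' Simulated pH titration curve
#'
#' Points on the one-proton deprotonation sigmoid
#' \eqn{f_{A^-}(pH) = 1/(1 + 10^{pK_a - pH})} over a pH grid, with Gaussian
#' noise clipped to `[0, 1]`. Warns when the grid does not span pKa +- 1,
#' since a curve that never crosses its transition cannot anchor the fit.
#'
#' @param pka Generating pKa.
#' @param ph_range Length-2 pH range.
#' @param n_points Number of equally spaced points.
#' @param noise_sd Gaussian noise on the fractions.
#' @param seed Integer seed.
#' @param replicate_id Label passed to [titration_curve()].
#'
#' @return A [titration_curve()].
#' @export
gen_ph_titration <- function(pka, ph_range = c(2, 7), n_points = 21,
                             noise_sd = 0, seed = 1, replicate_id = "r1") {
  stopifnot(length(ph_range) == 2L, n_points >= 2)
  if (ph_range[1] > pka - 1 || ph_range[2] < pka + 1) {
    warning(sprintf("pH range [%.2f, %.2f] does not span pKa %.2f +- 1; the fit may be ill-posed",
                    ph_range[1], ph_range[2], pka))
  }
  ph <- seq(ph_range[1], ph_range[2], length.out = n_points)
  fr <- 1 / (1 + 10^(pka - ph))
  if (noise_sd > 0) {
    fr <- withr::with_seed(seed, {
      pmin(pmax(fr + stats::rnorm(n_points, sd = noise_sd), 0), 1)
    })
  }
  titration_curve(ph, fr, replicate_id = replicate_id)
}

#' Write distance series as a minimal multi-model PDB trajectory
#'
#' Realises each distance series as one placeholder atom pair per frame: the
#' first atom of pair i sits at (20*i, 0, 0) and its partner at
#' (20*i + d, 0, 0), so re-reading the file and measuring distances
#' reproduces the input to within the 3-decimal PDB coordinate precision
#' (< 1e-3 angstrom). Pairs are written as residues numbered 1, 2, ... with
#' atom names `A1`/`A2`, parseable by [read_trajectory()].
#'
#' @param series_list Non-empty list of `distance_series` sharing one frame
#'   count.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
gen_trajectory_file <- function(series_list, path) {
  if (!is.list(series_list) || length(series_list) == 0 ||
      !all(vapply(series_list, inherits, TRUE, "distance_series"))) {
    stop("`series_list` must be a non-empty list of distance_series")
  }
  n_frames <- unique(vapply(series_list, function(s) length(s$distances), 0L))
  if (length(n_frames) != 1L) stop("all series must share one frame count")

  con <- file(path, "w")
  on.exit(close(con))
  fmt <- "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (i in seq_along(series_list)) {
      x0 <- 20 * i
      d <- series_list[[i]]$distances[f]
      serial <- serial + 1L
      writeLines(sprintf(fmt, serial, " A1 ", "PRB", "A", i,
                         x0, 0, 0, 1, 0, "C"), con)
      serial <- serial + 1L
      writeLines(sprintf(fmt, serial, " A2 ", "PRB", "A", i,
                         x0 + d, 0, 0, 1, 0, "C"), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Built-in synthetic hydrogen-bond scenarios
#'
#' Two caricature scenarios of a fragment in a kinase ATP site, stored in
#' `inst/extdata/hbond_scenarios.yaml` so that tests and documentation draw
#' on the same parameters. `"protonated"` keeps persistent hinge contacts
#' (Glu121 backbone carbonyl, Val123 amide) and no contact with Lys72 or
#' Thr183; `"deprotonated"` swaps the pattern: a stable Lys72 salt-bridge
#' contact, an intermittent Thr183 hydroxyl contact that breaks and reforms,
#' and no hinge contacts.
#'
#' @param name `"protonated"` or `"deprotonated"`.
#'
#' @return Named list of [two_state_kinetics()], one per contact
#'   (names `Glu121`, `Lys72`, `Val123`, `Thr183`).
#' @export
hbond_scenario <- function(name = c("protonated", "deprotonated")) {
  name <- match.arg(name)
  path <- system.file("extdata", "hbond_scenarios.yaml",
                      package = "protonbind", mustWork = TRUE)
  all <- yaml::read_yaml(path)
  lapply(all[[name]], function(p) {
    two_state_kinetics(p$p_stay_bound, p$p_stay_unbound,
                       p$bound_mean, p$unbound_mean, p$jitter_sd)
  })
}
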