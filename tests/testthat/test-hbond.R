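test_that("distance series reproduces hand-built geometry", {
  # two atoms forming a 3-4-5 triangle in every frame
  xyz <- matrix(rep(c(0, 0, 0, 3, 4, 0), 4), nrow = 4, byrow = TRUE)
  atoms <- data.frame(resid = c("GLU", "LIG"), resno = c(121, 1),
                      elety = c("O", "H"))
  tr <- trajectory(xyz, atoms, frame_interval = 0.1)
  d <- distance_series(tr, select_atoms(tr, 121, "O"), select_atoms(tr, 1, "H"))
  expect_equal(d$distances, rep(5, 4))
  expect_equal(d$times, (1:4) * 0.1)
  # single-frame trajectory
  tr1 <- trajectory(xyz[1, , drop = FALSE], atoms, frame_interval = 0.1)
  expect_length(distance_series(tr1, select_atoms(tr1, 121, "O"),
                                select_atoms(tr1, 1, "H"))$distances, 1)
  # unresolvable selection names the culprit
  expect_error(select_atoms(tr, 999, "O"), "999")
})

test_that("multi-atom selections use the per-frame minimum distance", {
  # carboxylate-like pair: two oxygens, the closer one varies by frame
  xyz <- rbind(c(0, 0, 0, 2, 0, 0, 9, 0, 0),
               c(0, 0, 0, 9, 0, 0, 3, 0, 0))
  atoms <- data.frame(resid = c("LYS", "LIG", "LIG"),
                      resno = c(72, 1, 1), elety = c("NZ", "O1", "O2"))
  tr <- trajectory(xyz, atoms, frame_interval = 1)
  d <- distance_series(tr, select_atoms(tr, 72, "NZ"),
                       select_atoms(tr, 1, c("O1", "O2")))
  expect_equal(d$distances, c(2, 3))
})

test_that("summary reproduces the hand-countable example and its degenerate limits", {
  s <- new_distance_series(c(2, 2, 4, 2, 4, 4), frame_interval = 1)
  sm <- summarize_hbond(s, cutoff = 3.5, gap_tolerance = 0)
  expect_equal(sm$occupancy, 0.5)
  expect_equal(sm$n_segments, 2)
  expect_equal(sm$longest_segment, 2)
  expect_equal(sm$n_break_events, 2)
  expect_equal(sm$n_reform_events, 1)
  # fully bonded
  sm1 <- summarize_hbond(new_distance_series(rep(2, 10), 1))
  expect_equal(sm1$occupancy, 1)
  expect_equal(sm1$n_segments, 1)
  expect_equal(sm1$longest_segment, 10)
  expect_equal(sm1$n_break_events + sm1$n_reform_events, 0)
  # a tie at exactly the cutoff counts as bonded
  expect_equal(summarize_hbond(new_distance_series(c(3.5, 3.5), 1))$occupancy, 1)
  # extreme cutoffs
  d <- new_distance_series(runif(50, 1, 8), 1)
  expect_equal(summarize_hbond(d, cutoff = Inf)$occupancy, 1)
  expect_equal(summarize_hbond(d, cutoff = 0)$occupancy, 0)
})

test_that("summary matches the brute-force run-length oracle on random binary series", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    bonded <- runif(n) < runif(1)
    gap <- sample(0:2, 1)
    d <- ifelse(bonded, 2, 6)
    sm <- summarize_hbond(new_distance_series(d, 1), gap_tolerance = gap)
    orc <- oracle_runs(bonded, gap)
    expect_equal(sm$n_segments, orc$n_segments)
    expect_equal(sm$longest_segment, orc$longest)
    expect_equal(sm$n_break_events, orc$breaks)
    expect_equal(sm$n_reform_events, orc$reforms)
    expect_equal(sm$occupancy, mean(bonded))
  }
})

test_that("occupancy grows with cutoff and segments shrink with gap tolerance", {
  g <- gen_distance_series(two_state_kinetics(0.98, 0.95), 2000, 0.1, seed = 5)
  occ <- vapply(c(2, 3, 3.5, 4, 5, 7),
                function(ct) summarize_hbond(g$series, cutoff = ct)$occupancy, 0)
  expect_true(all(diff(occ) >= 0))
  nseg <- vapply(0:5, function(gt)
    summarize_hbond(g$series, gap_tolerance = gt)$n_segments, 0L)
  expect_true(all(diff(nseg) <= 0))
})

test_that("telegraph-process occupancy matches the stationary bound fraction", {
  kin <- two_state_kinetics(0.997, 0.993)  # stationary 0.7
  expect_equal(kin$stationary_bound, 0.7, tolerance = 1e-12)
  g <- gen_distance_series(kin, 10000, 0.1, seed = 31)
  sm <- summarize_hbond(g$series)
  # binomial-approximation band, inflated for the chain's autocorrelation
  sd3 <- 3 * sqrt(0.7 * 0.3 / 10000) *
    sqrt((2 - kin$p_stay_bound - kin$p_stay_unbound)^-1 * 2)
  expect_lt(abs(sm$occupancy - 0.7), max(3 * sd3, 0.05))
  # distance-threshold states agree with the generator ground truth
  expect_gt(mean((g$series$distances <= 3.5) == g$states), 0.99)
})

test_that("report contrasts the protonated and deprotonated scenario fixtures", {
  mk_traj <- function(scn, seed0) {
    kins <- hbond_scenario(scn)
    sers <- lapply(seq_along(kins), function(i) {
      gen_distance_series(kins[[i]], 4000, 0.25, seed = seed0 + i)$series
    })
    names(sers) <- names(kins)
    path <- tempfile(fileext = ".pdb")
    gen_trajectory_file(sers, path)
    tr <- read_trajectory(path, 0.25)
    pairs <- lapply(seq_along(sers), function(i) {
      list(select_atoms(tr, i, "A1", label = names(sers)[i]),
           select_atoms(tr, i, "A2", label = "ligand"))
    })
    hbond_report(tr, pairs)
  }
  prot <- mk_traj("protonated", 400)
  rownames(prot) <- sub(" --.*", "", prot$pair)
  expect_gt(prot["Glu121", "occupancy"], 0.85)
  expect_gt(prot["Val123", "occupancy"], 0.85)
  expect_lt(prot["Lys72", "occupancy"], 0.1)
  expect_lt(prot["Thr183", "occupancy"], 0.1)

  deprot <- mk_traj("deprotonated", 500)
  rownames(deprot) <- sub(" --.*", "", deprot$pair)
  expect_lt(deprot["Glu121", "occupancy"], 0.1)
  expect_lt(deprot["Val123", "occupancy"], 0.1)
  expect_gt(deprot["Lys72", "occupancy"], 0.75)
  # Thr183 contact is intermediate and breaks/reforms
  expect_gt(deprot["Thr183", "occupancy"], 0.2)
  expect_lt(deprot["Thr183", "occupancy"], 0.8)
  expect_gte(deprot["Thr183", "n_breaks"], 1)
  expect_gte(deprot["Thr183", "n_reforms"], 1)
})

test_that("report collects per-pair errors without aborting and handles empty input", {
  xyz <- matrix(c(0, 0, 0, 3, 0, 0), nrow = 1)
  atoms <- data.frame(resid = c("GLU", "LIG"), resno = c(121, 1),
                      elety = c("O", "H"))
  tr <- trajectory(xyz, atoms, 1)
  rep <- hbond_report(tr, list(
    list(list(resno = 121, name = "O", label = NULL),
         list(resno = 1, name = "H", label = NULL)),
    list(list(resno = 999, name = "XX", label = NULL),
         list(resno = 1, name = "H", label = NULL))))
  expect_equal(nrow(rep), 2)
  expect_true(is.na(rep$error[1]))
  expect_match(rep$error[2], "999")
  expect_equal(nrow(hbond_report(tr, list())), 0)
})
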