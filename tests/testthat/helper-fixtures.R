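# Shared fixtures: the study's titration geometries and independent oracles.

# 19-injection protocol (0.4 uL + 18 x 2 uL) for the two experiment layouts
schedule_direct_lowc <- function() {
  injection_schedule(syringe_conc = 2.8e-3, cell_protein_conc = 140e-6)
}
schedule_displacement <- function(preload = 4.2e-3) {
  injection_schedule(syringe_conc = 300e-6, cell_protein_conc = 20e-6,
                     cell_preload_conc = preload)
}

# Independent single-site oracle: bisection on the complex concentration,
# no quadratic formula involved.
oracle_single_site <- function(p, l, kd, tol = 1e-14) {
  f <- function(x) (p - x) * (l - x) / kd - x
  lo <- 0; hi <- min(p, l)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(hi, 1e-300)) break
  }
  (lo + hi) / 2
}

# Independent competitive oracle built on stats::uniroot over free protein.
oracle_competitive <- function(p, a, b, ka, kb) {
  g <- function(pf) pf * (1 + a / (ka + pf) + b / (kb + pf)) - p
  pf <- stats::uniroot(g, c(0, p), tol = 1e-16)$root
  c(ca = a * pf / (ka + pf), cb = b * pf / (kb + pf))
}

# O(n^2)-ish brute-force run-length oracle over a binary bonded vector:
# enumerates every maximal bonded run by scanning all start positions.
oracle_runs <- function(bonded, gap_tolerance = 0) {
  n <- length(bonded)
  if (gap_tolerance > 0) {
    # bridge unbonded gaps <= gap_tolerance strictly between bonded frames
    b2 <- bonded
    i <- 1
    while (i <= n) {
      if (!bonded[i]) {
        j <- i
        while (j < n && !bonded[j + 1]) j <- j + 1
        if (i > 1 && j < n && (j - i + 1) <= gap_tolerance) b2[i:j] <- TRUE
        i <- j + 1
      } else i <- i + 1
    }
    bonded <- b2
  }
  segs <- list()
  i <- 1
  while (i <= n) {
    if (bonded[i] && (i == 1 || !bonded[i - 1])) {
      j <- i
      while (j < n && bonded[j + 1]) j <- j + 1
      segs[[length(segs) + 1]] <- c(start = i, end = j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(segs) == 0) {
    return(list(n_segments = 0L, longest = 0L, breaks = 0L, reforms = 0L))
  }
  m <- do.call(rbind, segs)
  list(n_segments = nrow(m),
       longest = as.integer(max(m[, "end"] - m[, "start"] + 1)),
       breaks = as.integer(sum(m[, "end"] < n)),
       reforms = as.integer(sum(m[, "start"] > 1)))
}
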