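#' Trajectory container
#'
#' A lightweight in-memory trajectory: per-frame coordinates plus an atom
#' table. Coordinates are in angstrom, the frame interval in nanoseconds.
#'
#' @param xyz Numeric matrix, one row per frame, 3 columns per atom
#'   (x1, y1, z1, x2, ...), as returned by `bio3d::read.pdb(multi = TRUE)`.
#' @param atoms Data frame with columns `resid` (residue name), `resno`
#'   (residue number) and `elety` (atom name), one row per atom.
#' @param frame_interval Time between frames, ns.
#'
#' @return A `trajectory` object.
#' @export
trajectory <- function(xyz, atoms, frame_interval) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0) stop("`xyz` must have 3 columns per atom")
  n_atoms <- ncol(xyz) / 3
  if (nrow(atoms) != n_atoms) {
    stop(sprintf("atom table has %d rows but coordinates describe %d atoms",
                 nrow(atoms), n_atoms))
  }
  stopifnot(all(c("resid", "resno", "elety") %in% names(atoms)))
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be > 0 (ns)")
  }
  structure(list(xyz = xyz, atoms = as.data.frame(atoms),
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %.4g ns (%.4g ns total)\n",
              nrow(x$xyz), nrow(x$atoms), x$frame_interval,
              nrow(x$xyz) * x$frame_interval))
  invisible(x)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses MODEL/ENDMDL records with `bio3d::read.pdb(multi = TRUE)`. The
#' frame interval is metadata the file format does not carry, so it must be
#' supplied.
#'
#' @param path Path to a multi-model PDB file.
#' @param frame_interval Time between models, ns.
#'
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, frame_interval) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  trajectory(xyz, pdb$atom[, c("resid", "resno", "elety")], frame_interval)
}

#' Select atoms by residue number and atom name
#'
#' @param traj A [trajectory()].
#' @param resno Residue number(s).
#' @param name Atom name(s), e.g. `"O"`, `"H"`, `"OG1"`.
#' @param label Optional label for reports; defaults to
#'   `"<resid><resno>:<name>"` of the first matching atom.
#'
#' @return An `atom_selection`: integer atom indices with a `label`
#'   attribute. Errors if nothing matches.
#' @export
select_atoms <- function(traj, resno, name, label = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- which(traj$atoms$resno %in% resno & traj$atoms$elety %in% name)
  if (length(idx) == 0) {
    stop(sprintf("selection resolves to no atoms: resno %s, name %s",
                 paste(resno, collapse = "/"), paste(name, collapse = "/")))
  }
  if (is.null(label)) {
    label <- sprintf("%s%d:%s", traj$atoms$resid[idx[1]],
                     traj$atoms$resno[idx[1]], traj$atoms$elety[idx[1]])
  }
  structure(idx, label = label, class = "atom_selection")
}

#' Donor-acceptor distance time series
#'
#' Euclidean distance between two atom selections in every frame. Selections
#' with several atoms (e.g. both oxygens of a rotatable carboxylate) use the
#' minimum pairwise distance per frame, matching how an intermittent contact
#' of a symmetric group is perceived.
#'
#' @param traj A [trajectory()].
#' @param a,b [select_atoms()] selections (or bare atom index vectors).
#'
#' @return A `distance_series`: list with `times` (ns), `distances`
#'   (angstrom), `label_a`, `label_b`, `frame_interval`.
#' @export
distance_series <- function(traj, a, b) {
  stopifnot(inherits(traj, "trajectory"))
  la <- attr(a, "label") %||% paste0("atoms ", paste(a, collapse = ","))
  lb <- attr(b, "label") %||% paste0("atoms ", paste(b, collapse = ","))
  n_frames <- nrow(traj$xyz)
  d <- rep(Inf, n_frames)
  for (ia in as.integer(a)) {
    xa <- traj$xyz[, 3 * ia - 2, drop = TRUE]
    ya <- traj$xyz[, 3 * ia - 1, drop = TRUE]
    za <- traj$xyz[, 3 * ia, drop = TRUE]
    for (ib in as.integer(b)) {
      di <- sqrt((xa - traj$xyz[, 3 * ib - 2])^2 +
                 (ya - traj$xyz[, 3 * ib - 1])^2 +
                 (za - traj$xyz[, 3 * ib])^2)
      d <- pmin(d, di)
    }
  }
  new_distance_series(d, traj$frame_interval, la, lb)
}

#' Build a distance series from raw values
#'
#' Low-level constructor used by the generators and handy in analyses that
#' already have distances in hand (times are `1:n * frame_interval`).
#'
#' @param distances Positive distances, angstrom.
#' @param frame_interval ns per frame.
#' @param label_a,label_b Endpoint labels.
#'
#' @return A `distance_series`.
#' @export
new_distance_series <- function(distances, frame_interval, label_a = "a",
                                label_b = "b") {
  if (any(distances <= 0)) stop("distances must be positive")
  structure(list(times = seq_along(distances) * frame_interval,
                 distances = as.numeric(distances),
                 frame_interval = frame_interval,
                 label_a = label_a, label_b = label_b),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s -- %s: %d frames, %.2f-%.2f A\n",
              x$label_a, x$label_b, length(x$distances),
              min(x$distances), max(x$distances)))
  invisible(x)
}

# run-length segmentation of a logical vector after bridging FALSE gaps of
# length <= gap_tolerance that sit between TRUE runs
bonded_segments <- function(bonded, gap_tolerance = 0) {
  if (gap_tolerance > 0 && any(bonded)) {
    r <- rle(bonded)
    n <- length(r$values)
    for (k in seq_len(n)) {
      if (!r$values[k] && r$lengths[k] <= gap_tolerance &&
          k > 1 && k < n) {
        r$values[k] <- TRUE
      }
    }
    bonded <- inverse.rle(r)
  }
  r <- rle(bonded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Hydrogen-bond occupancy and persistence summary
#'
#' Applies a distance criterion (default 3.5 angstrom, the conventional
#' cutoff for hydrogen bonds; distances at exactly the cutoff count as
#' bonded) to a donor-acceptor distance series and summarises occupancy and
#' the break/reform structure of the contact. Segments are maximal runs of
#' bonded frames after bridging unbonded gaps of at most `gap_tolerance`
#' frames; a break event is a segment ending before the final frame, a
#' reform event a segment starting after the first frame.
#'
#' @param series A `distance_series` (or bare numeric distances, taken at a
#'   1-frame-per-ns interval).
#' @param cutoff Distance criterion, angstrom; default 3.5.
#' @param gap_tolerance Number of consecutive unbonded frames bridged when
#'   they fall between bonded runs; default 0.
#'
#' @return An `hbond_summary`: `occupancy` (fraction of frames bonded,
#'   before gap bridging), `longest_segment` (ns; frames times interval),
#'   `n_segments`, `n_break_events`, `n_reform_events`, `cutoff`,
#'   `gap_tolerance`, `n_frames`.
#' @examples
#' s <- new_distance_series(c(2, 2, 4, 2, 4, 4), frame_interval = 1)
#' summarize_hbond(s)  # occupancy 0.5, 2 segments, 2 breaks, 1 reform
#' @export
summarize_hbond <- function(series, cutoff = 3.5, gap_tolerance = 0) {
  if (!inherits(series, "distance_series")) {
    series <- new_distance_series(series, frame_interval = 1)
  }
  d <- series$distances
  if (length(d) == 0) stop("empty distance series")
  if (cutoff < 0) stop("`cutoff` must be >= 0")
  bonded <- d <= cutoff
  seg <- bonded_segments(bonded, gap_tolerance)
  n <- length(d)
  structure(list(
    occupancy = mean(bonded),
    longest_segment = if (nrow(seg)) max(seg$length) * series$frame_interval else 0,
    n_segments = nrow(seg),
    n_break_events = if (nrow(seg)) sum(seg$end < n) else 0L,
    n_reform_events = if (nrow(seg)) sum(seg$start > 1) else 0L,
    cutoff = cutoff, gap_tolerance = gap_tolerance,
    n_frames = n,
    label_a = series$label_a, label_b = series$label_b),
    class = "hbond_summary")
}

#' @export
print.hbond_summary <- function(x, ...) {
  cat(sprintf("<hbond_summary> %s -- %s (cutoff %.2f A): occupancy %.1f%%, %d segment(s), longest %.4g ns, %d break(s), %d reform(s)\n",
              x$label_a, x$label_b, x$cutoff, 100 * x$occupancy,
              x$n_segments, x$longest_segment, x$n_break_events,
              x$n_reform_events))
  invisible(x)
}

#' Hydrogen-bond report over several donor-acceptor pairs
#'
#' Runs [distance_series()] and [summarize_hbond()] for each pair and
#' returns one row per pair, in input order. A pair whose selection fails
#' produces an `error` entry in its row without aborting the others.
#'
#' @param traj A [trajectory()].
#' @param pairs A list; each element is a list/pair of two [select_atoms()]
#'   selections (or of two `list(resno=, name=)` specs resolved against
#'   `traj`).
#' @param cutoff,gap_tolerance Passed to [summarize_hbond()].
#'
#' @return A data frame with columns `pair`, `occupancy`,
#'   `longest_segment_ns`, `n_breaks`, `n_reforms`, `error`.
#' @export
hbond_report <- function(traj, pairs, cutoff = 3.5, gap_tolerance = 0) {
  stopifnot(inherits(traj, "trajectory"), is.list(pairs))
  empty <- data.frame(pair = character(), occupancy = numeric(),
                      longest_segment_ns = numeric(), n_breaks = integer(),
                      n_reforms = integer(), error = character())
  if (length(pairs) == 0) return(empty)
  resolve <- function(sel) {
    if (inherits(sel, "atom_selection")) return(sel)
    select_atoms(traj, sel$resno, sel$name, label = sel$label)
  }
  rows <- lapply(pairs, function(pr) {
    tryCatch({
      a <- resolve(pr[[1]])
      b <- resolve(pr[[2]])
      s <- summarize_hbond(distance_series(traj, a, b), cutoff, gap_tolerance)
      data.frame(pair = paste(s$label_a, s$label_b, sep = " -- "),
                 occupancy = s$occupancy,
                 longest_segment_ns = s$longest_segment,
                 n_breaks = s$n_break_events,
                 n_reforms = s$n_reform_events,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(pair = NA_character_, occupancy = NA_real_,
                 longest_segment_ns = NA_real_, n_breaks = NA_integer_,
                 n_reforms = NA_integer_, error = conditionMessage(e))
    })
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
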