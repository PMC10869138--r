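#' Trajectories
#'
#' A `trajectory` stores frames of Cartesian coordinates (Angstrom) saved at
#' a fixed stride `dt_save` (ns per frame), together with the
#' [structure_model()] they belong to. The elapsed time of frame `i`
#' (1-based) is `(i - 1) * dt_save` ns, i.e. the first saved frame sits at
#' t = 0.
#'
#' @param coords Either an `n_atoms x 3 x n_frames` array or a list of
#'   `n_atoms x 3` matrices.
#' @param dt_save Saving interval in ns per frame (> 0).
#' @param structure The [structure_model()] the coordinates refer to.
#' @return A `trajectory` object.
#' @export
trajectory <- function(coords, dt_save, structure) {
  stopifnot(inherits(structure, "structure_model"))
  check_scalar(dt_save, "dt_save", positive = TRUE)
  if (is.list(coords)) {
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, length(coords)))
  }
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    abort("coords must be an n_atoms x 3 x n_frames array",
          class = "tcrmech_value_error")
  }
  if (dim(coords)[1] != nrow(structure$atoms)) {
    abort(sprintf("frame atom count (%d) != structure atom count (%d)",
                  dim(coords)[1], nrow(structure$atoms)),
          class = "tcrmech_value_error")
  }
  structure(
    list(coords = coords, dt_save = dt_save, structure = structure),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt_save = %g ns (%g ns total)\n",
              n_frames(x), dim(x$coords)[1], x$dt_save, total_time(x)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Total simulated time covered by the saved frames (ns)
#' @param traj A [trajectory()].
#' @export
total_time <- function(traj) n_frames(traj) * traj$dt_save

#' Frame times in ns (time of frame i is (i-1) * dt_save)
#' @param traj A [trajectory()].
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$dt_save

#' Coordinates of one frame
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return An `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Number of saved frames for a simulated duration
#'
#' With coordinates saved every `dt_save` ns, a run of `duration` ns yields
#' `floor(duration / dt_save)` frames (e.g. 50,000 frames for 1000 ns at a
#' 20-ps stride).
#'
#' @param duration Simulated time in ns (>= 0).
#' @param dt_save Saving interval in ns (> 0).
#' @return Integer frame count.
#' @export
frames_for_duration <- function(duration, dt_save) {
  check_scalar(duration, "duration", nonneg = TRUE)
  check_scalar(dt_save, "dt_save", positive = TRUE)
  # guard the floor against binary representation of, e.g., 1000/0.02
  as.integer(floor(duration / dt_save + 1e-9))
}

#' Extract the frames of a time interval
#'
#' Keeps frames whose time lies in `[start, end)` ns. The input trajectory
#' is untouched; frame times in the slice are re-zeroed bookkeeping-wise
#' (frame 1 of the slice is the first frame at or after `start`).
#'
#' @param traj A [trajectory()].
#' @param start,end Interval bounds in ns, `0 <= start < end <= total_time`.
#' @return A new [trajectory()].
#' @export
slice_trajectory <- function(traj, start, end) {
  check_scalar(start, "start", nonneg = TRUE)
  check_scalar(end, "end")
  if (start >= end) {
    abort("inverted range: need start < end", class = "tcrmech_value_error")
  }
  if (end > total_time(traj) + 1e-9) {
    abort(sprintf("slice end %g ns beyond trajectory end %g ns",
                  end, total_time(traj)), class = "tcrmech_value_error")
  }
  t <- frame_times(traj)
  keep <- which(t >= start - 1e-9 & t < end - 1e-9)
  trajectory(traj$coords[, , keep, drop = FALSE], traj$dt_save, traj$structure)
}

# 1-based frame indices at or after the equilibration cut (ns).
frames_after_cut <- function(traj, cut_ns) {
  which(frame_times(traj) >= cut_ns - 1e-9)
}

#' Analysis window settings
#'
#' Defaults follow the analysis recipe used throughout the package:
#' averages and standard deviations exclude the first 500 ns of a run;
#' time-resolved statistics use 40-ns windows stepping by 20 ns starting at
#' 200 ns (200-240, 220-260, ...); instantaneous occupancy is a 40-frame
#' trailing rolling mean (0.8 ns at a 20-ps stride).
#'
#' @param equilibration_cut Equilibration time excluded from averages (ns).
#' @param window Window length for time-resolved statistics (ns).
#' @param step Step between window starts (ns); `step <= window`.
#' @param window_start Start of the first window (ns).
#' @param rolling_frames Width of the instantaneous-occupancy rolling mean,
#'   in frames.
#' @return An `analysis_windows` object.
#' @export
analysis_windows <- function(equilibration_cut = 500, window = 40, step = 20,
                             window_start = 200, rolling_frames = 40) {
  check_scalar(equilibration_cut, "equilibration_cut", nonneg = TRUE)
  check_scalar(window, "window", positive = TRUE)
  check_scalar(step, "step", positive = TRUE)
  check_scalar(window_start, "window_start", nonneg = TRUE)
  check_scalar(rolling_frames, "rolling_frames", positive = TRUE)
  if (window < step) {
    abort("need window >= step", class = "tcrmech_value_error")
  }
  structure(
    list(equilibration_cut = equilibration_cut, window = window, step = step,
         window_start = window_start, rolling_frames = as.integer(rolling_frames)),
    class = "analysis_windows"
  )
}

#' Window spans covering a run
#'
#' @param windows An [analysis_windows()].
#' @param total_time Run length in ns.
#' @return A tibble with columns `window`, `start`, `end` (ns), e.g.
#'   200-240, 220-260, 240-280 for the defaults.
#' @export
window_spans <- function(windows, total_time) {
  stopifnot(inherits(windows, "analysis_windows"))
  if (total_time < windows$window_start + windows$window - 1e-9) {
    abort(sprintf("trajectory (%g ns) shorter than window_start + window (%g ns)",
                  total_time, windows$window_start + windows$window),
          class = "tcrmech_value_error")
  }
  starts <- seq(windows$window_start, total_time - windows$window + 1e-9,
                by = windows$step)
  tibble(window = seq_along(starts), start = starts, end = starts + windows$window)
}

## ---- file formats -----------------------------------------------------

#' Write / read the plain-text frame format
#'
#' A deliberately simple, diffable trajectory format for fixtures: one
#' header line `n_atoms dt_save`, then `x y z` (Angstrom, `%.4f`) per atom,
#' frame after frame.
#'
#' @param traj A [trajectory()].
#' @param path Output / input file path.
#' @param structure For [read_frames()], the [structure_model()] the
#'   coordinates belong to.
#' @return `write_frames()` returns `path` invisibly; `read_frames()`
#'   returns a [trajectory()].
#' @export
write_frames <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %.6g", dim(traj$coords)[1], traj$dt_save), con)
  for (i in seq_len(n_frames(traj))) {
    m <- traj$coords[, , i, drop = TRUE]
    writeLines(sprintf("%.4f %.4f %.4f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path, structure) {
  if (!file.exists(path)) {
    abort(sprintf("frame file not found: %s", path),
          class = "tcrmech_parse_error")
  }
  lines <- readLines(path)
  if (length(lines) < 1) abort("empty frame file", class = "tcrmech_parse_error")
  hdr <- scan(text = lines[1], quiet = TRUE)
  if (length(hdr) != 2 || hdr[1] < 1 || hdr[2] <= 0) {
    abort("frame file header must be: n_atoms dt_save",
          class = "tcrmech_parse_error")
  }
  n_atoms <- as.integer(hdr[1])
  body <- scan(text = lines[-1], quiet = TRUE)
  if (length(body) %% (3 * n_atoms) != 0) {
    abort("frame file body is not a whole number of frames",
          class = "tcrmech_parse_error")
  }
  nf <- length(body) / (3 * n_atoms)
  coords <- aperm(array(body, dim = c(3, n_atoms, nf)), c(2, 1, 3))
  trajectory(coords, hdr[2], structure)
}

#' Read a DCD trajectory
#'
#' Thin adapter over [bio3d::read.dcd()]. DCD stores no time step, so
#' `dt_save` must be given.
#'
#' @param path Path to a DCD file.
#' @param structure The matching [structure_model()].
#' @param dt_save Saving interval in ns per frame.
#' @return A [trajectory()].
#' @export
read_dcd_trajectory <- function(path, structure, dt_save) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  if (na != nrow(structure$atoms)) {
    abort(sprintf("DCD atom count (%d) != structure atom count (%d)",
                  na, nrow(structure$atoms)), class = "tcrmech_value_error")
  }
  coords <- aperm(array(t(xyz), dim = c(3, na, nf)), c(2, 1, 3))
  trajectory(coords, dt_save, structure)
}

#' Read a multi-model PDB as a trajectory
#'
#' @param path Path to a PDB file with MODEL/ENDMDL records.
#' @param dt_save Saving interval in ns per frame.
#' @param charge_table,annotate Passed to [read_structure()] semantics for
#'   the first model, which defines the structure.
#' @return A [trajectory()].
#' @export
read_pdb_trajectory <- function(path, dt_save, charge_table = NULL,
                                annotate = TRUE) {
  mod <- read_structure(path, charge_table = charge_table, annotate = annotate)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- aperm(array(t(xyz), dim = c(3, na, nf)), c(2, 1, 3))
  trajectory(coords, dt_save, mod)
}

## ---- alignment --------------------------------------------------------

#' Superpose every frame onto a reference
#'
#' Least-squares (Kabsch) superposition of the atoms in `fit_idx` of each
#' frame onto the same atoms of `reference`; the fitted rigid motion is
#' applied to all atoms of the frame.
#'
#' @param traj A [trajectory()].
#' @param fit_idx Atom indices used for the fit.
#' @param reference Reference coordinates: an `n_atoms x 3` matrix (same
#'   atom set as the trajectory) or `NULL` for the trajectory's first frame.
#' @return A new, aligned [trajectory()].
#' @export
align_trajectory <- function(traj, fit_idx, reference = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(fit_idx) >= 3)
  ref <- reference %||% frame_coords(traj, 1)
  ref_sel <- ref[fit_idx, , drop = FALSE]
  out <- traj$coords
  for (i in seq_len(n_frames(traj))) {
    m <- traj$coords[, , i, drop = TRUE]
    fit <- kabsch(m[fit_idx, , drop = FALSE], ref_sel)
    out[, , i] <- apply_kabsch(m, fit)
  }
  trajectory(out, traj$dt_save, traj$structure)
}

#' One-line summary of a structure + trajectory pair
#'
#' @param structure A [structure_model()].
#' @param traj Optional [trajectory()].
#' @return A tibble with atom/chain/frame counts and time coverage.
#' @export
trajectory_info <- function(structure, traj = NULL) {
  out <- tibble(
    n_atoms = nrow(structure$atoms),
    n_chains = length(structure$chains),
    chains = paste(structure$chains, collapse = ","),
    has_charges = any(!is.na(structure$atoms$charge))
  )
  if (!is.null(traj)) {
    out$n_frames <- n_frames(traj)
    out$dt_save_ns <- traj$dt_save
    out$total_ns <- total_time(traj)
  }
  out
}
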