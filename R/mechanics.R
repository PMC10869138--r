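#' Unit conversion: kcal/(mol A) to pN
#'
#' 1 kcal/(mol Angstrom) = 69.479 pN.
#'
#' @param f Force in kcal/(mol A).
#' @return Force in pN.
#' @export
kcal_mol_A_to_pN <- function(f) f * .pN_per_kcal_mol_A

#' Harmonic positional restraint specification
#'
#' Load is applied by holding two anchors at fixed positions with harmonic
#' restraints of stiffness `k` (energy `E = k/2 |x - x0|^2`, so the force
#' on a displaced anchor is `k (x - x0)`). An anchor resolves either to a
#' single atom (e.g. the C-alpha of the MHC-strand terminus) or to the
#' unweighted centre of mass of a small atom group (e.g. the two TCR
#' C-terminal C-alpha atoms). A flat-bottom pair restraint between the two
#' TCR terminal atoms engages beyond a 10-Angstrom separation.
#'
#' @param anchor Anchor atom selection: atom indices or a spec for
#'   [atom_group()]; more than one atom means the group centre of mass.
#' @param center Restraint centre, a 3-vector (Angstrom).
#' @param k Spring constant in kcal/(mol A^2) (default 1.0).
#' @param extension Optional extension label in Angstrom (bookkeeping).
#' @param energy_convention `"half_k"` (default; `E = k/2 dx^2`, force
#'   `k dx`, per-coordinate thermal rms `sqrt(kB T / k)`), or `"full_k"`
#'   (`E = k dx^2`, force `2 k dx`).
#' @param flat_bottom_onset,flat_bottom_k Flat-bottom pair restraint: onset
#'   distance (Angstrom) and stiffness (kcal/(mol A^2)).
#' @return A `restraint_spec` object.
#' @export
restraint_spec <- function(anchor, center, k = 1.0, extension = NA_real_,
                           energy_convention = c("half_k", "full_k"),
                           flat_bottom_onset = 10, flat_bottom_k = 1.0) {
  check_scalar(k, "k", positive = TRUE)
  stopifnot(length(center) == 3)
  structure(
    list(anchor = anchor, center = as.numeric(center), k = k,
         extension = extension,
         energy_convention = match.arg(energy_convention),
         flat_bottom_onset = flat_bottom_onset,
         flat_bottom_k = flat_bottom_k),
    class = "restraint_spec"
  )
}

anchor_positions <- function(traj, anchor) {
  idx <- atom_group(traj$structure, anchor)
  nf <- n_frames(traj)
  t(vapply(seq_len(nf), function(i) {
    colMeans(traj$coords[idx, , i, drop = FALSE])
  }, numeric(3)))
}

#' Estimate the applied force from a restrained anchor
#'
#' The force is the deviation of the anchor's average position from the
#' restraint centre, multiplied by the spring constant, converted to pN
#' (69.479 pN per kcal/(mol A)). The headline value averages frames after
#' the equilibration cut; window means use the overlapping analysis
#' windows (40 ns stepping 20 ns from 200 ns by default), and their
#' standard deviation is reported alongside.
#'
#' @param traj A [trajectory()].
#' @param restraint A [restraint_spec()].
#' @param windows An [analysis_windows()].
#' @param axis Optional load axis for the longitudinal/transverse
#'   decomposition: a 3-vector or 2 x 3 matrix of anchor centres.
#' @return A `force_estimate`: list with `mean_force_pN` (3-vector),
#'   `magnitude_pN`, `window_forces` (tibble `window`, `start`, `end`,
#'   `magnitude_pN`), `window_sd_pN`, and when `axis` is given
#'   `longitudinal_pN`/`transverse_pN`.
#' @export
estimate_force <- function(traj, restraint, windows = analysis_windows(),
                           axis = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(restraint, "restraint_spec"))
  pos <- anchor_positions(traj, restraint$anchor)
  k_eff <- if (restraint$energy_convention == "half_k") restraint$k else 2 * restraint$k
  t <- frame_times(traj)
  post <- which(t >= windows$equilibration_cut - 1e-9)
  if (length(post) == 0) {
    abort("equilibration cut leaves no frames", class = "tcrmech_value_error")
  }
  dx <- colMeans(pos[post, , drop = FALSE]) - restraint$center
  fvec <- kcal_mol_A_to_pN(k_eff * dx)
  spans <- tryCatch(window_spans(windows, total_time(traj)),
                    error = function(e) NULL)
  wf <- if (!is.null(spans)) {
    mag <- map_dbl(seq_len(nrow(spans)), function(i) {
      idx <- which(t >= spans$start[i] - 1e-9 & t < spans$end[i] - 1e-9)
      d <- colMeans(pos[idx, , drop = FALSE]) - restraint$center
      vec_norm(kcal_mol_A_to_pN(k_eff * d))
    })
    mutate(spans, magnitude_pN = mag)
  } else {
    tibble(window = integer(0), start = numeric(0), end = numeric(0),
           magnitude_pN = numeric(0))
  }
  out <- list(
    mean_force_pN = fvec,
    magnitude_pN = vec_norm(fvec),
    window_forces = wf,
    window_sd_pN = if (nrow(wf) > 1) sd(wf$magnitude_pN) else NA_real_,
    k = restraint$k, energy_convention = restraint$energy_convention
  )
  if (!is.null(axis)) {
    dec <- force_decomposition(matrix(fvec, nrow = 1), axis)
    out$longitudinal_pN <- dec$longitudinal
    out$transverse_pN <- dec$transverse
  }
  structure(out, class = "force_estimate")
}

#' @export
print.force_estimate <- function(x, ...) {
  cat(sprintf("<force_estimate> %.2f pN (window sd %.2f pN over %d windows)\n",
              x$magnitude_pN, x$window_sd_pN, nrow(x$window_forces)))
  invisible(x)
}

#' @export
glance.force_estimate <- function(x, ...) {
  tibble(
    magnitude_pN = x$magnitude_pN,
    window_sd_pN = x$window_sd_pN,
    n_windows = nrow(x$window_forces),
    longitudinal_pN = x$longitudinal_pN %||% NA_real_,
    transverse_pN = x$transverse_pN %||% NA_real_
  )
}

#' @export
tidy.force_estimate <- function(x, ...) x$window_forces

#' Per-window force trace plot
#' @param object A `force_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.force_estimate <- function(object, ...) {
  d <- object$window_forces
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$magnitude_pN)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window centre (ns)", y = "force (pN)")
}

#' Thermal fluctuation amplitude of a harmonic restraint
#'
#' Per-coordinate root-mean-square fluctuation of a coordinate confined by
#' `E = k/2 x^2` at temperature `T`: `sqrt(kB T / k)` by equipartition.
#' At k = 1 kcal/(mol A^2) and 300 K this is 0.772 Angstrom.
#'
#' @param k Spring constant in kcal/(mol A^2).
#' @param T Temperature in K.
#' @param energy_convention `"half_k"` (default) or `"full_k"`
#'   (`E = k x^2`, rms `sqrt(kB T / (2k))`).
#' @return RMS amplitude in Angstrom.
#' @export
thermal_amplitude <- function(k, T = 300,
                              energy_convention = c("half_k", "full_k")) {
  check_scalar(k, "k", positive = TRUE)
  check_scalar(T, "T", positive = TRUE)
  k_eff <- switch(match.arg(energy_convention), half_k = k, full_k = 2 * k)
  sqrt(.kB_kcal_mol_K * T / k_eff)
}

#' Longitudinal / transverse force decomposition
#'
#' Projects per-frame force vectors onto the load axis; the residual
#' in-plane magnitude is the transverse component. Per frame,
#' `|F|^2 = F_par^2 + F_perp^2`.
#'
#' @param force_vectors An `n x 3` matrix (or 3-vector) of forces.
#' @param axis Load axis: 3-vector or 2 x 3 matrix of anchor centres.
#' @return A list with per-frame `longitudinal` (signed) and `transverse`
#'   (magnitude) components plus their means `mean_longitudinal`,
#'   `mean_transverse`.
#' @export
force_decomposition <- function(force_vectors, axis) {
  if (is.vector(force_vectors)) force_vectors <- matrix(force_vectors, nrow = 1)
  if (is.matrix(axis)) axis <- axis[2, ] - axis[1, ]
  if (vec_norm(axis) < 1e-9) {
    abort("zero load axis", class = "tcrmech_configuration_error")
  }
  u <- unit(axis)
  lon <- as.vector(force_vectors %*% u)
  perp <- force_vectors - outer(lon, u)
  list(longitudinal = lon, transverse = vec_norm(perp),
       mean_longitudinal = mean(lon), mean_transverse = mean(vec_norm(perp)))
}

#' Flat-bottom pair restraint force
#'
#' Zero below the onset separation; harmonic beyond it, with force
#' `k (d - onset)` (energy `k/2 (d - onset)^2`).
#'
#' @param pair_distance Separation(s) in Angstrom (>= 0).
#' @param onset Onset distance in Angstrom (default 10).
#' @param k Stiffness in kcal/(mol A^2) (default 1.0).
#' @return Restoring force magnitude in kcal/(mol A); multiply with
#'   [kcal_mol_A_to_pN()] for pN.
#' @export
flat_bottom_force <- function(pair_distance, onset = 10, k = 1.0) {
  stopifnot(all(pair_distance >= 0))
  check_scalar(onset, "onset", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  pmax(0, k * (pair_distance - onset))
}
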