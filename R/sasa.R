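#' SASA sampling parameters
#'
#' Shrake-Rupley sphere sampling: each atom's solvent-accessible surface is
#' probed at `n_points` deterministically placed (golden-spiral) points on
#' the sphere of radius `r_atom + probe`; a point is accessible when it
#' lies outside every neighbour's probe-inflated sphere. 960 points per
#' atom keeps the single-sphere error well below 1%.
#'
#' @param n_points Sample points per atom (default 960).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param radii Named vector of van der Waals radii per element (Angstrom);
#'   unknown elements fall back to `default_radius`.
#' @param default_radius Radius for elements missing from `radii`.
#' @return A `sasa_params` object.
#' @export
sasa_params <- function(n_points = 960, probe = 1.4,
                        radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                  H = 1.20, P = 1.80),
                        default_radius = 1.70) {
  check_scalar(n_points, "n_points", positive = TRUE)
  check_scalar(probe, "probe", nonneg = TRUE)
  structure(list(n_points = as.integer(n_points), probe = probe,
                 radii = radii, default_radius = default_radius),
            class = "sasa_params")
}

atom_radii <- function(elements, params) {
  r <- params$radii[elements]
  r[is.na(r)] <- params$default_radius
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param radii Per-atom van der Waals radii (length n).
#' @param params A [sasa_params()].
#' @param subset Indices of atoms whose SASA is wanted (default all);
#'   occlusion still considers every atom in `coords`.
#' @return Numeric vector of per-atom SASA in Angstrom^2 for `subset`.
#' @export
shrake_rupley <- function(coords, radii, params = sasa_params(),
                          subset = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, length(radii) == nrow(coords))
  subset <- subset %||% seq_len(nrow(coords))
  pts <- sphere_points(params$n_points)
  rp <- radii + params$probe
  out <- numeric(length(subset))
  for (s in seq_along(subset)) {
    i <- subset[s]
    ri <- rp[i]
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (ri + rp)^2 & seq_len(nrow(coords)) != i)
    if (length(nb) == 0) {
      out[s] <- 4 * pi * ri^2
      next
    }
    p <- sweep(pts * ri, 2, coords[i, ], `+`)
    free <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums(sweep(p[free, , drop = FALSE], 2, coords[j, ])^2)
      free[free] <- dj > rp[j]^2
    }
    out[s] <- 4 * pi * ri^2 * sum(free) / params$n_points
  }
  out
}

#' Buried surface area of interfacial residues
#'
#' Selects residues of the receptor side whose maximum instantaneous
#' contact occupancy with the partner exceeds `bsa_inst_max`, then per
#' frame computes, for each selected residue, SASA in the receptor alone
#' minus SASA in the complex (probe 1.4 Angstrom). The total BSA is the sum
#' over selected residues; the per-residue BSA is the total divided by the
#' number of selected residues. Mean and standard deviation are taken over
#' post-equilibration frames.
#'
#' @param traj A [trajectory()].
#' @param group_side,group_partner Atom groups (see [atom_group()]) for the
#'   receptor side and its partner.
#' @param timelines Optional precomputed `contact_timelines` for this
#'   interface; built from `traj` when `NULL`.
#' @param criteria A [contact_criteria()] (only used when building
#'   timelines).
#' @param thresholds An [occupancy_thresholds()] (supplies `bsa_inst_max`).
#' @param windows An [analysis_windows()].
#' @param params A [sasa_params()].
#' @param stride Analyse every `stride`-th post-equilibration frame
#'   (default 1); SASA is the slow step.
#' @return A `bsa_result`: list with `residues` (tibble of selected
#'   residues), `per_frame` (tibble `frame`, `time`, `total_bsa`),
#'   `total_bsa` (mean), `total_bsa_sd`, `per_residue_bsa`.
#' @export
compute_bsa <- function(traj, group_side, group_partner, timelines = NULL,
                        criteria = contact_criteria(),
                        thresholds = occupancy_thresholds(),
                        windows = analysis_windows(),
                        params = sasa_params(), stride = 1) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$structure$atoms
  i_side <- atom_group(traj$structure, group_side)
  i_part <- atom_group(traj$structure, group_partner)
  if (is.null(timelines)) {
    timelines <- build_timelines(traj, i_side, i_part, criteria, windows)
  }
  max_inst <- apply(inst_occupancy(timelines), 2, max)
  sel_keys <- timelines$keys[max_inst > thresholds$bsa_inst_max, ]
  residues <- distinct(tibble(chain = sel_keys$chain_a,
                              resno = sel_keys$resno_a,
                              resid = sel_keys$resid_a)) |>
    arrange(.data$chain, .data$resno)
  if (nrow(residues) == 0) {
    warn("no residue passes the BSA occupancy criterion; total BSA is 0")
    return(structure(list(residues = residues,
                          per_frame = tibble(frame = integer(0),
                                             time = numeric(0),
                                             total_bsa = numeric(0)),
                          total_bsa = 0, total_bsa_sd = 0,
                          per_residue_bsa = 0),
                     class = "bsa_result"))
  }
  res_atoms <- purrr::map(seq_len(nrow(residues)), function(r) {
    intersect(i_side, which(a$chain == residues$chain[r] &
                              a$resno == residues$resno[r] &
                              !a$is_hydrogen))
  })
  heavy_side <- i_side[!a$is_hydrogen[i_side]]
  heavy_part <- i_part[!a$is_hydrogen[i_part]]
  complex_idx <- c(heavy_side, heavy_part)
  rad_all <- atom_radii(a$element, params)
  sel_atoms <- unlist(res_atoms)
  frames <- frames_after_cut(traj, windows$equilibration_cut)
  if (length(frames) == 0) {
    abort("equilibration cut leaves no frames", class = "tcrmech_value_error")
  }
  frames <- frames[seq(1, length(frames), by = stride)]
  totals <- numeric(length(frames))
  for (f in seq_along(frames)) {
    m <- traj$coords[, , frames[f], drop = TRUE]
    alone <- shrake_rupley(m[heavy_side, , drop = FALSE], rad_all[heavy_side],
                           params,
                           subset = match(sel_atoms, heavy_side))
    complexed <- shrake_rupley(m[complex_idx, , drop = FALSE],
                               rad_all[complex_idx], params,
                               subset = match(sel_atoms, complex_idx))
    totals[f] <- sum(alone - complexed)
  }
  t <- (frames - 1) * traj$dt_save
  structure(
    list(residues = residues,
         per_frame = tibble(frame = frames, time = t, total_bsa = totals),
         total_bsa = mean(totals),
         total_bsa_sd = if (length(totals) > 1) sd(totals) else 0,
         per_residue_bsa = mean(totals) / nrow(residues)),
    class = "bsa_result"
  )
}

#' @export
print.bsa_result <- function(x, ...) {
  cat(sprintf("<bsa_result> %d residues, total BSA %.1f +/- %.1f A^2 (%.1f A^2 per residue)\n",
              nrow(x$residues), x$total_bsa, x$total_bsa_sd, x$per_residue_bsa))
  invisible(x)
}

#' @export
glance.bsa_result <- function(x, ...) {
  tibble(n_residues = nrow(x$residues), total_bsa = x$total_bsa,
         total_bsa_sd = x$total_bsa_sd, per_residue_bsa = x$per_residue_bsa)
}
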