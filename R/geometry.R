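#' Bead-on-chain (BOC) specification
#'
#' The V-C bead-on-chain reduces the TCR to six beads per frame: the Valpha
#' and Vbeta triad-core centroids, the Calpha and Cbeta constant-domain
#' core centroids, and the two hinge beads Halpha (C-alpha of alpha-chain
#' residue 114) and Hbeta (midpoint of the C-alpha atoms of beta-chain
#' residues 117 and 118). Frames are first superposed on the C-module core
#' atoms of a reference frame, so bead motion reads as V-module motion
#' relative to the C-module.
#'
#' Default constant-domain cores (renumbered A6 indices): Calpha A118-R123,
#' V132-D137, Y153-T158, S171-S176; Cbeta T143-A148, L158-N163, S192-V197,
#' F209-Q214.
#'
#' @param chain_alpha,chain_beta Chain ids of the TCR alpha / beta chains.
#' @param valpha,vbeta [triad_spec()]s for the variable domains.
#' @param calpha_segments,cbeta_segments Lists of `c(first, last)`
#'   renumbered residue ranges for the constant-domain cores.
#' @param hinge_alpha Renumbered alpha-chain residue whose C-alpha is the
#'   Halpha bead.
#' @param hinge_beta Two renumbered beta-chain residues whose C-alpha
#'   midpoint is the Hbeta bead.
#' @return A `boc_spec` object.
#' @export
boc_spec <- function(chain_alpha = "D", chain_beta = "E",
                     valpha = triad_spec_valpha(chain_alpha),
                     vbeta = triad_spec_vbeta(chain_beta),
                     calpha_segments = list(c(118, 123), c(132, 137),
                                            c(153, 158), c(171, 176)),
                     cbeta_segments = list(c(143, 148), c(158, 163),
                                           c(192, 197), c(209, 214)),
                     hinge_alpha = 114, hinge_beta = c(117, 118)) {
  structure(list(chain_alpha = chain_alpha, chain_beta = chain_beta,
                 valpha = valpha, vbeta = vbeta,
                 calpha_segments = calpha_segments,
                 cbeta_segments = cbeta_segments,
                 hinge_alpha = hinge_alpha, hinge_beta = hinge_beta),
            class = "boc_spec")
}

seg_resnos <- function(segments) {
  unlist(lapply(segments, function(s) seq(s[1], s[2])))
}

# C-module core C-alpha indices (Calpha + Cbeta cores), used for alignment.
c_module_indices <- function(structure, spec) {
  c(ca_indices(structure, spec$chain_alpha, seg_resnos(spec$calpha_segments)),
    ca_indices(structure, spec$chain_beta, seg_resnos(spec$cbeta_segments)))
}

#' Build the V-C bead-on-chain trajectory
#'
#' Each frame is least-squares superposed (Kabsch) on the C-module core
#' C-alpha atoms of `reference`, then the six beads are emitted. Using one
#' common reference across runs makes average BOCs comparable between
#' simulations.
#'
#' @param traj A [trajectory()].
#' @param spec A [boc_spec()].
#' @param reference Reference coordinates for the C-module alignment: an
#'   `n_atoms x 3` matrix over the same atom set, or `NULL` for the
#'   trajectory's first frame.
#' @return A `boc_model`: list with `beads` (`6 x 3 x n_frames` array, bead
#'   order Va, Vb, Ca, Cb, Ha, Hb), `dt_save`, `spec`.
#' @export
build_boc <- function(traj, spec = boc_spec(), reference = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(spec, "boc_spec"))
  st <- traj$structure
  idx <- list(
    Va = ca_indices(st, spec$chain_alpha, spec_resnos(spec$valpha)),
    Vb = ca_indices(st, spec$chain_beta, spec_resnos(spec$vbeta)),
    Ca = ca_indices(st, spec$chain_alpha, seg_resnos(spec$calpha_segments)),
    Cb = ca_indices(st, spec$chain_beta, seg_resnos(spec$cbeta_segments)),
    Ha = ca_indices(st, spec$chain_alpha, spec$hinge_alpha),
    Hb = ca_indices(st, spec$chain_beta, spec$hinge_beta)
  )
  fit_idx <- c(idx$Ca, idx$Cb)
  ref <- reference %||% frame_coords(traj, 1)
  ref_sel <- ref[fit_idx, , drop = FALSE]
  nf <- n_frames(traj)
  beads <- array(0, dim = c(6, 3, nf),
                 dimnames = list(c("Va", "Vb", "Ca", "Cb", "Ha", "Hb"),
                                 c("x", "y", "z"), NULL))
  for (i in seq_len(nf)) {
    m <- traj$coords[, , i, drop = TRUE]
    m <- apply_kabsch(m, kabsch(m[fit_idx, , drop = FALSE], ref_sel))
    for (b in names(idx)) {
      beads[b, , i] <- colMeans(m[idx[[b]], , drop = FALSE])
    }
  }
  structure(list(beads = beads, dt_save = traj$dt_save, spec = spec),
            class = "boc_model")
}

#' @export
print.boc_model <- function(x, ...) {
  cat(sprintf("<boc_model> 6 beads x %d frames\n", dim(x$beads)[3]))
  invisible(x)
}

#' @export
tidy.boc_model <- function(x, ...) {
  nf <- dim(x$beads)[3]
  beads <- dimnames(x$beads)[[1]]
  tibble(
    frame = rep(seq_len(nf), each = 6),
    time = rep((seq_len(nf) - 1) * x$dt_save, each = 6),
    bead = rep(beads, times = nf),
    x = as.vector(x$beads[, 1, ]),
    y = as.vector(x$beads[, 2, ]),
    z = as.vector(x$beads[, 3, ])
  )
}

#' Hinge angles of the bead-on-chain
#'
#' The alpha-chain hinge angle is the angle at the Halpha bead between the
#' vectors Halpha->Va and Halpha->Ca, in degrees (180 when collinear);
#' analogously for the beta chain. Arm definitions are configurable.
#'
#' @param boc A `boc_model` from [build_boc()].
#' @param arms_alpha,arms_beta Character 3-vectors `c(tip, vertex, tip)`
#'   naming the beads of each angle.
#' @return A tibble `frame`, `time`, `angle_alpha`, `angle_beta` (degrees).
#' @export
hinge_angles <- function(boc, arms_alpha = c("Va", "Ha", "Ca"),
                         arms_beta = c("Vb", "Hb", "Cb")) {
  stopifnot(inherits(boc, "boc_model"))
  ang <- function(arms) {
    v1 <- t(boc$beads[arms[1], , ] - boc$beads[arms[2], , ])
    v2 <- t(boc$beads[arms[3], , ] - boc$beads[arms[2], , ])
    n1 <- vec_norm(v1)
    n2 <- vec_norm(v2)
    if (any(n1 < 1e-9) || any(n2 < 1e-9)) {
      abort("coincident beads: hinge angle undefined",
            class = "tcrmech_geometry_error")
    }
    acos_deg(rowSums(v1 * v2) / (n1 * n2))
  }
  nf <- dim(boc$beads)[3]
  tibble(
    frame = seq_len(nf),
    time = (seq_len(nf) - 1) * boc$dt_save,
    angle_alpha = ang(arms_alpha),
    angle_beta = ang(arms_beta)
  )
}

#' CDR3 distance
#'
#' Distance between the midpoint of the C-alpha atoms of the two CDR3alpha
#' base residues (renumbered alpha-chain T92 and K97 by default) and the
#' midpoint of the two CDR3beta base residues (beta-chain R94 and E103).
#'
#' @param x A [trajectory()] or a [structure_model()] (single frame).
#' @param alpha,beta Lists `list(chain, resno)` naming the two base
#'   residues of each loop.
#' @return For a structure, a single distance in Angstrom; for a
#'   trajectory, a tibble `frame`, `time`, `value` (Angstrom).
#' @export
cdr3_distance <- function(x, alpha = list(chain = "D", resno = c(92, 97)),
                          beta = list(chain = "E", resno = c(94, 103))) {
  st <- if (inherits(x, "trajectory")) x$structure else x
  stopifnot(inherits(st, "structure_model"))
  ia <- ca_indices(st, alpha$chain, alpha$resno)
  ib <- ca_indices(st, beta$chain, beta$resno)
  dist_of <- function(m) {
    vec_norm(colMeans(m[ia, , drop = FALSE]) - colMeans(m[ib, , drop = FALSE]))
  }
  if (inherits(x, "structure_model")) {
    return(dist_of(structure_coords(x)))
  }
  nf <- n_frames(x)
  val <- vapply(seq_len(nf), function(i) dist_of(x$coords[, , i, drop = TRUE]),
                numeric(1))
  tibble(frame = seq_len(nf), time = (seq_len(nf) - 1) * x$dt_save,
         value = val)
}

#' Peptide tilt angle relative to the V-module
#'
#' At each frame, the least-squares fit line through the peptide backbone
#' C-alpha atoms is compared with the vector joining the Valpha and Vbeta
#' triad centroids. Because the fit line is undirected, the angle is
#' reported acute, in \[0, 90\] degrees.
#'
#' @param traj A [trajectory()].
#' @param peptide_chain Chain id of the peptide.
#' @param triads_alpha,triads_beta `triad_series` for the two variable
#'   domains (fitted with [fit_triads()] on the same trajectory), or `NULL`
#'   to fit them here with the default specs.
#' @param valpha,vbeta [triad_spec()]s used when fitting here.
#' @return A tibble `frame`, `time`, `value` (degrees).
#' @export
peptide_angle <- function(traj, peptide_chain = "C",
                          triads_alpha = NULL, triads_beta = NULL,
                          valpha = triad_spec_valpha(),
                          vbeta = triad_spec_vbeta()) {
  stopifnot(inherits(traj, "trajectory"))
  pep_res <- unique(traj$structure$atoms$resno[
    traj$structure$atoms$chain == peptide_chain])
  pep_idx <- ca_indices(traj$structure, peptide_chain, sort(pep_res))
  if (length(pep_idx) < 2) {
    abort("peptide line fit needs at least 2 C-alpha atoms",
          class = "tcrmech_geometry_error")
  }
  triads_alpha <- triads_alpha %||% fit_triads(traj, valpha)
  triads_beta <- triads_beta %||% fit_triads(traj, vbeta)
  nf <- n_frames(traj)
  val <- vapply(seq_len(nf), function(i) {
    m <- traj$coords[pep_idx, , i, drop = TRUE]
    centred <- sweep(m, 2, colMeans(m))
    d <- eigen(crossprod(centred), symmetric = TRUE)$vectors[, 1]
    v <- triads_beta$centroid[i, ] - triads_alpha$centroid[i, ]
    acos_deg(abs(sum(d * unit(v))))
  }, numeric(1))
  tibble(frame = seq_len(nf), time = (seq_len(nf) - 1) * traj$dt_save,
         value = val)
}

#' Running average of a scalar series
#'
#' Trailing rolling mean of `value` over a `width_ns` window (truncated at
#' the start), added as column `run_avg`.
#'
#' @param series A tibble with columns `time` and `value` at fixed stride.
#' @param width_ns Window width in ns (e.g. 50).
#' @return The series with an extra `run_avg` column.
#' @export
running_average <- function(series, width_ns) {
  stopifnot(all(c("time", "value") %in% names(series)), nrow(series) >= 2)
  dt <- series$time[2] - series$time[1]
  k <- max(1L, as.integer(round(width_ns / dt)))
  mutate(series, run_avg = rolling_mean_trailing(.data$value, k))
}

#' Interval statistics of a scalar series
#'
#' @param series A tibble with `time` and `value`.
#' @param interval `c(start, end)` ns (end-exclusive) or `NULL` for all.
#' @return A one-row tibble `mean`, `sd`, `n`.
#' @export
series_stats <- function(series, interval = NULL) {
  v <- series$value
  if (!is.null(interval)) {
    keep <- series$time >= interval[1] - 1e-9 & series$time < interval[2] - 1e-9
    v <- v[keep]
  }
  if (length(v) == 0) {
    abort("interval contains no samples", class = "tcrmech_value_error")
  }
  tibble(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0, n = length(v))
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are superposed (Kabsch) on `alignment_selection` against the
#' reference, then each selected atom's RMSF is the root-mean-square
#' deviation from its mean position across frames.
#'
#' @param traj A [trajectory()].
#' @param selection Atom indices to report (see [atom_group()]).
#' @param alignment_selection Atom indices used for superposition
#'   (default: the selection itself).
#' @param reference Reference coordinates (`n_atoms x 3`) or `NULL` for the
#'   first frame (the start of the production run).
#' @return A tibble `atom_id`, `chain`, `resno`, `name`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection, alignment_selection = NULL,
                 reference = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- atom_group(traj$structure, selection)
  if (length(sel) == 0) {
    abort("empty selection", class = "tcrmech_value_error")
  }
  fit_idx <- if (is.null(alignment_selection)) sel else {
    atom_group(traj$structure, alignment_selection)
  }
  aligned <- align_trajectory(traj, fit_idx, reference)
  nf <- n_frames(aligned)
  xs <- aligned$coords[sel, , , drop = FALSE]
  mean_pos <- apply(xs, c(1, 2), mean)
  dev2 <- array(0, dim = c(length(sel), nf))
  for (i in seq_len(nf)) {
    dev2[, i] <- rowSums((xs[, , i, drop = TRUE] - mean_pos)^2)
  }
  a <- traj$structure$atoms[sel, ]
  tibble(atom_id = a$atom_id, chain = a$chain, resno = a$resno,
         name = a$name, rmsf = sqrt(rowMeans(dev2)))
}

#' Transverse RMSF of a group's centre of mass
#'
#' RMSF of the centre of mass of `group` projected onto the plane
#' orthogonal to the load axis; measures lateral excursion of, e.g., the
#' peptide under an end-to-end restraint.
#'
#' @param traj A [trajectory()].
#' @param group Atom indices (see [atom_group()]) whose unweighted centre
#'   of mass is tracked.
#' @param axis Load-axis direction: a 3-vector, or a 2 x 3 matrix of the
#'   two restraint anchor points whose difference defines it.
#' @return The transverse RMSF in Angstrom. The per-frame transverse
#'   displacement components are attached as attribute `"per_frame"`.
#' @export
transverse_rmsf <- function(traj, group, axis) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- atom_group(traj$structure, group)
  if (is.matrix(axis)) {
    stopifnot(nrow(axis) == 2, ncol(axis) == 3)
    axis <- axis[2, ] - axis[1, ]
  }
  if (length(axis) != 3 || vec_norm(axis) < 1e-9) {
    abort("load axis undefined (zero vector)",
          class = "tcrmech_configuration_error")
  }
  u <- unit(axis)
  nf <- n_frames(traj)
  com <- t(vapply(seq_len(nf), function(i) {
    colMeans(traj$coords[idx, , i, drop = FALSE])
  }, numeric(3)))
  transverse <- com - outer(as.vector(com %*% u), u)
  dev <- sweep(transverse, 2, colMeans(transverse))
  out <- sqrt(mean(rowSums(dev^2)))
  attr(out, "per_frame") <- tibble(
    frame = seq_len(nf), time = (seq_len(nf) - 1) * traj$dt_save,
    transverse_displacement = vec_norm(dev)
  )
  out
}
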