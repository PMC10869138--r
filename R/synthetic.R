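# Synthetic trajectories with known ground truth.
#
# The generator builds a minimal TCR-pMHC-like complex out of C-alpha
# pseudo-atoms -- planar four-strand beta-sheet cores for the four
# V/C domains, hinge residues, a nine-residue peptide, restraint anchor
# atoms and a pool of interfacial contact sites -- and animates it with
# prescribed rigid-body rotational modes, scheduled contact toggling and
# Ornstein-Uhlenbeck restrained anchors. Every analysis stage can then be
# checked by parameter recovery.

# Evaluate expr with a local RNG seeded at `seed`, restoring global state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic domain template
#'
#' Builds a C-alpha pseudo-atom [structure_model()] shaped like a
#' TCR-pMHC complex and laid out so the package's default residue
#' specifications resolve directly: chain D (TCR alpha analogue, residues
#' 1-177 with the 177th a terminal anchor), chain E (TCR beta analogue,
#' 1-215 with the 215th a terminal anchor), chain C (nine-residue
#' peptide), chain A (one pseudo-atom per interfacial contact site plus an
#' MHC-side anchor). The two TCR chains are mirror images across the
#' x = 0 plane, so mirror-symmetric modes give zero amplitude asymmetry.
#'
#' Contact sites come pre-annotated: hydrogen-bond sites pair a donor
#' nitrogen on the TCR side with an acceptor oxygen on chain A; nonpolar
#' sites pair carbons carrying 0.05 e; all other atoms carry 0.5 e so they
#' can never satisfy the nonpolar charge criterion.
#'
#' @param n_hbond_sites,n_nonpolar_sites Number of contact sites of each
#'   kind (alternating between the two TCR chains).
#' @param off_distance Site separation (Angstrom) when a contact is
#'   scheduled off (default 6, outside both cutoffs).
#' @return A [structure_model()] with attributes `sites` (tibble of
#'   contact sites), `groups` (named atom-index lists for the rigid
#'   bodies), `anchors` (restraint anchor indices) and `layout` (key
#'   template coordinates).
#' @export
make_domain_template <- function(n_hbond_sites = 6, n_nonpolar_sites = 6,
                                 off_distance = 6) {
  x_alpha <- -9
  x_beta <- 9
  strand_z <- function(r) 3.4 * (r - 1)
  # four-strand core grid around (x0, 0, 0..17); segments 1,4 inner, 2,3 outer
  core_grid <- function(x0, mirror) {
    sgn <- if (mirror) -1 else 1
    # inner sheet nearer the partner domain (towards x = 0)
    offs <- list(c(sgn * 2, -2.4), c(-sgn * 2, -2.4),
                 c(-sgn * 2, 2.4), c(sgn * 2, 2.4))
    do.call(rbind, lapply(1:4, function(s) {
      cbind(x0 + offs[[s]][1], offs[[s]][2], strand_z(1:6))
    }))
  }
  rows <- list()
  add <- function(chain, resno, xyz, name = "CA", element = "C",
                  resid = "GLY") {
    rows[[length(rows) + 1]] <<- tibble(
      chain = chain, resno = resno, resid = resid, name = name,
      element = element, x = xyz[1], y = xyz[2], z = xyz[3]
    )
  }
  place_chain <- function(chain, x0, mirror, v_segs, cdr3, n_v, hinge,
                          c_segs, n_total) {
    core_v <- core_grid(x0, mirror)
    core_c <- core_grid(x0, mirror)
    core_c[, 3] <- core_c[, 3] - 22            # C-domain core z in [-22, -5]
    v_res <- unlist(lapply(v_segs, function(s) seq(s[1], s[2])))
    c_res <- unlist(lapply(c_segs, function(s) seq(s[1], s[2])))
    for (r in seq_len(n_total)) {
      if (r %in% v_res) {
        add(chain, r, core_v[match(r, v_res), ])
      } else if (r %in% cdr3) {
        dx <- if (match(r, cdr3) == 1) -1 else 1
        add(chain, r, c(x0 + dx, 0, 20))
      } else if (r %in% hinge) {
        dy <- if (length(hinge) == 2) c(-0.5, 0.5)[match(r, hinge)] else 0
        add(chain, r, c(x0, dy, -2))
      } else if (r %in% c_res) {
        add(chain, r, core_c[match(r, c_res), ])
      } else if (r == n_total) {               # terminal anchor
        add(chain, r, c(x0 / 4.5, 0, -40))
      } else {
        # filler: rigid with whichever module its index falls in, laid out
        # on a 3.6-Angstrom grid so no two atoms sit within contact range
        gx <- 3.6 * (r %% 6)
        gy <- 6 + 3.6 * ((r %/% 6) %% 6)
        gz <- 3.6 * (r %/% 36)
        side <- if (mirror) 1 else -1   # grid grows away from the mirror plane
        if (r < min(hinge)) {
          add(chain, r, c(x0 + side * (6 + gx), gy, 2 + gz))
        } else {
          add(chain, r, c(x0 + side * (6 + gx), gy, -30 - gz))
        }
      }
    }
  }
  place_chain("D", x_alpha, FALSE,
              list(c(19, 24), c(32, 37), c(70, 75), c(86, 91)), c(92, 97),
              113, 114, list(c(118, 123), c(132, 137), c(153, 158),
                             c(171, 176)), 177)
  place_chain("E", x_beta, TRUE,
              list(c(20, 25), c(33, 38), c(74, 79), c(88, 93)), c(94, 103),
              116, c(117, 118), list(c(143, 148), c(158, 163),
                                     c(192, 197), c(209, 214)), 215)
  for (r in 1:9) add("C", r, c(-8 + 2 * (r - 1), 0, 24), resid = "ALA")
  # contact sites: TCR partners on filler residues D40.. / E40..
  n_sites <- n_hbond_sites + n_nonpolar_sites
  kinds <- c(rep("hbond", n_hbond_sites), rep("nonpolar", n_nonpolar_sites))
  partner_chain <- rep(c("D", "E"), length.out = n_sites)
  partner_resno <- 40 + 2 * (ceiling(seq_len(n_sites) / 2) - 1)
  for (j in seq_len(n_sites)) {
    add("A", j, c(0, 0, 0), resid = "SER",
        element = if (kinds[j] == "hbond") "O" else "C")
  }
  add("A", n_sites + 1, c(0, 0, 45), resid = "ILE")  # MHC-side anchor
  atoms <- bind_rows(rows)
  atoms$charge <- 0.5
  mod <- structure_model(atoms, renumber = TRUE)
  a <- mod$atoms
  idx_of <- function(chain, resno) {
    vapply(resno, function(r) which(a$chain == chain & a$resno == r)[1],
           integer(1))
  }
  sites <- tibble(
    site = seq_len(n_sites), kind = kinds,
    tcr_chain = partner_chain, tcr_resno = partner_resno,
    a_resno = seq_len(n_sites),
    tcr_idx = unname(mapply(function(ch, r) idx_of(ch, r),
                            partner_chain, partner_resno)),
    a_idx = idx_of("A", seq_len(n_sites))
  )
  # annotations and charges at the sites
  don <- rep(FALSE, nrow(a)); acc <- rep(FALSE, nrow(a))
  hb <- sites[sites$kind == "hbond", ]
  np <- sites[sites$kind == "nonpolar", ]
  don[hb$tcr_idx] <- TRUE
  acc[hb$a_idx] <- TRUE
  mod$atoms$element[hb$tcr_idx] <- "N"
  mod$atoms$charge[c(np$tcr_idx, np$a_idx)] <- 0.05
  mod <- assign_donors_acceptors(mod, donors = don, acceptors = acc)
  # place A-side site atoms at their off positions
  co <- structure_coords(mod)
  co[sites$a_idx, ] <- co[sites$tcr_idx, ] +
    matrix(rep(c(0, 0, off_distance), each = nrow(sites)), ncol = 3)
  mod$atoms$x <- co[, 1]; mod$atoms$y <- co[, 2]; mod$atoms$z <- co[, 3]
  groups <- list(
    valpha = which(a$chain == "D" & a$resno <= 113),
    vbeta = which(a$chain == "E" & a$resno <= 116),
    calpha = which(a$chain == "D" & a$resno >= 117 & a$resno <= 176),
    cbeta = which(a$chain == "E" & a$resno >= 119 & a$resno <= 214),
    peptide = which(a$chain == "C")
  )
  anchors <- list(
    mhc = idx_of("A", n_sites + 1),
    tcr = c(idx_of("D", 177), idx_of("E", 215))
  )
  layout <- list(
    x_alpha = x_alpha, x_beta = x_beta,
    hinge_alpha = unname(colMeans(co[idx_of("D", 114), , drop = FALSE])),
    hinge_beta = unname(colMeans(co[idx_of("E", c(117, 118)), , drop = FALSE])),
    valpha_centroid = unname(colMeans(co[ca_indices(mod, "D",
      spec_resnos(triad_spec_valpha("D"))), , drop = FALSE])),
    vbeta_centroid = unname(colMeans(co[ca_indices(mod, "E",
      spec_resnos(triad_spec_vbeta("E"))), , drop = FALSE])),
    off_distance = off_distance
  )
  attr(mod, "sites") <- sites
  attr(mod, "groups") <- groups
  attr(mod, "anchors") <- anchors
  attr(mod, "layout") <- layout
  mod
}

#' Interface groups of the synthetic template
#'
#' @param template A template from [make_domain_template()].
#' @return `list(group_a, group_b)`: chain A site atoms vs the two TCR
#'   chains, for [build_timelines()] and friends.
#' @export
synthetic_interface <- function(template) {
  sites <- attr(template, "sites")
  a <- template$atoms
  list(group_a = sites$a_idx,
       group_b = which(a$chain %in% c("D", "E")))
}

## ---- modes ------------------------------------------------------------

# A mode is a list: kind, amplitude (deg, peak-to-peak), baseline (deg),
# period (ns) or tau (ns, OU), waveform, and parts -- each part a list
# (group, axis, pivot, weight) meaning "rotate `group` by weight * theta
# about `axis` through `pivot`".
new_mode <- function(kind, amplitude, period, baseline, waveform, tau, parts) {
  check_scalar(amplitude, "amplitude", nonneg = TRUE)
  structure(list(kind = kind, amplitude = amplitude, period = period,
                 baseline = baseline, waveform = waveform, tau = tau,
                 parts = parts),
            class = "synthetic_mode")
}

#' Prescribed rotational modes for the synthetic generator
#'
#' Each mode rotates rigid groups of the template by a time-dependent
#' angle `theta(t) = baseline + (amplitude/2) sin(2 pi t / period)`
#' (degrees; `amplitude` is the peak-to-peak range) or, with
#' `waveform = "ou"`, by an Ornstein-Uhlenbeck angle with stationary
#' standard deviation `amplitude/2` and correlation time `tau` about
#' `baseline`. The named modes reproduce the classic relative Valpha-Vbeta
#' rotations: `scissor` (counter-rotation about e1: angle e1 fixed, e2 and
#' e3 respond), `flap` (about e2), `twist` (about e3) and `hinge_bend`
#' (each V domain about the y axis through its own hinge bead, so the
#' hinge angle departs from 180 degrees by `theta`).
#'
#' @param amplitude Peak-to-peak angle range in degrees.
#' @param period Sinusoid period in ns.
#' @param baseline Baseline angle in degrees (defaults to `amplitude`, so
#'   the relative angle never folds through zero).
#' @param waveform `"sine"`, `"ou"`, or `"constant"` (theta fixed at
#'   `baseline`).
#' @param tau OU correlation time in ns (`waveform = "ou"`).
#' @param chains For `mode_hinge_bend()`: bend `"both"` V domains
#'   (mirror-symmetric) or only `"alpha"` / `"beta"`.
#' @return A `synthetic_mode` for [synthetic_config()].
#' @export
mode_scissor <- function(amplitude, period = 10, baseline = amplitude,
                         waveform = "sine", tau = 1) {
  new_mode("scissor", amplitude, period, baseline, waveform, tau,
           list(list(group = "valpha", axis = c(1, 0, 0),
                     pivot = "valpha_centroid", weight = 0.5),
                list(group = "vbeta", axis = c(1, 0, 0),
                     pivot = "vbeta_centroid", weight = -0.5)))
}

#' @rdname mode_scissor
#' @export
mode_flap <- function(amplitude, period = 10, baseline = amplitude,
                      waveform = "sine", tau = 1) {
  new_mode("flap", amplitude, period, baseline, waveform, tau,
           list(list(group = "valpha", axis = c(0, 1, 0),
                     pivot = "valpha_centroid", weight = 0.5),
                list(group = "vbeta", axis = c(0, 1, 0),
                     pivot = "vbeta_centroid", weight = -0.5)))
}

#' @rdname mode_scissor
#' @export
mode_twist <- function(amplitude, period = 10, baseline = amplitude,
                       waveform = "sine", tau = 1) {
  new_mode("twist", amplitude, period, baseline, waveform, tau,
           list(list(group = "valpha", axis = c(0, 0, 1),
                     pivot = "valpha_centroid", weight = 0.5),
                list(group = "vbeta", axis = c(0, 0, 1),
                     pivot = "vbeta_centroid", weight = -0.5)))
}

#' @rdname mode_scissor
#' @export
mode_hinge_bend <- function(amplitude, period = 10, baseline = amplitude,
                            waveform = "sine", tau = 1,
                            chains = c("both", "alpha", "beta")) {
  chains <- match.arg(chains)
  parts <- list()
  if (chains %in% c("both", "alpha")) {
    parts <- c(parts, list(list(group = "valpha", axis = c(0, 1, 0),
                                pivot = "hinge_alpha", weight = 1)))
  }
  if (chains %in% c("both", "beta")) {
    parts <- c(parts, list(list(group = "vbeta", axis = c(0, 1, 0),
                                pivot = "hinge_beta", weight = -1)))
  }
  new_mode(paste0("hinge_bend_", chains), amplitude, period, baseline,
           waveform, tau, parts)
}

#' @rdname mode_scissor
#' @param group,axis,pivot For `mode_rotation()`: an arbitrary rigid
#'   rotation of one named template group about `axis` through `pivot`
#'   (a 3-vector or the name of a template layout point).
#' @export
mode_rotation <- function(group, axis, pivot, amplitude, period = 10,
                          baseline = amplitude, waveform = "sine", tau = 1) {
  new_mode(paste0("rotation_", group), amplitude, period, baseline, waveform,
           tau, list(list(group = group, axis = axis, pivot = pivot,
                          weight = 1)))
}

## ---- contact schedules ------------------------------------------------

#' Deterministic presence schedule for one contact
#'
#' `occupancy` spreads `floor(n_frames * occupancy)` present frames evenly
#' across the run (so the realised average occupancy equals the target to
#' 1/n_frames); `off_after_ns` keeps the contact present until that time
#' and absent after; `on_intervals` is an explicit list of `c(start, end)`
#' ns intervals.
#'
#' @param n_frames,dt Frame count and stride (ns).
#' @param occupancy Target occupancy in \[0, 1\].
#' @param off_after_ns Switch-off time in ns.
#' @param on_intervals List of `c(start, end)` ns intervals.
#' @return Logical vector of length `n_frames`.
#' @export
schedule_presence <- function(n_frames, dt, occupancy = NULL,
                              off_after_ns = NULL, on_intervals = NULL) {
  if (!is.null(occupancy)) {
    stopifnot(occupancy >= 0, occupancy <= 1)
    i <- seq_len(n_frames)
    return(floor(i * occupancy) > floor((i - 1) * occupancy))
  }
  t <- (seq_len(n_frames) - 1) * dt
  if (!is.null(off_after_ns)) return(t < off_after_ns - 1e-9)
  if (!is.null(on_intervals)) {
    on <- rep(FALSE, n_frames)
    for (iv in on_intervals) on <- on | (t >= iv[1] - 1e-9 & t < iv[2] - 1e-9)
    return(on)
  }
  rep(FALSE, n_frames)
}

## ---- configuration ----------------------------------------------------

#' Synthetic trajectory configuration
#'
#' @param template A [make_domain_template()].
#' @param n_frames Number of frames.
#' @param dt_save Saving interval in ns (default 0.02, i.e. 20 ps).
#' @param modes List of `synthetic_mode`s (see [mode_scissor()]); applied
#'   in the declared order each frame.
#' @param contacts Contact schedules: a list of
#'   `list(site =, occupancy = / off_after_ns = / on_intervals =)` entries
#'   referring to template site numbers. Unscheduled sites stay off.
#' @param noise_sd I.i.d. Gaussian positional noise per coordinate
#'   (Angstrom), added after mode composition.
#' @param restraint `NULL`, or a list with `k` (kcal/(mol A^2)), `T` (K),
#'   `friction` (kcal ns/(mol A^2)) and optional `bias` (3-vector force in
#'   kcal/(mol A) applied at the TCR-side anchor): the anchor atoms then
#'   perform Ornstein-Uhlenbeck motion about their restraint centres.
#' @param on_distance Named on-separations per kind (Angstrom).
#' @param seed Integer seed fixing the full output.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(template = make_domain_template(),
                             n_frames = 500, dt_save = 0.02,
                             modes = list(), contacts = list(),
                             noise_sd = 0, restraint = NULL,
                             on_distance = c(hbond = 2.0, nonpolar = 2.6),
                             seed = 1) {
  check_scalar(n_frames, "n_frames", positive = TRUE)
  check_scalar(dt_save, "dt_save", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  sites <- attr(template, "sites")
  for (cs in contacts) {
    if (is.null(cs$site) || !cs$site %in% sites$site) {
      abort("contact schedule refers to an unknown template site",
            class = "tcrmech_configuration_error")
    }
  }
  if (!is.null(restraint)) {
    check_scalar(restraint$k, "restraint$k", positive = TRUE)
    check_scalar(restraint$T %||% 300, "restraint$T", positive = TRUE)
    restraint$T <- restraint$T %||% 300
    restraint$friction <- restraint$friction %||% 0.05
    restraint$bias <- restraint$bias %||% c(0, 0, 0)
    if (dt_save > restraint$friction / restraint$k) {
      abort("dt_save exceeds friction/k: restrained-coordinate update would undersample the relaxation time",
            class = "tcrmech_value_error")
    }
  }
  structure(
    list(template = template, n_frames = as.integer(n_frames),
         dt_save = dt_save, modes = modes, contacts = contacts,
         noise_sd = noise_sd, restraint = restraint,
         on_distance = on_distance, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# theta series (degrees) for one mode, frames at times t.
mode_theta <- function(mode, t, seed) {
  if (mode$waveform == "constant" || mode$amplitude == 0) {
    return(rep(mode$baseline, length(t)))
  }
  if (mode$waveform == "sine") {
    return(mode$baseline + (mode$amplitude / 2) * sin(2 * pi * t / mode$period))
  }
  if (mode$waveform == "ou") {
    dt <- if (length(t) > 1) t[2] - t[1] else 1
    s <- ou_path(n = length(t), dt = dt, tau = mode$tau,
                 sd = mode$amplitude / 2, mean = mode$baseline, seed = seed)
    return(s)
  }
  abort(sprintf("unknown waveform '%s'", mode$waveform),
        class = "tcrmech_configuration_error")
}

# Exact-update OU path with stationary sd and mean; deterministic by seed.
# The AR(1) recursion is evaluated with stats::filter for speed.
ou_path <- function(n, dt, tau, sd, mean, seed) {
  with_seed(seed, {
    a <- exp(-dt / tau)
    innov <- c(sd * rnorm(1), sd * sqrt(1 - a^2) * rnorm(n - 1))
    x <- as.numeric(stats::filter(innov, a, method = "recursive"))
    mean + x
  })
}

resolve_pivot <- function(pivot, layout) {
  if (is.character(pivot)) {
    p <- layout[[pivot]]
    if (is.null(p)) {
      abort(sprintf("unknown layout point '%s'", pivot),
            class = "tcrmech_configuration_error")
    }
    p
  } else {
    as.numeric(pivot)
  }
}

# Apply all modes at angles theta_deg (one per mode) to template coords.
apply_modes <- function(coords, modes, theta_deg, groups, layout) {
  for (m in seq_along(modes)) {
    mode <- modes[[m]]
    th <- deg2rad(theta_deg[m])
    for (part in mode$parts) {
      idx <- groups[[part$group]]
      if (is.null(idx)) {
        abort(sprintf("unknown template group '%s'", part$group),
              class = "tcrmech_configuration_error")
      }
      R <- rotation_matrix(part$axis, part$weight * th)
      pivot <- resolve_pivot(part$pivot, layout)
      coords[idx, ] <- sweep(sweep(coords[idx, , drop = FALSE], 2, pivot) %*%
                               t(R), 2, pivot, `+`)
    }
  }
  coords
}

# 18-dim triad-pair configuration of a single frame (no alignment needed
# for finite differences: the template C module is static).
frame_triad_config <- function(coords, template) {
  tr <- function(spec) {
    core_idx <- ca_indices(template, spec$chain, spec_resnos(spec))
    cdr3_idx <- ca_indices(template, spec$chain, spec$cdr3)
    fit_triad(coords[core_idx, , drop = FALSE],
              sheet_rows(spec, spec$inner), sheet_rows(spec, spec$outer),
              cdr3_point = colMeans(coords[cdr3_idx, , drop = FALSE]))
  }
  a <- tr(triad_spec_valpha("D"))
  b <- tr(triad_spec_vbeta("E"))
  c(a$e1, a$e2, a$e3, b$e1, b$e2, b$e3)
}

# 18-dim BOC bead configuration of a single frame.
frame_boc_config <- function(coords, template, spec = boc_spec()) {
  idx <- list(
    Va = ca_indices(template, spec$chain_alpha, spec_resnos(spec$valpha)),
    Vb = ca_indices(template, spec$chain_beta, spec_resnos(spec$vbeta)),
    Ca = ca_indices(template, spec$chain_alpha, seg_resnos(spec$calpha_segments)),
    Cb = ca_indices(template, spec$chain_beta, seg_resnos(spec$cbeta_segments)),
    Ha = ca_indices(template, spec$chain_alpha, spec$hinge_alpha),
    Hb = ca_indices(template, spec$chain_beta, spec$hinge_beta)
  )
  unlist(lapply(idx, function(i) colMeans(coords[i, , drop = FALSE])),
         use.names = FALSE)
}

#' Generate a synthetic trajectory with ground truth
#'
#' Frames are built by composing the configured rigid-body mode rotations
#' (in declared order) on the template, placing each scheduled contact's
#' chain-A atom at its TCR partner's current position plus the on/off
#' separation, moving restrained anchor atoms along precomputed
#' Ornstein-Uhlenbeck paths, and finally adding i.i.d. Gaussian noise.
#' Identical config and seed give identical output.
#'
#' @param config A [synthetic_config()].
#' @return A list with `trajectory` (a [trajectory()]) and `ground_truth`:
#'   the per-frame mode angles (`theta`, degrees), per-mode injected
#'   directions in triad and BOC coordinates with their gradient norms and
#'   the projection standard deviations they predict, the scheduled
#'   presence matrix and expected occupancies, and the restraint
#'   parameters (centres, stationary sd, mean displacement).
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  template <- config$template
  groups <- attr(template, "groups")
  layout <- attr(template, "layout")
  sites <- attr(template, "sites")
  anchors <- attr(template, "anchors")
  base <- structure_coords(template)
  nf <- config$n_frames
  t <- (seq_len(nf) - 1) * config$dt_save

  theta <- matrix(0, nrow = nf, ncol = length(config$modes))
  for (m in seq_along(config$modes)) {
    theta[, m] <- mode_theta(config$modes[[m]], t, seed = config$seed + 1000 * m)
  }

  presence <- NULL
  if (length(config$contacts) > 0) {
    presence <- matrix(FALSE, nrow = nf, ncol = length(config$contacts))
    for (j in seq_along(config$contacts)) {
      cs <- config$contacts[[j]]
      presence[, j] <- schedule_presence(nf, config$dt_save,
                                         occupancy = cs$occupancy,
                                         off_after_ns = cs$off_after_ns,
                                         on_intervals = cs$on_intervals)
    }
  }

  ou <- NULL
  if (!is.null(config$restraint)) {
    rs <- config$restraint
    sd_st <- sqrt(.kB_kcal_mol_K * rs$T / rs$k)
    mean_disp <- rs$bias / rs$k
    # six independent coordinates: MHC end then TCR end
    ou <- lapply(1:6, function(d) {
      mu <- if (d > 3) mean_disp[d - 3] else 0
      ou_path(nf, config$dt_save, rs$friction / rs$k, sd_st, mu,
              seed = config$seed + 77 * d)
    })
  }

  coords <- array(0, dim = c(nrow(base), 3, nf))
  noise <- if (config$noise_sd > 0) {
    with_seed(config$seed + 5,
              array(rnorm(length(coords), sd = config$noise_sd),
                    dim = dim(coords)))
  }
  scheduled_sites <- vapply(config$contacts, function(cs) as.integer(cs$site),
                            integer(1))
  for (i in seq_len(nf)) {
    m <- apply_modes(base, config$modes, theta[i, ], groups, layout)
    # contact sites ride with their partner; separation per schedule
    sep <- rep(layout$off_distance, nrow(sites))
    if (!is.null(presence)) {
      on_d <- config$on_distance[sites$kind[scheduled_sites]]
      sep[scheduled_sites] <- ifelse(presence[i, ], on_d, layout$off_distance)
    }
    m[sites$a_idx, ] <- m[sites$tcr_idx, ] + cbind(0, 0, sep)
    if (!is.null(ou)) {
      m[anchors$mhc, ] <- m[anchors$mhc, ] +
        c(ou[[1]][i], ou[[2]][i], ou[[3]][i])
      shift <- c(ou[[4]][i], ou[[5]][i], ou[[6]][i])
      m[anchors$tcr, ] <- sweep(m[anchors$tcr, , drop = FALSE], 2, shift, `+`)
    }
    coords[, , i] <- m
  }
  if (!is.null(noise)) coords <- coords + noise
  traj <- trajectory(coords, config$dt_save, template)

  # injected mode directions by central finite difference at the baseline
  base_theta <- vapply(config$modes, function(m) m$baseline, numeric(1))
  mode_truth <- purrr::imap(config$modes, function(mode, m) {
    eps <- 0.5  # degrees
    th_hi <- base_theta; th_hi[m] <- th_hi[m] + eps
    th_lo <- base_theta; th_lo[m] <- th_lo[m] - eps
    c_hi <- apply_modes(base, config$modes, th_hi, groups, layout)
    c_lo <- apply_modes(base, config$modes, th_lo, groups, layout)
    d_triad <- (frame_triad_config(c_hi, template) -
                  frame_triad_config(c_lo, template)) / deg2rad(2 * eps)
    d_boc <- (frame_boc_config(c_hi, template) -
                frame_boc_config(c_lo, template)) / deg2rad(2 * eps)
    th_sd_rad <- deg2rad(sd(theta[, m]))
    list(kind = mode$kind, amplitude = mode$amplitude,
         baseline = mode$baseline, waveform = mode$waveform,
         theta_sd_deg = sd(theta[, m]),
         dir_triad = unit(d_triad), grad_norm_triad = vec_norm(d_triad),
         dir_boc = if (vec_norm(d_boc) > 1e-9) unit(d_boc) else d_boc,
         grad_norm_boc = vec_norm(d_boc),
         expected_sd_triad = th_sd_rad * vec_norm(d_triad),
         expected_sd_boc = th_sd_rad * vec_norm(d_boc))
  })

  contact_truth <- NULL
  if (!is.null(presence)) {
    contact_truth <- list(
      schedule = tibble(
        site = scheduled_sites,
        kind = sites$kind[scheduled_sites],
        # keyed with the chain-A side first, matching timelines built with
        # synthetic_interface()'s group order
        contact = contact_key("A", sites$a_resno[scheduled_sites],
                              sites$tcr_chain[scheduled_sites],
                              sites$tcr_resno[scheduled_sites],
                              sites$kind[scheduled_sites]),
        expected_occupancy = colMeans(presence)
      ),
      presence = presence
    )
  }

  restraint_truth <- NULL
  if (!is.null(config$restraint)) {
    rs <- config$restraint
    restraint_truth <- list(
      k = rs$k, T = rs$T, friction = rs$friction, bias = rs$bias,
      stationary_sd = sqrt(.kB_kcal_mol_K * rs$T / rs$k),
      mean_displacement = rs$bias / rs$k,
      center_mhc = base[anchors$mhc, ],
      center_tcr = colMeans(base[anchors$tcr, , drop = FALSE]),
      anchor_mhc = anchors$mhc, anchor_tcr = anchors$tcr
    )
  }

  list(
    trajectory = traj,
    ground_truth = list(
      seed = config$seed, n_frames = nf, dt_save = config$dt_save,
      theta = theta, modes = mode_truth, contacts = contact_truth,
      restraint = restraint_truth
    )
  )
}

#' Simulate a harmonically restrained coordinate (Ornstein-Uhlenbeck)
#'
#' Overdamped Langevin dynamics of a coordinate in a harmonic well
#' `E = k/2 x^2` with friction `gamma`: relaxation time `tau = gamma / k`,
#' stationary standard deviation `sqrt(kB T / k)` per coordinate, and
#' stationary mean `bias / k` under a constant bias force. The exact
#' discrete OU update is used, started from a stationary sample;
#' deterministic given the seed.
#'
#' @param k Spring constant, kcal/(mol A^2).
#' @param T Temperature, K.
#' @param friction Friction gamma, kcal ns/(mol A^2).
#' @param dt Time step in ns; must not exceed `friction / k`.
#' @param n_steps Number of steps.
#' @param bias Constant bias force, kcal/(mol A) (scalar, or length `dim`).
#' @param seed Integer seed.
#' @param dim 1 or 3 coordinates.
#' @return A tibble `step`, `time`, and `x` (plus `y`, `z` when
#'   `dim = 3`).
#' @export
simulate_restrained_coordinate <- function(k, T = 300, friction = 0.05,
                                           dt = 0.02, n_steps = 1000,
                                           bias = 0, seed = 1, dim = 1) {
  check_scalar(k, "k", positive = TRUE)
  check_scalar(T, "T", positive = TRUE)
  check_scalar(friction, "friction", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(n_steps, "n_steps", positive = TRUE)
  if (dt > friction / k) {
    abort("dt exceeds friction/k: the update would undersample the relaxation time",
          class = "tcrmech_value_error")
  }
  stopifnot(dim %in% c(1, 3))
  bias <- rep(bias, length.out = dim)
  sd_st <- sqrt(.kB_kcal_mol_K * T / k)
  cols <- lapply(seq_len(dim), function(d) {
    ou_path(n_steps, dt, friction / k, sd_st, bias[d] / k,
            seed = seed + 77 * d)
  })
  out <- tibble(step = seq_len(n_steps), time = (seq_len(n_steps) - 1) * dt)
  names(cols) <- c("x", "y", "z")[seq_len(dim)]
  bind_cols(out, as_tibble(cols))
}

#' Write a synthetic run to disk
#'
#' Writes the plain-text frame format, a PDB-style topology of the
#' template, and a JSON ground-truth summary (mode parameters, contact
#' schedule, restraint parameters) alongside.
#'
#' @param run A list from [generate_trajectory()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frames(run$trajectory, file.path(dir, "frames.txt"))
  write_template_pdb(run$trajectory$structure, file.path(dir, "template.pdb"))
  gt <- run$ground_truth
  summary <- list(
    seed = gt$seed, n_frames = gt$n_frames, dt_save = gt$dt_save,
    modes = lapply(gt$modes, function(m) {
      m[c("kind", "amplitude", "baseline", "waveform", "theta_sd_deg",
          "grad_norm_triad", "grad_norm_boc",
          "expected_sd_triad", "expected_sd_boc")]
    }),
    contacts = if (!is.null(gt$contacts)) {
      as.list(gt$contacts$schedule)
    },
    restraint = if (!is.null(gt$restraint)) {
      gt$restraint[c("k", "T", "friction", "bias", "stationary_sd",
                     "mean_displacement")]
    }
  )
  jsonlite::write_json(summary, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Minimal fixed-width ATOM-record writer for the synthetic template.
write_template_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    a$atom_id %% 100000, substr(a$name, 1, 4), substr(a$resid, 1, 3),
    a$chain, a$resno %% 10000, a$x, a$y, a$z, a$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
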