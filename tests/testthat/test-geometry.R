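# Triads, bead-on-chain, and angle/distance order parameters.

planar_core <- function() {
  # four 6-residue strands in the z-y plane, strand direction z (length 17)
  # much longer than the sheet spread (y), so the major in-plane axis is z
  do.call(rbind, lapply(1:4, function(s) {
    y <- c(0, 4, 8, 12)[s]
    x <- c(0, 1.5, 1.5, 0)[s]   # segments 1,4 inner; 2,3 outer
    cbind(x, y, 3.4 * (0:5))
  }))
}

test_that("the triad e3 arm is the major in-plane principal axis", {
  core <- planar_core()
  tr <- fit_triad(core, tcrmech:::sheet_rows(triad_spec_valpha(), c(1, 4)),
                  tcrmech:::sheet_rows(triad_spec_valpha(), c(2, 3)),
                  cdr3_point = c(0, 6, 30))
  # eigen-decomposition oracle on the constructed covariance
  centred <- sweep(core, 2, colMeans(core))
  ev <- eigen(crossprod(centred) / nrow(core), symmetric = TRUE)
  expect_equal(abs(sum(tr$e3 * ev$vectors[, 1])), 1, tolerance = 1e-8)
  expect_gt(sum(tr$e3 * c(0, 0, 1)), 0.9)  # points towards the CDR3 side
  expect_gt(sum(tr$e1 * c(1, 0, 0)), 0.9)  # inner -> outer is +x here
})

test_that("triads are orthonormal and right-handed by construction", {
  withr::with_seed(21, {
    for (i in 1:10) {
      core <- planar_core() + matrix(rnorm(72, sd = 0.3), 24, 3)
      tr <- fit_triad(core, 1:12, 13:24)
      G <- rbind(tr$e1, tr$e2, tr$e3)
      expect_equal(G %*% t(G), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(tcrmech:::cross3(tr$e3, tr$e1), tr$e2, tolerance = 1e-8)
      expect_equal(det(G), 1, tolerance = 1e-8)
    }
  })
})

test_that("triad fitting is equivariant under rigid rotation", {
  withr::with_seed(22, {
    core <- planar_core() + matrix(rnorm(72, sd = 0.2), 24, 3)
    cdr3 <- c(0.7, 6, 25)
    tr <- fit_triad(core, 1:12, 13:24, cdr3_point = cdr3)
    for (i in 1:5) {
      R <- random_rotation()
      tr2 <- fit_triad(core %*% t(R), 1:12, 13:24,
                       cdr3_point = as.vector(R %*% cdr3))
      expect_equal(tr2$e1, as.vector(R %*% tr$e1), tolerance = 1e-8)
      expect_equal(tr2$e2, as.vector(R %*% tr$e2), tolerance = 1e-8)
      expect_equal(tr2$e3, as.vector(R %*% tr$e3), tolerance = 1e-8)
      expect_equal(tr2$centroid, as.vector(R %*% tr$centroid),
                   tolerance = 1e-8)
    }
  })
})

test_that("collinear core points are a geometry error", {
  line <- cbind(0, 0, seq_len(12))
  expect_error(fit_triad(line, 1:6, 7:12), class = "tcrmech_geometry_error")
})

test_that("triad-arm angles follow rotation geometry", {
  core <- planar_core()
  tr <- fit_triad(core, 1:12, 13:24, cdr3_point = c(0, 6, 30))
  expect_equal(triad_angles(tr, tr), c(e1 = 0, e2 = 0, e3 = 0),
               tolerance = 1e-7)
  # rotating 30 degrees about the shared e1 leaves angle(e1) = 0
  rot_triad <- function(tr, R) {
    structure(list(e1 = as.vector(R %*% tr$e1), e2 = as.vector(R %*% tr$e2),
                   e3 = as.vector(R %*% tr$e3), centroid = tr$centroid),
              class = "triad")
  }
  R30 <- tcrmech:::rotation_matrix(tr$e1, 30 * pi / 180)
  expect_equal(triad_angles(tr, rot_triad(tr, R30)),
               c(e1 = 0, e2 = 30, e3 = 30), tolerance = 1e-7)
  # random rotations: each angle equals the rotation-matrix oracle
  withr::with_seed(23, {
    for (i in 1:10) {
      R <- random_rotation()
      got <- triad_angles(tr, rot_triad(tr, R))
      oracle <- vapply(list(tr$e1, tr$e2, tr$e3), function(e) {
        acos(pmin(1, pmax(-1, crossprod(e, R %*% e)))) * 180 / pi
      }, numeric(1))
      expect_equal(unname(got), oracle, tolerance = 1e-7)
    }
  })
})

test_that("CDR3 distance is the distance between base-pair midpoints", {
  # four CA atoms placed so both midpoints coincide -> 0
  mk <- function(a1, a2, b1, b2) {
    atoms <- tibble::tibble(
      chain = rep(c("D", "E"), each = 2),
      resno = c(92, 97, 94, 103), resid = "GLY", name = "CA", element = "C",
      x = c(a1[1], a2[1], b1[1], b2[1]),
      y = c(a1[2], a2[2], b1[2], b2[2]),
      z = c(a1[3], a2[3], b1[3], b2[3])
    )
    structure_model(atoms, renumber = FALSE)
  }
  st0 <- mk(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_equal(cdr3_distance(st0), 0)
  # midpoints at origin and (3,4,0) -> 5
  st1 <- mk(c(1, 0, 0), c(-1, 0, 0), c(4, 4, 0), c(2, 4, 0))
  expect_equal(cdr3_distance(st1), 5)
  # missing residue -> selection error naming it
  st2 <- mk(c(1, 0, 0), c(-1, 0, 0), c(4, 4, 0), c(2, 4, 0))
  expect_error(cdr3_distance(st2, beta = list(chain = "E", resno = c(94, 200))),
               regexp = "E200", class = "tcrmech_selection_error")
})

test_that("CDR3 distance is invariant under rigid motion of each frame", {
  cfg <- synthetic_config(template, n_frames = 5, seed = 30,
                          modes = list(mode_scissor(8, period = 0.06)))
  traj <- generate_trajectory(cfg)$trajectory
  base <- cdr3_distance(traj)
  withr::with_seed(31, {
    moved <- traj
    for (i in 1:5) {
      R <- random_rotation()
      moved$coords[, , i] <- traj$coords[, , i] %*% t(R) +
        matrix(rep(rnorm(3, sd = 10), each = dim(traj$coords)[1]), ncol = 3)
    }
    expect_equal(cdr3_distance(moved)$value, base$value, tolerance = 1e-8)
  })
})

test_that("the BOC is six beads, invariant to rigid body motion of frames", {
  cfg <- synthetic_config(template, n_frames = 4, seed = 32)
  traj <- generate_trajectory(cfg)$trajectory
  # translate every frame differently: alignment must undo it
  for (i in 1:4) {
    traj$coords[, , i] <- traj$coords[, , i] +
      matrix(rep(c(5 * i, -3 * i, 2 * i), each = dim(traj$coords)[1]), ncol = 3)
  }
  boc <- build_boc(traj)
  expect_equal(dim(boc$beads), c(6, 3, 4))
  for (i in 2:4) {
    expect_equal(boc$beads[, , i], boc$beads[, , 1], tolerance = 1e-8)
  }
})

test_that("a V-module rotation about the beta hinge moves the Vb bead on its arc", {
  amp <- 14
  cfg <- synthetic_config(template, n_frames = 40, seed = 33,
    modes = list(mode_rotation("vbeta", axis = c(0, 1, 0),
                               pivot = "hinge_beta", amplitude = amp,
                               period = 0.4, baseline = 0)))
  run <- generate_trajectory(cfg)
  boc <- build_boc(run$trajectory)
  hinge <- attr(template, "layout")$hinge_beta
  vb0 <- tcrmech:::frame_boc_config(structure_coords(template), template)[4:6]
  r <- sqrt(sum((vb0 - hinge)^2))
  theta <- run$ground_truth$theta[, 1]
  # chord length for a rotation by theta about the hinge
  expected <- 2 * r * abs(sin(tcrmech:::deg2rad(theta) / 2))
  got <- sqrt(colSums((boc$beads["Vb", , ] - vb0)^2))
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("hinge angles recover closed-form toy and injected bend amplitude", {
  mk_boc <- function(va, ha, ca) {
    beads <- array(0, dim = c(6, 3, 1),
                   dimnames = list(c("Va", "Vb", "Ca", "Cb", "Ha", "Hb"),
                                   c("x", "y", "z"), NULL))
    beads["Va", , 1] <- va; beads["Ha", , 1] <- ha; beads["Ca", , 1] <- ca
    beads["Vb", , 1] <- va + c(10, 0, 0)
    beads["Hb", , 1] <- ha + c(10, 0, 0)
    beads["Cb", , 1] <- ca + c(10, 0, 0)
    structure(list(beads = beads, dt_save = 0.02, spec = boc_spec()),
              class = "boc_model")
  }
  expect_equal(hinge_angles(mk_boc(c(0, 0, 10), c(0, 0, 0), c(0, 0, -10)))$angle_alpha,
               180)
  expect_equal(hinge_angles(mk_boc(c(10, 0, 0), c(0, 0, 0), c(0, 0, -10)))$angle_alpha,
               90)
  expect_error(hinge_angles(mk_boc(c(0, 0, 0), c(0, 0, 0), c(0, 0, -10))),
               class = "tcrmech_geometry_error")
  # injected hinge bend of peak-to-peak amplitude A -> angle range A
  # period chosen so the 20-ps sampling grid hits the sine extrema exactly
  amp <- 9
  cfg <- synthetic_config(template, n_frames = 60, seed = 34,
                          modes = list(mode_hinge_bend(amp, period = 0.4)))
  run <- generate_trajectory(cfg)
  ha <- hinge_angles(build_boc(run$trajectory))
  expect_equal(diff(range(ha$angle_alpha)), amp, tolerance = 1e-3)
  expect_equal(diff(range(ha$angle_beta)), amp, tolerance = 1e-3)
  # and the angle tracks 180 - theta frame by frame
  expect_equal(ha$angle_alpha, 180 - run$ground_truth$theta[, 1],
               tolerance = 1e-3)
})

test_that("peptide angle reads the acute angle between fit line and V axis", {
  cfg <- synthetic_config(template, n_frames = 3, seed = 35)
  traj <- generate_trajectory(cfg)$trajectory
  # template peptide lies along x, as does the Valpha -> Vbeta axis
  pa <- peptide_angle(traj)
  expect_equal(pa$value, rep(0, 3), tolerance = 1e-6)
  # rotate the peptide to a known tilt about y through its centre
  tilt <- function(traj, deg) {
    out <- traj
    idx <- attr(template, "groups")$peptide
    for (i in seq_len(n_frames(traj))) {
      m <- traj$coords[idx, , i]
      ctr <- colMeans(m)
      R <- tcrmech:::rotation_matrix(c(0, 1, 0), deg * pi / 180)
      out$coords[idx, , i] <- sweep(sweep(m, 2, ctr) %*% t(R), 2, ctr, `+`)
    }
    out
  }
  expect_equal(peptide_angle(tilt(traj, 58))$value, rep(58, 3),
               tolerance = 1e-6)
  expect_equal(peptide_angle(tilt(traj, 90))$value, rep(90, 3),
               tolerance = 1e-6)
  # reported angle is acute regardless of direction
  expect_equal(peptide_angle(tilt(traj, 122))$value, rep(58, 3),
               tolerance = 1e-6)
})

test_that("running averages and interval statistics work on scalar series", {
  s <- tibble::tibble(time = (0:99) * 0.02, value = rep(c(0, 1), 50))
  ra <- running_average(s, width_ns = 0.4)  # 20 frames
  expect_equal(ra$run_avg[seq(20, 100, 10)], rep(0.5, 9))
  st <- series_stats(s, c(0, 1))
  expect_equal(st$n, 50)
  expect_equal(st$mean, 0.5)
  expect_error(series_stats(s, c(10, 11)), class = "tcrmech_value_error")
})

test_that("RMSF is zero for static frames and for rigidly moving aligned sets", {
  cfg <- synthetic_config(template, n_frames = 10, seed = 36)
  traj <- generate_trajectory(cfg)$trajectory
  sel <- attr(template, "groups")$peptide
  out <- rmsf(traj, sel)
  expect_equal(out$rmsf, rep(0, length(sel)), tolerance = 1e-9)
  # rigid rotation+translation of everything: alignment removes it
  withr::with_seed(37, {
    for (i in 1:10) {
      R <- random_rotation()
      traj$coords[, , i] <- traj$coords[, , i] %*% t(R) +
        matrix(rep(rnorm(3, sd = 4), each = dim(traj$coords)[1]), ncol = 3)
    }
  })
  out2 <- rmsf(traj, sel, alignment_selection = sel)
  expect_lt(max(out2$rmsf), 1e-7)
  expect_error(rmsf(traj, integer(0)), class = "tcrmech_value_error")
})

test_that("RMSF of isotropic Gaussian jitter converges to sigma * sqrt(3)", {
  sigma <- 0.25
  nf <- 400
  cfg <- synthetic_config(template, n_frames = nf, seed = 38,
                          noise_sd = sigma)
  traj <- generate_trajectory(cfg)$trajectory
  # alignment on the large static TCR core barely moves the frames
  core <- attr(template, "groups")$calpha
  sel <- attr(template, "groups")$peptide
  out <- rmsf(traj, sel, alignment_selection = core)
  expected <- sigma * sqrt(3)
  # 3 sigma / sqrt(n) tolerance per atom, pooled over the peptide
  expect_equal(mean(out$rmsf), expected, tolerance = 3 / sqrt(nf))
})

test_that("transverse RMSF isolates motion orthogonal to the load axis", {
  st <- structure_model(tibble::tibble(
    chain = "P", resno = 1, resid = "GLY", name = "CA", element = "C",
    x = 0, y = 0, z = 0
  ))
  nf <- 64
  # motion purely along the axis -> 0
  along <- array(0, dim = c(1, 3, nf))
  along[1, 3, ] <- sin(seq_len(nf))
  expect_equal(as.numeric(transverse_rmsf(trajectory(along, 0.02, st), 1,
                                          c(0, 0, 1))), 0)
  # circular motion of radius r in the transverse plane -> r
  r <- 2.5
  circ <- array(0, dim = c(1, 3, nf))
  phi <- 2 * pi * seq_len(nf) / nf
  circ[1, 1, ] <- r * cos(phi)
  circ[1, 2, ] <- r * sin(phi)
  expect_equal(as.numeric(transverse_rmsf(trajectory(circ, 0.02, st), 1,
                                          c(0, 0, 1))), r, tolerance = 1e-8)
  # static -> 0; undefined axis -> error
  static <- array(1, dim = c(1, 3, nf))
  expect_equal(as.numeric(transverse_rmsf(trajectory(static, 0.02, st), 1,
                                          c(0, 0, 1))), 0)
  expect_error(transverse_rmsf(trajectory(static, 0.02, st), 1, c(0, 0, 0)),
               class = "tcrmech_configuration_error")
})
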