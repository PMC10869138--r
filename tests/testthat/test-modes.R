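# PCA on triad arms and BOC beads: recovery, similarity, asymmetry.

test_that("a motionless trajectory has zero PCA amplitudes", {
  cfg <- synthetic_config(template, n_frames = 30, seed = 40)
  run <- generate_trajectory(cfg)
  tr <- aligned_v_triads(run$trajectory)
  pca <- pca_triads(tr$alpha, tr$beta, short_windows())
  expect_equal(unname(pca$amplitudes), rep(0, 18), tolerance = 1e-10)
  boc <- build_boc(run$trajectory)
  pcb <- pca_boc(boc, short_windows())
  expect_equal(unname(pcb$amplitudes), rep(0, 18), tolerance = 1e-10)
})

test_that("an injected sinusoidal mode is recovered as PC1 with its amplitude", {
  cfg <- synthetic_config(template, n_frames = 200, seed = 41,
                          modes = list(mode_scissor(10, period = 0.4)),
                          noise_sd = 0.05)
  run <- generate_trajectory(cfg)
  gt <- run$ground_truth$modes[[1]]
  tr <- aligned_v_triads(run$trajectory)
  pca <- pca_triads(tr$alpha, tr$beta, short_windows())
  expect_gt(mode_similarity(pca$modes[, 1], gt$dir_triad), 0.95)
  expect_equal(unname(pca$amplitudes[1]), gt$expected_sd_triad,
               tolerance = 0.1)
})

test_that("two orthogonal injected modes are recovered in amplitude order", {
  cfg <- synthetic_config(template, n_frames = 240, seed = 42,
                          modes = list(mode_scissor(12, period = 0.4),
                                       mode_twist(4, period = 0.24)),
                          noise_sd = 0.02)
  run <- generate_trajectory(cfg)
  gts <- run$ground_truth$modes
  tr <- aligned_v_triads(run$trajectory)
  pca <- pca_triads(tr$alpha, tr$beta, short_windows())
  expect_gt(mode_similarity(pca$modes[, 1], gts[[1]]$dir_triad), 0.95)
  expect_gt(mode_similarity(pca$modes[, 2], gts[[2]]$dir_triad), 0.95)
  expect_true(all(diff(pca$amplitudes) <= 1e-12))
})

test_that("mode recovery holds at SNR >= 5 across 20 seeds", {
  dots <- vapply(1:20, function(s) {
    cfg <- synthetic_config(template, n_frames = 120, seed = 100 + s,
                            modes = list(mode_scissor(10, period = 0.4)),
                            noise_sd = 0.05)
    run <- generate_trajectory(cfg)
    tr <- aligned_v_triads(run$trajectory)
    pca <- pca_triads(tr$alpha, tr$beta, short_windows())
    mode_similarity(pca$modes[, 1], run$ground_truth$modes[[1]]$dir_triad)
  }, numeric(1))
  expect_true(all(dots > 0.95))
})

test_that("BOC PCA sees V-bead motion with near-stationary hinges under a bend", {
  cfg <- synthetic_config(template, n_frames = 120, seed = 43,
                          modes = list(mode_hinge_bend(10, period = 0.4)))
  run <- generate_trajectory(cfg)
  boc <- build_boc(run$trajectory)
  pca <- pca_boc(boc, short_windows())
  gt <- run$ground_truth$modes[[1]]
  expect_gt(mode_similarity(pca$modes[, 1], gt$dir_boc), 0.95)
  v <- pca$modes[, 1]
  bead_disp <- sqrt(colSums(matrix(v^2, nrow = 3)))
  names(bead_disp) <- c("Va", "Vb", "Ca", "Cb", "Ha", "Hb")
  expect_gt(min(bead_disp[c("Va", "Vb")]), 10 * max(bead_disp[c("Ha", "Hb", "Ca", "Cb")]))
  # amplitudes are invariant to permuting the frame order
  perm <- sample(seq_len(dim(boc$beads)[3]))
  boc2 <- boc
  boc2$beads <- boc$beads[, , perm]
  pca2 <- pca_boc(boc2, short_windows())
  expect_equal(pca2$amplitudes, pca$amplitudes, tolerance = 1e-10)
})

test_that("total variance is conserved across modes (trace identity)", {
  cfg <- synthetic_config(template, n_frames = 150, seed = 44,
                          modes = list(mode_scissor(8, period = 0.4),
                                       mode_flap(5, period = 0.3)),
                          noise_sd = 0.08)
  run <- generate_trajectory(cfg)
  tr <- aligned_v_triads(run$trajectory)
  pca <- pca_triads(tr$alpha, tr$beta, short_windows())
  X <- cbind(tr$alpha$e1, tr$alpha$e2, tr$alpha$e3,
             tr$beta$e1, tr$beta$e2, tr$beta$e3)
  total_var <- sum(apply(X, 2, stats::var))
  expect_equal(sum(pca$eigenvalues), total_var, tolerance = 1e-10)
})

test_that("mode similarity is symmetric, sign-invariant, and checks dims", {
  v <- tcrmech:::unit(rnorm(18))
  w <- tcrmech:::unit(rnorm(18))
  expect_equal(mode_similarity(v, v), 1)
  expect_equal(mode_similarity(v, -v), 1)
  expect_equal(mode_similarity(v, w), mode_similarity(w, v))
  u <- v - sum(v * w) * w
  expect_equal(mode_similarity(w, tcrmech:::unit(u - sum(u * w) * w)), 0,
               tolerance = 1e-10)
  expect_error(mode_similarity(v, rnorm(6)), class = "tcrmech_value_error")
})

test_that("projections behave like coordinates in the mode basis", {
  cfg <- synthetic_config(template, n_frames = 100, seed = 45,
                          modes = list(mode_scissor(10, period = 0.4)),
                          noise_sd = 0.03)
  run <- generate_trajectory(cfg)
  tr <- aligned_v_triads(run$trajectory)
  pca <- pca_triads(tr$alpha, tr$beta, short_windows())
  # the mean configuration projects to 0
  expect_equal(project_onto_mode(pca, pca$mean), 0, tolerance = 1e-10)
  # mean + alpha * PC1 projects to alpha
  alpha <- 0.37
  expect_equal(project_onto_mode(pca, pca$mean + alpha * pca$modes[, 1]),
               alpha, tolerance = 1e-10)
  # the reported amplitude is the sd of the analysed projections
  expect_equal(unname(pca$amplitudes[1]),
               sd(pca$projections[pca$analysis_rows, 1]))
  expect_error(project_onto_mode(pca, rnorm(5)),
               class = "tcrmech_value_error")
})

test_that("amplitude asymmetry vanishes for mirror-symmetric motion", {
  cfg <- synthetic_config(template, n_frames = 120, seed = 46,
                          modes = list(mode_hinge_bend(10, period = 0.4,
                                                       chains = "both")))
  run <- generate_trajectory(cfg)
  pca <- pca_boc(build_boc(run$trajectory), short_windows())
  asym <- amplitude_asymmetry(pca, n_modes = 3)
  expect_equal(asym$asymmetry[1], 0, tolerance = 1e-8)
})

test_that("motion injected on one chain shows up as signed asymmetry", {
  cfg <- synthetic_config(template, n_frames = 120, seed = 47,
                          modes = list(mode_hinge_bend(10, period = 0.4,
                                                       chains = "alpha")))
  run <- generate_trajectory(cfg)
  pca <- pca_boc(build_boc(run$trajectory), short_windows())
  asym <- amplitude_asymmetry(pca)
  expect_gt(asym$asymmetry[1], 0)
  # swapping the group labels negates the report
  swapped <- amplitude_asymmetry(pca, group_map = list(
    alpha = pca$group_map$beta, beta = pca$group_map$alpha))
  expect_equal(swapped$asymmetry, -asym$asymmetry)
  # unmatched groups are a configuration error
  expect_error(amplitude_asymmetry(pca, group_map = list(alpha = 1:6,
                                                         beta = 1:6)),
               class = "tcrmech_configuration_error")
  expect_error(amplitude_asymmetry(pca, group_map = list(alpha = 1:4,
                                                         beta = 5:8)),
               class = "tcrmech_configuration_error")
})

test_that("angle-conditional statistics bin correctly and flag sparse tails", {
  # constant scalar: every bin mean is that constant with zero sd
  ang <- runif(500, 0, 90)
  out <- angle_conditional_stats(ang, rep(7, 500), n_bins = 10)
  expect_true(all(abs(out$mean - 7) < 1e-12))
  expect_true(all(out$sd == 0))
  # noiseless linear relation: each bin mean is the line evaluated at the
  # mean angle of the bin's samples
  sc <- 2 * ang + 1
  out2 <- angle_conditional_stats(ang, sc, n_bins = 10)
  edges <- seq(min(ang), max(ang), length.out = 11)
  bin <- pmin(findInterval(ang, edges, rightmost.closed = TRUE), 10)
  expected <- as.numeric(tapply(ang, bin, function(a) 2 * mean(a) + 1))
  expect_equal(out2$mean, expected, tolerance = 1e-10)
  expect_error(angle_conditional_stats(ang, sc, n_bins = 1),
               class = "tcrmech_value_error")
  expect_error(angle_conditional_stats(ang[1:10], sc),
               class = "tcrmech_value_error")
  # sparse flag
  ang3 <- c(rep(10, 100), 89)
  out3 <- angle_conditional_stats(ang3, rep(1, 101), n_bins = 4)
  expect_true(out3$sparse[out3$n == 1])
})

test_that("CDR3 distance grows monotonically with the scissor angle", {
  cfg <- synthetic_config(template, n_frames = 200, seed = 48,
                          modes = list(mode_scissor(16, period = 0.4)))
  run <- generate_trajectory(cfg)
  tr <- aligned_v_triads(run$trajectory)
  ang <- triad_angles(tr$alpha, tr$beta)
  cdr3 <- cdr3_distance(run$trajectory)
  out <- angle_conditional_stats(ang$angle_e3, cdr3$value, n_bins = 8)
  dense <- out[!out$sparse, ]
  expect_true(all(diff(dense$mean) > 0))
})
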