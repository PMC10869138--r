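# Unit tests for contact detection and occupancy kinetics.

two_sided_atoms <- function(d, q1 = 0.5, q2 = 0.5, donor1 = TRUE,
                            acceptor2 = TRUE) {
  tibble::tibble(
    chain = c("A", "B"), resno = c(1, 1), resid = "GLY",
    name = c("N", "O"), element = c("N", "O"),
    x = c(0, d), y = 0, z = 0, charge = c(q1, q2),
    donor = c(donor1, FALSE), acceptor = c(FALSE, acceptor2)
  )
}

test_that("hydrogen bonds follow the donor-acceptor distance criterion", {
  st <- toy_contact_structure(two_sided_atoms(2.3))
  hits <- detect_contacts(NULL, st, "A", "B", kinds = "hbond")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$kind, "hbond")
  st_far <- toy_contact_structure(two_sided_atoms(2.5))
  expect_equal(nrow(detect_contacts(NULL, st_far, "A", "B", kinds = "hbond")), 0)
})

test_that("nonpolar contacts require proximity and two small charges", {
  mk <- function(d, q1, q2) {
    atoms <- two_sided_atoms(d, q1, q2, donor1 = FALSE, acceptor2 = FALSE)
    atoms$element <- "C"
    toy_contact_structure(atoms)
  }
  expect_equal(nrow(detect_contacts(NULL, mk(2.9, 0.1, -0.05), "A", "B",
                                    kinds = "nonpolar")), 1)
  expect_equal(nrow(detect_contacts(NULL, mk(2.9, 0.4, -0.05), "A", "B",
                                    kinds = "nonpolar")), 0)
  expect_equal(nrow(detect_contacts(NULL, mk(3.2, 0.1, -0.05), "A", "B",
                                    kinds = "nonpolar")), 0)
  # missing charges are a configuration error
  atoms <- two_sided_atoms(2.9, NA, 0.1, donor1 = FALSE, acceptor2 = FALSE)
  st <- toy_contact_structure(atoms)
  expect_error(detect_contacts(NULL, st, "A", "B", kinds = "nonpolar"),
               class = "tcrmech_configuration_error")
})

test_that("detection matches a brute-force all-pairs scan on random frames", {
  # independent O(N^2) oracle: scan every cross pair against the criteria
  brute_force <- function(st, coords, crit = contact_criteria()) {
    a <- st$atoms
    ia <- which(a$chain == "A")
    ib <- which(a$chain == "B")
    found <- character(0)
    for (i in ia) for (j in ib) {
      if (a$is_hydrogen[i] || a$is_hydrogen[j]) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      hb <- ((a$is_donor[i] && a$is_acceptor[j]) ||
               (a$is_acceptor[i] && a$is_donor[j])) && d <= crit$hbond_cutoff
      np <- !is.na(a$charge[i]) && !is.na(a$charge[j]) &&
        abs(a$charge[i]) < crit$charge_cutoff &&
        abs(a$charge[j]) < crit$charge_cutoff && d <= crit$nonpolar_cutoff
      if (hb) found <- c(found, sprintf("%s%d-%s%d/hb", a$chain[i], a$resno[i],
                                        a$chain[j], a$resno[j]))
      if (np) found <- c(found, sprintf("%s%d-%s%d/np", a$chain[i], a$resno[i],
                                        a$chain[j], a$resno[j]))
    }
    sort(unique(found))
  }
  withr::with_seed(101, {
    for (rep in 1:5) {
      n_a <- 80
      n_b <- 120
      atoms <- tibble::tibble(
        chain = rep(c("A", "B"), c(n_a, n_b)),
        resno = c(seq_len(n_a), seq_len(n_b)),
        resid = "GLY",
        name = sample(c("N", "O", "C"), n_a + n_b, replace = TRUE),
        element = NA_character_,
        x = runif(n_a + n_b, 0, 14), y = runif(n_a + n_b, 0, 14),
        z = runif(n_a + n_b, 0, 14),
        charge = round(runif(n_a + n_b, -0.6, 0.6), 2),
        donor = sample(c(TRUE, FALSE), n_a + n_b, replace = TRUE),
        acceptor = sample(c(TRUE, FALSE), n_a + n_b, replace = TRUE)
      )
      atoms$element <- substr(atoms$name, 1, 1)
      st <- toy_contact_structure(atoms)
      got <- detect_contacts(NULL, st, "A", "B")
      expect_identical(sort(got$contact), brute_force(st, structure_coords(st)))
    }
  })
})

test_that("occupancies follow their definitions exactly", {
  cfg <- synthetic_config(template, n_frames = 100, seed = 5,
                          contacts = list(list(site = 1, occupancy = 0.6),
                                          list(site = 3, occupancy = 1)))
  run <- generate_trajectory(cfg)
  tl <- build_timelines(run$trajectory, iface$group_a, iface$group_b,
                        windows = short_windows())
  occ <- avg_occupancy(tl)
  expect_equal(sort(occ$avg_occupancy), c(0.6, 1))
  # always-present contact: instantaneous occupancy 1 everywhere
  inst <- inst_occupancy(tl)
  always <- which(occ$avg_occupancy == 1)
  expect_true(all(inst[, always] == 1))
  # 60-of-100 frames: average occupancy exactly 0.6
  expect_equal(occ$avg_occupancy[occ$avg_occupancy < 1], 0.6)
})

test_that("rolling occupancy of an alternating contact is 0.5 in full windows", {
  p <- rep(c(TRUE, FALSE), 50)
  inst <- tcrmech:::rolling_mean_trailing(p, 40)
  expect_equal(inst[40:100], rep(0.5, 61))
  # truncated start: mean over the first i frames
  expect_equal(inst[1], 1)
  expect_equal(inst[2], 0.5)
  expect_equal(inst[5], mean(p[1:5]))
})

test_that("average occupancy equals the mean of whole-interval rolling occupancy", {
  withr::with_seed(7, {
    p <- runif(200) < 0.4
    whole <- tcrmech:::rolling_mean_trailing(p, 200)
    expect_equal(whole[200], mean(p))
  })
})

test_that("high-occupancy counting applies both thresholds after the cut", {
  mk_tl <- function(presence) {
    structure(list(
      keys = tibble::tibble(contact = paste0("c", seq_len(ncol(presence))),
                            kind = "hbond"),
      presence = presence, dt_save = 0.02,
      windows = analysis_windows(equilibration_cut = 0)
    ), class = "contact_timelines")
  }
  # avg 0.9 + max inst 1 -> counted; avg 0.56 with scattered presence whose
  # rolling occupancy never reaches 0.8 -> not counted
  p1 <- c(rep(TRUE, 90), rep(FALSE, 10))
  p2 <- c(rep(c(FALSE, TRUE), 20), rep(c(TRUE, TRUE, FALSE, TRUE, FALSE), 12))
  tl <- mk_tl(cbind(p1, p2))
  expect_identical(as.integer(count_high_occupancy(tl)), 1L)
  detail <- attr(count_high_occupancy(tl), "detail")
  expect_true(detail$counted[1])
  expect_false(detail$counted[2])
  expect_lt(detail$max_inst_occupancy[2], 0.8)
  # random schedules against a brute-force filter
  withr::with_seed(33, {
    presence <- matrix(runif(400 * 20) < runif(20)[col(matrix(0, 400, 20))],
                       nrow = 400)
    tl2 <- mk_tl(presence)
    avg <- colMeans(presence)
    maxinst <- apply(presence, 2, function(p) {
      max(tcrmech:::rolling_mean_trailing(p, 40))
    })
    expect_identical(as.integer(count_high_occupancy(tl2)),
                     sum(avg > 0.5 & maxinst >= 0.8))
  })
})

test_that("heat-map rows respect both thresholds and bin a two-phase contact", {
  cfg <- synthetic_config(template, n_frames = 200, seed = 6,
    contacts = list(list(site = 1, on_intervals = list(c(0, 2))),  # on for first half
                    list(site = 2, occupancy = 0.35)))
  run <- generate_trajectory(cfg)
  tl <- build_timelines(run$trajectory, iface$group_a, iface$group_b,
                        windows = short_windows())
  hm <- heatmap_table(tl, bin_ns = 0.4)
  # two-phase contact passes (avg 0.5, max inst 1): first-half bins 1, last 0
  two_phase <- hm[hm$contact == "A1-D40/hb", ]
  expect_equal(nrow(two_phase), 10)
  expect_equal(two_phase$occupancy[1:5], rep(1, 5))
  expect_equal(two_phase$occupancy[6:10], rep(0, 5))
  # 0.35-occupancy evenly spread contact: avg > 0.3 but max inst << 0.8
  expect_false("A2-E40/hb" %in% hm$contact)
  # all below thresholds: empty table, not an error
  cfg0 <- synthetic_config(template, n_frames = 100, seed = 6,
                           contacts = list(list(site = 1, occupancy = 0.1)))
  tl0 <- build_timelines(generate_trajectory(cfg0)$trajectory,
                         iface$group_a, iface$group_b,
                         windows = short_windows())
  expect_equal(nrow(heatmap_table(tl0)), 0)
})

test_that("Hamming distance counts programmed losses of baseline contacts", {
  # 5 baseline contacts; 2 switch off permanently at 2 ns of a 4-ns run
  contacts <- c(
    lapply(1:3, function(s) list(site = s, occupancy = 1)),
    lapply(4:5, function(s) list(site = s, off_after_ns = 2))
  )
  cfg <- synthetic_config(template, n_frames = 200, seed = 8,
                          contacts = contacts)
  run <- generate_trajectory(cfg)
  tl <- build_timelines(run$trajectory, iface$group_a, iface$group_b,
                        windows = short_windows())
  h <- hamming_distance(tl, baseline_interval = c(0, 1))
  expect_equal(nrow(attr(h, "baseline")), 5)
  expect_true(all(h$H[h$time < 2] == 0))
  expect_equal(tail(h$H, 1), 2L)
  # with the permanent rule H is non-decreasing
  hp <- hamming_distance(tl, baseline_interval = c(0, 1),
                         loss_rule = "permanent")
  expect_true(all(diff(hp$H) >= 0))
  expect_equal(tail(hp$H, 1), 2L)
  expect_true(all(h$H <= nrow(attr(h, "baseline"))))
})

test_that("persisting contacts give H identically zero, empty baseline warns", {
  cfg <- synthetic_config(template, n_frames = 100, seed = 9,
                          contacts = list(list(site = 1, occupancy = 1)))
  tl <- build_timelines(generate_trajectory(cfg)$trajectory,
                        iface$group_a, iface$group_b,
                        windows = short_windows())
  h <- hamming_distance(tl, baseline_interval = c(0, 1))
  expect_true(all(h$H == 0))
  # no contact above 80% in the baseline window
  cfg2 <- synthetic_config(template, n_frames = 100, seed = 9,
                           contacts = list(list(site = 1, occupancy = 0.5)))
  tl2 <- build_timelines(generate_trajectory(cfg2)$trajectory,
                         iface$group_a, iface$group_b,
                         windows = short_windows())
  expect_warning(h2 <- hamming_distance(tl2, baseline_interval = c(0, 1)),
                 "identically 0")
  expect_true(all(h2$H == 0))
})

test_that("windowed total occupancy sums selected per-window averages", {
  # 3 permanent contacts plus one decaying one
  contacts <- c(lapply(1:3, function(s) list(site = s, occupancy = 1)),
                list(list(site = 4, off_after_ns = 2.5)))
  cfg <- synthetic_config(template, n_frames = 200, seed = 10,
                          contacts = contacts)
  run <- generate_trajectory(cfg)
  w <- analysis_windows(equilibration_cut = 0, window = 1, step = 0.5,
                        window_start = 0.5, rolling_frames = 40)
  tl <- build_timelines(run$trajectory, iface$group_a, iface$group_b,
                        windows = w)
  out <- windowed_total_occupancy(tl, windows = w)
  expect_equal(out$start, c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0))
  # brute-force per-window means from the programmed schedule
  gt <- run$ground_truth$contacts$presence
  t <- (seq_len(nrow(gt)) - 1) * 0.02
  sel <- which(colMeans(gt) > 0.5 &
                 apply(gt, 2, function(p) max(tcrmech:::rolling_mean_trailing(p, 40))) > 0.8)
  expected <- vapply(seq_len(nrow(out)), function(i) {
    idx <- t >= out$start[i] - 1e-9 & t < out$end[i] - 1e-9
    sum(colMeans(gt[idx, sel, drop = FALSE]))
  }, numeric(1))
  expect_equal(out$total_occupancy, expected)
  # decaying contact drops out window by window; the three persistent
  # contacts contribute exactly 1 each once it is fully off
  expect_equal(out$total_occupancy[out$start >= 2.5], rep(3, 2))
  expect_equal(out$total_occupancy[out$start <= 1.5], rep(4, 3))
  # trajectory shorter than window_start + window errors
  expect_error(
    windowed_total_occupancy(tl, windows = analysis_windows(
      equilibration_cut = 0, window = 10, step = 5, window_start = 0)),
    class = "tcrmech_value_error")
})

test_that("timelines tidy/glance export the long table and summary", {
  cfg <- synthetic_config(template, n_frames = 50, seed = 11,
                          contacts = list(list(site = 1, occupancy = 0.5)))
  tl <- build_timelines(generate_trajectory(cfg)$trajectory,
                        iface$group_a, iface$group_b,
                        windows = short_windows())
  td <- tidy(tl)
  expect_equal(nrow(td), 50 * ncol(tl$presence))
  expect_true(all(td$inst_occupancy >= 0 & td$inst_occupancy <= 1))
  expect_equal(glance(tl)$n_frames, 50)
})
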