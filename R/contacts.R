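#' Contact detection criteria
#'
#' Hydrogen bonds (salt bridges included) are scored on the donor-acceptor
#' distance; nonpolar contacts on heavy-atom pairs whose partial charges
#' are both below `charge_cutoff` in magnitude.
#'
#' @param hbond_cutoff Donor-acceptor distance cutoff in Angstrom
#'   (default 2.4).
#' @param nonpolar_cutoff Heavy-atom distance cutoff in Angstrom
#'   (default 3.0).
#' @param charge_cutoff Partial-charge magnitude bound in e (default 0.3);
#'   both atoms of a nonpolar pair must satisfy `|q| < charge_cutoff`.
#' @param hbond_mode `"heavy"` scores the donor heavy atom to acceptor
#'   distance literally at `hbond_cutoff`; `"hydrogen"` scores annotated
#'   polar hydrogens to acceptors instead (for structures with hydrogens).
#' @return A `contact_criteria` object.
#' @export
contact_criteria <- function(hbond_cutoff = 2.4, nonpolar_cutoff = 3.0,
                             charge_cutoff = 0.3,
                             hbond_mode = c("heavy", "hydrogen")) {
  check_scalar(hbond_cutoff, "hbond_cutoff", positive = TRUE)
  check_scalar(nonpolar_cutoff, "nonpolar_cutoff", positive = TRUE)
  check_scalar(charge_cutoff, "charge_cutoff", positive = TRUE)
  structure(
    list(hbond_cutoff = hbond_cutoff, nonpolar_cutoff = nonpolar_cutoff,
         charge_cutoff = charge_cutoff, hbond_mode = match.arg(hbond_mode)),
    class = "contact_criteria"
  )
}

#' Occupancy thresholds
#'
#' The thresholds used to select contacts for the different summaries:
#' contact counting (`count_*`), occupancy heat maps (`heatmap_*`), the
#' Hamming-distance baseline (`hamming_baseline_avg`) and buried-surface
#' residue selection (`bsa_inst_max`).
#'
#' @param count_avg Counting: average occupancy must exceed this (0.50).
#' @param count_inst_max Counting: maximum instantaneous occupancy must
#'   reach at least this (0.80).
#' @param heatmap_avg Heat map: overall average occupancy must exceed this
#'   (0.30).
#' @param heatmap_inst_max Heat map: maximum instantaneous occupancy over
#'   the whole run must exceed this (0.80).
#' @param hamming_baseline_avg Hamming baseline: average occupancy in the
#'   baseline interval must exceed this (0.80).
#' @param bsa_inst_max BSA residue selection: maximum instantaneous
#'   occupancy with the partner must exceed this (0.80).
#' @return An `occupancy_thresholds` object.
#' @export
occupancy_thresholds <- function(count_avg = 0.50, count_inst_max = 0.80,
                                 heatmap_avg = 0.30, heatmap_inst_max = 0.80,
                                 hamming_baseline_avg = 0.80,
                                 bsa_inst_max = 0.80) {
  vals <- c(count_avg, count_inst_max, heatmap_avg, heatmap_inst_max,
            hamming_baseline_avg, bsa_inst_max)
  if (any(vals <= 0 | vals > 1)) {
    abort("occupancy thresholds must lie in (0, 1]",
          class = "tcrmech_value_error")
  }
  structure(
    list(count_avg = count_avg, count_inst_max = count_inst_max,
         heatmap_avg = heatmap_avg, heatmap_inst_max = heatmap_inst_max,
         hamming_baseline_avg = hamming_baseline_avg,
         bsa_inst_max = bsa_inst_max),
    class = "occupancy_thresholds"
  )
}

#' Resolve an interface side to atom indices
#'
#' @param structure A [structure_model()].
#' @param spec Either an integer vector of atom indices, a character vector
#'   of chain ids, or a list with elements `chain` and optionally `resno`.
#' @return Integer atom indices.
#' @export
atom_group <- function(structure, spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  if (is.character(spec)) return(select_atoms(structure, chain = spec))
  if (is.list(spec)) {
    return(select_atoms(structure, chain = spec$chain, resno = spec$resno))
  }
  abort("interface side must be atom indices, chain ids, or list(chain, resno)",
        class = "tcrmech_configuration_error")
}

contact_key <- function(chain_a, resno_a, chain_b, resno_b, kind) {
  sprintf("%s%d-%s%d/%s", chain_a, resno_a, chain_b, resno_b,
          ifelse(kind == "hbond", "hb", "np"))
}

#' Detect interfacial contacts in one frame
#'
#' Hydrogen bonds: a donor-acceptor pair across the interface within
#' `hbond_cutoff`. Nonpolar contacts: a heavy-atom pair across the
#' interface within `nonpolar_cutoff` with both partial-charge magnitudes
#' below `charge_cutoff`. Multiple atom pairs between the same residue pair
#' and kind collapse to a single residue-pair contact.
#'
#' @param coords An `n_atoms x 3` coordinate matrix (one frame), or `NULL`
#'   to use the structure's reference coordinates.
#' @param structure A [structure_model()] (charges required for nonpolar
#'   detection, donor/acceptor annotations for hydrogen bonds).
#' @param group_a,group_b Atom indices (or specs for [atom_group()]) of the
#'   two sides of the interface.
#' @param criteria A [contact_criteria()].
#' @param kinds Which kinds to detect (default both).
#' @return A tibble of residue-pair contacts: `contact`, `chain_a`,
#'   `resno_a`, `resid_a`, `chain_b`, `resno_b`, `resid_b`, `kind`.
#' @export
detect_contacts <- function(coords, structure, group_a, group_b,
                            criteria = contact_criteria(),
                            kinds = c("hbond", "nonpolar")) {
  ctx <- contact_context(structure, group_a, group_b, criteria, kinds)
  if (is.null(coords)) coords <- structure_coords(structure)
  keys_frame_contacts(coords, ctx)
}

# Precompute candidate atom-pair lists so per-frame work is distance only.
contact_context <- function(structure, group_a, group_b, criteria, kinds) {
  stopifnot(inherits(structure, "structure_model"))
  kinds <- match.arg(kinds, c("hbond", "nonpolar"), several.ok = TRUE)
  a <- structure$atoms
  ia <- atom_group(structure, group_a)
  ib <- atom_group(structure, group_b)
  if (length(intersect(ia, ib)) > 0) {
    abort("interface sides share atoms", class = "tcrmech_configuration_error")
  }
  heavy <- !a$is_hydrogen
  pairs <- list()
  if ("hbond" %in% kinds) {
    if (criteria$hbond_mode == "heavy") {
      don_a <- ia[a$is_donor[ia] & heavy[ia]]
      don_b <- ib[a$is_donor[ib] & heavy[ib]]
    } else {
      don_a <- ia[a$is_donor[ia] & a$is_hydrogen[ia]]
      don_b <- ib[a$is_donor[ib] & a$is_hydrogen[ib]]
      if (length(don_a) + length(don_b) == 0) {
        abort("hbond_mode = 'hydrogen' needs donor-annotated hydrogens",
              class = "tcrmech_configuration_error")
      }
    }
    acc_a <- ia[a$is_acceptor[ia] & heavy[ia]]
    acc_b <- ib[a$is_acceptor[ib] & heavy[ib]]
    pairs$hbond <- rbind(expand_pairs(don_a, acc_b), expand_pairs(acc_a, don_b))
  }
  if ("nonpolar" %in% kinds) {
    ha <- ia[heavy[ia]]
    hb <- ib[heavy[ib]]
    if (anyNA(a$charge[c(ha, hb)])) {
      abort("nonpolar contact detection needs partial charges on all heavy atoms of the interface",
            class = "tcrmech_configuration_error")
    }
    qa <- ha[abs(a$charge[ha]) < criteria$charge_cutoff]
    qb <- hb[abs(a$charge[hb]) < criteria$charge_cutoff]
    pairs$nonpolar <- expand_pairs(qa, qb)
  }
  list(atoms = a, pairs = pairs, criteria = criteria)
}

expand_pairs <- function(i, j) {
  if (length(i) == 0 || length(j) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  cbind(rep(i, times = length(j)), rep(j, each = length(i)))
}

# Residue-pair contacts of one frame given a prepared context.
keys_frame_contacts <- function(coords, ctx) {
  rows <- list()
  for (kind in names(ctx$pairs)) {
    p <- ctx$pairs[[kind]]
    if (nrow(p) == 0) next
    cutoff <- if (kind == "hbond") ctx$criteria$hbond_cutoff else ctx$criteria$nonpolar_cutoff
    d2 <- rowSums((coords[p[, 1], , drop = FALSE] -
                   coords[p[, 2], , drop = FALSE])^2)
    hit <- p[d2 <= cutoff^2, , drop = FALSE]
    if (nrow(hit) == 0) next
    a <- ctx$atoms
    rows[[kind]] <- tibble(
      chain_a = a$chain[hit[, 1]], resno_a = a$resno[hit[, 1]],
      resid_a = a$resid[hit[, 1]],
      chain_b = a$chain[hit[, 2]], resno_b = a$resno[hit[, 2]],
      resid_b = a$resid[hit[, 2]],
      kind = kind
    )
  }
  if (length(rows) == 0) {
    return(tibble(contact = character(0), chain_a = character(0),
                  resno_a = integer(0), resid_a = character(0),
                  chain_b = character(0), resno_b = integer(0),
                  resid_b = character(0), kind = character(0)))
  }
  out <- distinct(bind_rows(rows))
  out$contact <- contact_key(out$chain_a, out$resno_a, out$chain_b,
                             out$resno_b, out$kind)
  select(out, "contact", dplyr::everything())
}

#' Contact timelines over a trajectory
#'
#' Detects contacts in every frame of `traj` across one declared interface
#' and assembles, per residue-pair contact ever observed, a boolean
#' presence series plus derived occupancies: the average occupancy over an
#' interval is the fraction of its frames in which the contact is present;
#' the instantaneous occupancy is a trailing `rolling_frames`-frame rolling
#' mean (truncated at the start of the series).
#'
#' @inheritParams detect_contacts
#' @param traj A [trajectory()].
#' @param windows An [analysis_windows()] (supplies `rolling_frames`).
#' @return A `contact_timelines` object with fields `keys` (tibble of
#'   contact identities), `presence` (`n_frames x n_contacts` logical
#'   matrix), `dt_save`, and `windows`. Use [tidy()] for the long table.
#' @export
build_timelines <- function(traj, group_a, group_b,
                            criteria = contact_criteria(),
                            windows = analysis_windows(),
                            kinds = c("hbond", "nonpolar")) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf == 0) abort("empty trajectory", class = "tcrmech_value_error")
  if (nf < windows$rolling_frames) {
    abort(sprintf("need at least rolling_frames = %d frames, got %d",
                  windows$rolling_frames, nf), class = "tcrmech_value_error")
  }
  ctx <- contact_context(traj$structure, group_a, group_b, criteria, kinds)
  per_frame <- vector("list", nf)
  for (i in seq_len(nf)) {
    per_frame[[i]] <- keys_frame_contacts(traj$coords[, , i, drop = TRUE], ctx)
  }
  keys <- distinct(bind_rows(per_frame)) |>
    arrange(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b,
            .data$kind)
  presence <- matrix(FALSE, nrow = nf, ncol = nrow(keys),
                     dimnames = list(NULL, keys$contact))
  for (i in seq_len(nf)) {
    hit <- per_frame[[i]]$contact
    if (length(hit) > 0) presence[i, match(hit, keys$contact)] <- TRUE
  }
  structure(
    list(keys = keys, presence = presence, dt_save = traj$dt_save,
         windows = windows),
    class = "contact_timelines"
  )
}

#' @export
print.contact_timelines <- function(x, ...) {
  cat(sprintf("<contact_timelines> %d contacts x %d frames (dt_save = %g ns)\n",
              ncol(x$presence), nrow(x$presence), x$dt_save))
  invisible(x)
}

# Frame indices covering a time interval [start, end) in ns (frame i at
# time (i-1)*dt); NULL interval means all frames.
interval_frames <- function(tl, interval) {
  nf <- nrow(tl$presence)
  if (is.null(interval)) return(seq_len(nf))
  t <- (seq_len(nf) - 1) * tl$dt_save
  idx <- which(t >= interval[1] - 1e-9 & t < interval[2] - 1e-9)
  if (length(idx) == 0) {
    abort(sprintf("no frames in interval [%g, %g) ns", interval[1], interval[2]),
          class = "tcrmech_value_error")
  }
  idx
}

#' Average occupancy per contact over an interval
#'
#' @param timelines A `contact_timelines`.
#' @param interval `c(start, end)` in ns (end-exclusive), or `NULL` for the
#'   whole run.
#' @return A tibble `contact`, `kind`, `avg_occupancy`.
#' @export
avg_occupancy <- function(timelines, interval = NULL) {
  idx <- interval_frames(timelines, interval)
  tibble(
    contact = timelines$keys$contact,
    kind = timelines$keys$kind,
    avg_occupancy = unname(colMeans(timelines$presence[idx, , drop = FALSE]))
  )
}

#' Instantaneous (rolling) occupancy matrix
#'
#' Trailing rolling mean of the presence series, width
#' `windows$rolling_frames`, truncated at the start. When `interval` is
#' given the rolling mean is recomputed within that interval only.
#'
#' @inheritParams avg_occupancy
#' @return A numeric matrix (frames of the interval x contacts).
#' @export
inst_occupancy <- function(timelines, interval = NULL) {
  idx <- interval_frames(timelines, interval)
  apply(timelines$presence[idx, , drop = FALSE], 2, rolling_mean_trailing,
        k = timelines$windows$rolling_frames)
}

#' @export
tidy.contact_timelines <- function(x, ...) {
  inst <- inst_occupancy(x)
  nf <- nrow(x$presence)
  tibble(
    contact = rep(x$keys$contact, each = nf),
    kind = rep(x$keys$kind, each = nf),
    frame = rep(seq_len(nf), times = ncol(x$presence)),
    time = rep((seq_len(nf) - 1) * x$dt_save, times = ncol(x$presence)),
    present = as.vector(x$presence),
    inst_occupancy = as.vector(inst)
  )
}

#' @export
glance.contact_timelines <- function(x, ...) {
  tibble(
    n_contacts = ncol(x$presence),
    n_frames = nrow(x$presence),
    total_ns = nrow(x$presence) * x$dt_save,
    n_hbond = sum(x$keys$kind == "hbond"),
    n_nonpolar = sum(x$keys$kind == "nonpolar")
  )
}

#' Count high-occupancy contacts
#'
#' A contact counts when, over the post-equilibration interval, its average
#' occupancy exceeds `count_avg` and its maximum instantaneous occupancy
#' reaches at least `count_inst_max`.
#'
#' @param timelines A `contact_timelines`.
#' @param thresholds An [occupancy_thresholds()].
#' @param windows An [analysis_windows()] (supplies `equilibration_cut`);
#'   defaults to the windows stored in `timelines`.
#' @return Integer count. The per-contact table is attached as attribute
#'   `"detail"`.
#' @export
count_high_occupancy <- function(timelines, thresholds = occupancy_thresholds(),
                                 windows = NULL) {
  windows <- windows %||% timelines$windows
  total <- nrow(timelines$presence) * timelines$dt_save
  interval <- c(windows$equilibration_cut, total)
  if (interval[1] >= total) {
    abort("equilibration cut leaves no frames", class = "tcrmech_value_error")
  }
  avg <- avg_occupancy(timelines, interval)$avg_occupancy
  max_inst <- apply(inst_occupancy(timelines, interval), 2, max)
  pass <- avg > thresholds$count_avg & max_inst >= thresholds$count_inst_max
  detail <- timelines$keys |>
    mutate(avg_occupancy = avg, max_inst_occupancy = max_inst, counted = pass)
  out <- sum(pass)
  attr(out, "detail") <- detail
  out
}

#' Occupancy heat-map table
#'
#' Rows are contacts whose overall average occupancy exceeds `heatmap_avg`
#' and whose maximum instantaneous occupancy over the whole run exceeds
#' `heatmap_inst_max`; cells are the average occupancy within consecutive
#' time bins.
#'
#' @inheritParams count_high_occupancy
#' @param bin_ns Width of the time bins in ns; default splits the run into
#'   50 bins.
#' @return A tibble `contact`, `kind`, `bin`, `start`, `end`, `occupancy`
#'   (empty, not an error, when no contact passes).
#' @export
heatmap_table <- function(timelines, thresholds = occupancy_thresholds(),
                          bin_ns = NULL) {
  nf <- nrow(timelines$presence)
  total <- nf * timelines$dt_save
  bin_ns <- bin_ns %||% (total / 50)
  if (bin_ns <= 0) abort("bin_ns must be > 0", class = "tcrmech_value_error")
  avg <- avg_occupancy(timelines)$avg_occupancy
  max_inst <- apply(inst_occupancy(timelines), 2, max)
  keep <- which(avg > thresholds$heatmap_avg &
                  max_inst > thresholds$heatmap_inst_max)
  if (length(keep) == 0) {
    return(tibble(contact = character(0), kind = character(0),
                  bin = integer(0), start = numeric(0), end = numeric(0),
                  occupancy = numeric(0)))
  }
  t <- (seq_len(nf) - 1) * timelines$dt_save
  bin <- pmin(floor(t / bin_ns) + 1, ceiling(total / bin_ns))
  out <- purrr::map(keep, function(j) {
    occ <- tapply(timelines$presence[, j], bin, mean)
    b <- as.integer(names(occ))
    tibble(contact = timelines$keys$contact[j], kind = timelines$keys$kind[j],
           bin = b, start = (b - 1) * bin_ns, end = pmin(b * bin_ns, total),
           occupancy = as.numeric(occ))
  })
  bind_rows(out)
}

#' Hamming distance of initially persistent contacts
#'
#' The baseline is the set of contacts whose average occupancy exceeds
#' `hamming_baseline_avg` during the baseline interval (first 50 ns by
#' default). `H(t)` counts how many baseline contacts are lost at frame t.
#' With `loss_rule = "rolling"` (default) a contact is lost wherever its
#' trailing rolling occupancy drops below `loss_occupancy`; with
#' `"permanent"` it is lost at all frames after its last presence.
#'
#' @inheritParams count_high_occupancy
#' @param baseline_interval `c(start, end)` ns of the baseline window
#'   (default `c(0, 50)`).
#' @param loss_rule `"rolling"` or `"permanent"`.
#' @param loss_occupancy Rolling-occupancy threshold below which a baseline
#'   contact counts as lost (default 0.5; `"rolling"` rule only).
#' @return A tibble `frame`, `time`, `H` with the baseline contact keys in
#'   attribute `"baseline"`.
#' @export
hamming_distance <- function(timelines, baseline_interval = c(0, 50),
                             thresholds = occupancy_thresholds(),
                             loss_rule = c("rolling", "permanent"),
                             loss_occupancy = 0.5) {
  loss_rule <- match.arg(loss_rule)
  nf <- nrow(timelines$presence)
  total <- nf * timelines$dt_save
  if (total < baseline_interval[2] - 1e-9) {
    abort(sprintf("trajectory (%g ns) shorter than baseline interval end (%g ns)",
                  total, baseline_interval[2]), class = "tcrmech_value_error")
  }
  avg <- avg_occupancy(timelines, baseline_interval)$avg_occupancy
  base <- which(avg > thresholds$hamming_baseline_avg)
  t <- (seq_len(nf) - 1) * timelines$dt_save
  if (length(base) == 0) {
    warn("no contact exceeds the baseline occupancy threshold; H is identically 0")
    out <- tibble(frame = seq_len(nf), time = t, H = 0L)
    attr(out, "baseline") <- timelines$keys[0, ]
    return(out)
  }
  lost <- matrix(FALSE, nrow = nf, ncol = length(base))
  for (j in seq_along(base)) {
    p <- timelines$presence[, base[j]]
    if (loss_rule == "rolling") {
      inst <- rolling_mean_trailing(p, timelines$windows$rolling_frames)
      lost[, j] <- inst < loss_occupancy
    } else {
      last <- if (any(p)) max(which(p)) else 0L
      if (last < nf) lost[(last + 1):nf, j] <- TRUE
    }
  }
  out <- tibble(frame = seq_len(nf), time = t, H = as.integer(rowSums(lost)))
  attr(out, "baseline") <- timelines$keys[base, ]
  out
}

#' Windowed total occupancy
#'
#' Selects contacts with average occupancy above `count_avg` and maximum
#' instantaneous occupancy above `count_inst_max` over the entire run, then
#' for every analysis window sums the per-contact window-average
#' occupancies. Typical interface groupings are intermolecular (MHC-Valpha,
#' MHC-Vbeta, peptide-Valpha, peptide-Vbeta) and intramolecular
#' (Valpha-Vbeta, Valpha-Calpha, Vbeta-Cbeta; the Calpha-Cbeta interface is
#' excluded), each built as its own timelines object.
#'
#' @param timelines A `contact_timelines` or a named list of them (one per
#'   interface group).
#' @inheritParams count_high_occupancy
#' @return A tibble `group`, `window`, `start`, `end`, `n_selected`,
#'   `total_occupancy`.
#' @export
windowed_total_occupancy <- function(timelines,
                                     thresholds = occupancy_thresholds(),
                                     windows = NULL) {
  if (inherits(timelines, "contact_timelines")) {
    timelines <- list(all = timelines)
  }
  out <- imap(timelines, function(tl, nm) {
    w <- windows %||% tl$windows
    nf <- nrow(tl$presence)
    total <- nf * tl$dt_save
    spans <- window_spans(w, total)
    avg <- avg_occupancy(tl)$avg_occupancy
    max_inst <- apply(inst_occupancy(tl), 2, max)
    sel <- which(avg > thresholds$count_avg & max_inst > thresholds$count_inst_max)
    t <- (seq_len(nf) - 1) * tl$dt_save
    tot <- map_dbl(seq_len(nrow(spans)), function(i) {
      idx <- which(t >= spans$start[i] - 1e-9 & t < spans$end[i] - 1e-9)
      if (length(sel) == 0) return(0)
      sum(colMeans(tl$presence[idx, sel, drop = FALSE]))
    })
    mutate(spans, group = nm, n_selected = length(sel), total_occupancy = tot)
  })
  bind_rows(out) |>
    select("group", "window", "start", "end", "n_selected", "total_occupancy")
}

#' Heat-map style plot of contact timelines
#'
#' @param object A `contact_timelines`.
#' @param thresholds,bin_ns Passed to [heatmap_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_timelines <- function(object,
                                       thresholds = occupancy_thresholds(),
                                       bin_ns = NULL, ...) {
  hm <- heatmap_table(object, thresholds, bin_ns)
  ggplot2::ggplot(hm, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$contact,
                                   fill = .data$occupancy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time (ns)", y = NULL, fill = "occupancy")
}
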