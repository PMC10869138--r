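#' Build a run configuration
#'
#' Collects everything one analysis run needs: the structure and
#' trajectory (paths or in-memory objects), chain roles, residue
#' specifications, criteria/threshold/window settings, declared
#' interfaces, and an optional restraint. All analysis defaults encode the
#' standard recipe (2.4 / 3.0 Angstrom and 0.3 e contact criteria,
#' 50%/80% counting and 30%/80% heat-map thresholds, 40-frame rolling
#' occupancy, 500-ns equilibration cut, 40-ns windows stepping 20 ns from
#' 200 ns, 50-ns Hamming baseline, k = 1 kcal/(mol A^2)), so a bare
#' configuration reproduces it.
#'
#' @param config A named list or the path of a YAML file with any of the
#'   fields below; missing fields take the defaults.
#' @return A `run_config` list with fields `structure`, `trajectory`,
#'   `trajectory_format`, `dt_save`, `chains`, `criteria`, `thresholds`,
#'   `windows`, `triads`, `boc`, `cdr3`, `interfaces`, `restraint`,
#'   `stages`, `bsa_stride`, `output_dir`, `seed`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "tcrmech_configuration_error")
    }
    config <- yaml::read_yaml(config)
  }
  chains <- modifyList(
    list(mhc = "A", b2m = "B", peptide = "C", tcr_alpha = "D", tcr_beta = "E"),
    config$chains %||% list()
  )
  defaults <- list(
    structure = NULL, trajectory = NULL, trajectory_format = "frames",
    charge_table = NULL, dt_save = 0.02, chains = chains,
    criteria = contact_criteria(), thresholds = occupancy_thresholds(),
    windows = analysis_windows(),
    triads = list(valpha = triad_spec_valpha(chains$tcr_alpha),
                  vbeta = triad_spec_vbeta(chains$tcr_beta)),
    boc = boc_spec(chains$tcr_alpha, chains$tcr_beta),
    cdr3 = list(alpha = list(chain = chains$tcr_alpha, resno = c(92, 97)),
                beta = list(chain = chains$tcr_beta, resno = c(94, 103))),
    interfaces = NULL, restraint = NULL,
    stages = c("contacts", "bsa", "cdr3", "triads", "boc", "peptide",
               "rmsf", "force"),
    bsa_stride = 10, hamming_baseline = c(0, 50),
    output_dir = NULL, seed = 1
  )
  cfg <- modifyList(defaults, config[setdiff(names(config), "chains")])
  cfg$chains <- chains
  if (is.null(cfg$interfaces)) {
    cfg$interfaces <- list(
      pmhc_tcr = list(a = c(chains$mhc, chains$peptide),
                      b = c(chains$tcr_alpha, chains$tcr_beta))
    )
  }
  structure(cfg, class = "run_config")
}

load_run_inputs <- function(cfg) {
  st <- cfg$structure
  if (is.character(st)) {
    st <- read_structure(st, charge_table = cfg$charge_table)
  }
  tr <- cfg$trajectory
  if (is.character(tr)) {
    if (!file.exists(tr)) {
      abort(sprintf("trajectory file not found: %s", tr),
            class = "tcrmech_configuration_error")
    }
    tr <- switch(cfg$trajectory_format,
      frames = read_frames(tr, st),
      dcd = read_dcd_trajectory(tr, st, cfg$dt_save),
      pdb = {
        out <- read_pdb_trajectory(tr, cfg$dt_save)
        st <- out$structure
        out
      },
      abort(sprintf("unknown trajectory format '%s'", cfg$trajectory_format),
            class = "tcrmech_configuration_error")
    )
  }
  if (is.null(st) && inherits(tr, "trajectory")) st <- tr$structure
  if (is.null(st) || is.null(tr)) {
    abort("config must provide a structure and a trajectory",
          class = "tcrmech_configuration_error")
  }
  list(structure = st, trajectory = tr)
}

run_stage <- function(report, name, expr) {
  report$stages[[name]] <- tryCatch(
    list(ok = TRUE, result = force(expr)),
    error = function(e) list(ok = FALSE, error = conditionMessage(e))
  )
  report
}

#' Run the full per-system analysis
#'
#' Executes every configured stage -- contact timelines, counts, heat
#' map, Hamming distance and windowed total occupancy per declared
#' interface; buried surface area; CDR3 distance; triad fitting, triad
#' angles and triad PCA (on a trajectory aligned to the two V-domain
#' cores); the V-C bead-on-chain, hinge angles, BOC PCA and the companion
#' C-frame triad PCA; peptide tilt angle; peptide RMSF (and transverse
#' RMSF when a restraint defines the load axis); force estimation -- on
#' one structure/trajectory pair. A failing stage is recorded with its
#' error message and never blocks the others.
#'
#' @param config A [run_config()] (or list/path accepted by it).
#' @return A `system_report`: list with `stages` (each `ok` + result or
#'   error), `config`. Use [report_summary()] for a flat summary and
#'   [write_report()] to export JSON + CSVs.
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  inputs <- load_run_inputs(config)
  st <- inputs$structure
  traj <- inputs$trajectory
  cfg <- config
  report <- structure(list(stages = list(), config = cfg),
                      class = "system_report")

  if ("contacts" %in% cfg$stages) {
    report <- run_stage(report, "contacts", {
      per_iface <- imap(cfg$interfaces, function(iface, nm) {
        tl <- build_timelines(traj, iface$a, iface$b, cfg$criteria,
                              cfg$windows)
        count <- count_high_occupancy(tl, cfg$thresholds, cfg$windows)
        list(
          timelines = tl,
          count = as.integer(count),
          count_detail = attr(count, "detail"),
          heatmap = heatmap_table(tl, cfg$thresholds),
          hamming = hamming_distance(tl, cfg$hamming_baseline,
                                     cfg$thresholds)
        )
      })
      tls <- purrr::map(per_iface, "timelines")
      windowed <- tryCatch(
        windowed_total_occupancy(tls, cfg$thresholds, cfg$windows),
        error = function(e) NULL
      )
      list(interfaces = per_iface, windowed_occupancy = windowed)
    })
  }

  if ("bsa" %in% cfg$stages) {
    report <- run_stage(report, "bsa", {
      iface <- cfg$interfaces[[1]]
      # sides swapped relative to the timelines: BSA selects TCR residues
      compute_bsa(traj, group_side = iface$b, group_partner = iface$a,
                  criteria = cfg$criteria, thresholds = cfg$thresholds,
                  windows = cfg$windows, stride = cfg$bsa_stride)
    })
  }

  if ("cdr3" %in% cfg$stages) {
    report <- run_stage(report, "cdr3", {
      series <- cdr3_distance(traj, cfg$cdr3$alpha, cfg$cdr3$beta)
      list(series = series,
           stats = series_stats(series, c(cfg$windows$equilibration_cut,
                                          total_time(traj))))
    })
  }

  if ("triads" %in% cfg$stages) {
    report <- run_stage(report, "triads", {
      v_idx <- c(ca_indices(st, cfg$triads$valpha$chain,
                            spec_resnos(cfg$triads$valpha)),
                 ca_indices(st, cfg$triads$vbeta$chain,
                            spec_resnos(cfg$triads$vbeta)))
      aligned <- align_trajectory(traj, v_idx)
      ta <- fit_triads(aligned, cfg$triads$valpha)
      tb <- fit_triads(aligned, cfg$triads$vbeta)
      list(angles = triad_angles(ta, tb),
           pca = pca_triads(ta, tb, cfg$windows))
    })
  }

  if ("boc" %in% cfg$stages) {
    report <- run_stage(report, "boc", {
      boc <- build_boc(traj, cfg$boc, reference = cfg$boc_reference)
      c_idx <- c_module_indices(st, cfg$boc)
      c_aligned <- align_trajectory(traj, c_idx,
                                    reference = cfg$boc_reference)
      ta <- fit_triads(c_aligned, cfg$triads$valpha)
      tb <- fit_triads(c_aligned, cfg$triads$vbeta)
      pca <- pca_boc(boc, cfg$windows)
      list(boc = boc, hinge = hinge_angles(boc), pca = pca,
           pca_triads_cframe = pca_triads(ta, tb, cfg$windows),
           asymmetry = amplitude_asymmetry(pca))
    })
  }

  if ("peptide" %in% cfg$stages) {
    report <- run_stage(report, "peptide", {
      series <- peptide_angle(traj, cfg$chains$peptide,
                              valpha = cfg$triads$valpha,
                              vbeta = cfg$triads$vbeta)
      list(series = series,
           stats = series_stats(series, c(cfg$windows$equilibration_cut,
                                          total_time(traj))))
    })
  }

  if ("rmsf" %in% cfg$stages) {
    report <- run_stage(report, "rmsf", {
      pep_ca <- select_atoms(st, chain = cfg$chains$peptide, name = "CA")
      out <- list(peptide = rmsf(traj, pep_ca))
      if (!is.null(cfg$restraint) && !is.null(cfg$restraint$axis)) {
        out$transverse <- as.numeric(
          transverse_rmsf(traj, pep_ca, cfg$restraint$axis))
      }
      out
    })
  }

  if ("force" %in% cfg$stages && !is.null(cfg$restraint)) {
    report <- run_stage(report, "force", {
      rs <- cfg$restraint
      spec <- restraint_spec(rs$anchor, rs$center, rs$k %||% 1,
                             extension = rs$extension %||% NA_real_)
      estimate_force(traj, spec, cfg$windows, axis = rs$axis)
    })
  }

  report
}

#' @export
print.system_report <- function(x, ...) {
  cat("<system_report>\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-10s %s\n", nm,
                if (s$ok) "ok" else paste("FAILED:", s$error)))
  }
  invisible(x)
}

#' Flat summary of a system report
#'
#' @param report A `system_report` from [run_analysis()].
#' @return A named list of plain summary values (counts, means, PCA
#'   amplitudes, force), suitable for JSON export; failed stages appear
#'   as `skipped` entries with their reason.
#' @export
report_summary <- function(report) {
  out <- list()
  skipped <- list()
  g <- function(nm) {
    s <- report$stages[[nm]]
    if (is.null(s)) return(NULL)
    if (!s$ok) {
      skipped[[nm]] <<- s$error
      return(NULL)
    }
    s$result
  }
  if (!is.null(co <- g("contacts"))) {
    out$contact_counts <- purrr::map(co$interfaces, "count")
    out$hamming_final <- purrr::map(co$interfaces, function(i) {
      as.integer(tail(i$hamming$H, 1))
    })
    if (!is.null(co$windowed_occupancy)) {
      out$windowed_occupancy <- as.list(co$windowed_occupancy)
    }
  }
  if (!is.null(b <- g("bsa"))) {
    out$bsa <- list(total = b$total_bsa, sd = b$total_bsa_sd,
                    per_residue = b$per_residue_bsa,
                    n_residues = nrow(b$residues))
  }
  if (!is.null(cd <- g("cdr3"))) {
    out$cdr3 <- list(mean = cd$stats$mean, sd = cd$stats$sd)
  }
  if (!is.null(tr <- g("triads"))) {
    out$triad_pca_amplitudes <- as.numeric(head(tr$pca$amplitudes, 6))
  }
  if (!is.null(bo <- g("boc"))) {
    out$boc_pca_amplitudes <- as.numeric(head(bo$pca$amplitudes, 6))
    out$hinge <- list(
      alpha_mean = mean(bo$hinge$angle_alpha),
      beta_mean = mean(bo$hinge$angle_beta)
    )
    out$asymmetry_pc1 <- bo$asymmetry$asymmetry[1]
  }
  if (!is.null(p <- g("peptide"))) {
    out$peptide_angle <- list(mean = p$stats$mean, sd = p$stats$sd)
  }
  if (!is.null(r <- g("rmsf"))) {
    out$peptide_rmsf_mean <- mean(r$peptide$rmsf)
    if (!is.null(r$transverse)) out$transverse_rmsf <- r$transverse
  }
  if (!is.null(f <- g("force"))) {
    out$force <- list(magnitude_pN = f$magnitude_pN,
                      window_sd_pN = f$window_sd_pN)
  }
  if (length(skipped) > 0) out$skipped <- skipped
  out
}

#' Write a report bundle
#'
#' Writes `report.json` (the [report_summary()]) plus per-metric CSVs
#' (timelines, heat map, Hamming series, CDR3/peptide series, hinge
#' angles, window forces) into a directory. Output is deterministic for
#' identical inputs.
#'
#' @param report A `system_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  s <- report$stages
  if (!is.null(s$contacts) && s$contacts$ok) {
    for (nm in names(s$contacts$result$interfaces)) {
      i <- s$contacts$result$interfaces[[nm]]
      wcsv(tidy(i$timelines), sprintf("timelines_%s.csv", nm))
      wcsv(i$heatmap, sprintf("heatmap_%s.csv", nm))
      wcsv(i$hamming, sprintf("hamming_%s.csv", nm))
    }
    if (!is.null(s$contacts$result$windowed_occupancy)) {
      wcsv(s$contacts$result$windowed_occupancy, "windowed_occupancy.csv")
    }
  }
  if (!is.null(s$cdr3) && s$cdr3$ok) wcsv(s$cdr3$result$series, "cdr3.csv")
  if (!is.null(s$peptide) && s$peptide$ok) {
    wcsv(s$peptide$result$series, "peptide_angle.csv")
  }
  if (!is.null(s$boc) && s$boc$ok) wcsv(s$boc$result$hinge, "hinge_angles.csv")
  if (!is.null(s$force) && s$force$ok) {
    wcsv(s$force$result$window_forces, "window_forces.csv")
  }
  invisible(dir)
}

#' Compare reports across systems
#'
#' Because triads and beads are assigned identically in every run,
#' relative motion in different simulations can be compared directly:
#' pairwise absolute dot products between leading PCA modes, contact
#' counts and BSA side by side, and displacement of each average BOC bead
#' from a designated reference system's.
#'
#' @param reports Named list of `system_report`s (>= 2).
#' @param n_modes Leading modes for the similarity matrices.
#' @param reference Name or index of the reference report for BOC
#'   displacements (default the first).
#' @return A list with `similarity_triad`, `similarity_boc` (matrices of
#'   PC1 similarities), `counts` (tibble), `boc_displacement` (tibble
#'   `system`, `bead`, `displacement`).
#' @export
compare_systems <- function(reports, n_modes = 1, reference = 1) {
  if (length(reports) < 2) {
    abort("need at least 2 reports", class = "tcrmech_value_error")
  }
  if (is.null(names(reports))) names(reports) <- paste0("run", seq_along(reports))
  get_pca <- function(r, stage) {
    s <- r$stages[[stage]]
    if (is.null(s) || !s$ok) return(NULL)
    s$result$pca
  }
  sim_matrix <- function(stage) {
    pcas <- purrr::map(reports, get_pca, stage = stage)
    ok <- !vapply(pcas, is.null, logical(1))
    if (sum(ok) < 2) return(NULL)
    nm <- names(reports)[ok]
    m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      m[i, j] <- mode_similarity(pcas[[nm[i]]], pcas[[nm[j]]])
    }
    m
  }
  counts <- purrr::imap(reports, function(r, nm) {
    s <- r$stages$contacts
    if (is.null(s) || !s$ok) return(NULL)
    tibble(system = nm,
           interface = names(s$result$interfaces),
           count = vapply(s$result$interfaces, function(i) i$count,
                          integer(1)))
  }) |> bind_rows()
  mean_beads <- purrr::map(reports, function(r) {
    s <- r$stages$boc
    if (is.null(s) || !s$ok) return(NULL)
    apply(s$result$boc$beads, c(1, 2), mean)
  })
  ref_nm <- if (is.numeric(reference)) names(reports)[reference] else reference
  disp <- NULL
  if (!is.null(mean_beads[[ref_nm]])) {
    disp <- purrr::imap(mean_beads, function(mb, nm) {
      if (is.null(mb)) return(NULL)
      d <- unname(vec_norm(mb - mean_beads[[ref_nm]]))
      tibble(system = nm, bead = rownames(mb), displacement = d)
    }) |> bind_rows()
  }
  list(similarity_triad = sim_matrix("triads"),
       similarity_boc = sim_matrix("boc"),
       counts = counts,
       boc_displacement = disp)
}
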