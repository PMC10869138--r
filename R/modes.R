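# Core PCA machinery shared by the triad and BOC variants.
#
# X: frames x d configuration matrix. The mean and covariance are
# estimated on the post-equilibration frames only; projections are
# reported for all frames. Mode sign convention: first component larger
# than 1e-12 in magnitude is positive (determinism; similarity comparisons
# use absolute dot products anyway).
pca_core <- function(X, analysis_rows, labels, kind, group_map,
                     units = "") {
  if (length(analysis_rows) < 2) {
    abort("PCA needs at least 2 frames after the equilibration cut",
          class = "tcrmech_value_error")
  }
  mu <- colMeans(X[analysis_rows, , drop = FALSE])
  centred <- sweep(X, 2, mu)
  C <- cov(centred[analysis_rows, , drop = FALSE])
  ev <- eigen(C, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  modes <- ev$vectors
  for (m in seq_len(ncol(modes))) {
    nz <- which(abs(modes[, m]) > 1e-12)
    if (length(nz) > 0 && modes[nz[1], m] < 0) modes[, m] <- -modes[, m]
  }
  proj <- centred %*% modes
  amplitudes <- apply(proj[analysis_rows, , drop = FALSE], 2, sd)
  # zero amplitude beyond numerical rank
  rank_tol <- max(vals) * 1e-10
  amplitudes[vals <= rank_tol] <- 0
  dimnames(modes) <- list(labels, paste0("PC", seq_len(ncol(modes))))
  colnames(proj) <- colnames(modes)
  structure(
    list(mean = setNames(mu, labels), modes = modes,
         amplitudes = setNames(amplitudes, colnames(modes)),
         eigenvalues = setNames(vals, colnames(modes)),
         projections = proj, analysis_rows = analysis_rows,
         labels = labels, kind = kind, units = units,
         group_map = group_map),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %s PCA: %d dims, %d frames (%d analysed)\n",
              x$kind, length(x$mean), nrow(x$projections),
              length(x$analysis_rows)))
  k <- min(5, length(x$amplitudes))
  cat("  amplitudes:", sprintf("%.4g", x$amplitudes[seq_len(k)]),
      if (length(x$amplitudes) > k) "..." else "", x$units, "\n")
  invisible(x)
}

#' PCA of the paired variable-domain triads
#'
#' The configuration vector of a frame is the 18 components of the six
#' triad arms (e1, e2, e3 of Valpha then Vbeta). Because the arms are unit
#' vectors, small-angle arm displacements approximate rotation angles, so
#' mode amplitudes (standard deviations of the projections) are in
#' radians. The trajectory must be pre-aligned to the two domains'
#' beta-sheet cores (see [align_trajectory()]) so global rigid motion does
#' not masquerade as arm motion.
#'
#' @param triads_alpha,triads_beta `triad_series` from [fit_triads()], same
#'   length.
#' @param windows An [analysis_windows()]; the covariance and mean use
#'   frames after `equilibration_cut`, projections cover all frames.
#' @return A `pca_result` (see [tidy.pca_result()], [glance.pca_result()]).
#' @export
pca_triads <- function(triads_alpha, triads_beta,
                       windows = analysis_windows()) {
  stopifnot(inherits(triads_alpha, "triad_series"),
            inherits(triads_beta, "triad_series"),
            nrow(triads_alpha$e1) == nrow(triads_beta$e1))
  X <- cbind(triads_alpha$e1, triads_alpha$e2, triads_alpha$e3,
             triads_beta$e1, triads_beta$e2, triads_beta$e3)
  labels <- as.vector(outer(
    c("x", "y", "z"),
    c("a.e1", "a.e2", "a.e3", "b.e1", "b.e2", "b.e3"),
    function(ax, arm) paste(arm, ax, sep = ".")
  ))
  nf <- nrow(X)
  t <- (seq_len(nf) - 1) * triads_alpha$dt_save
  rows <- which(t >= windows$equilibration_cut - 1e-9)
  group_map <- list(alpha = 1:9, beta = 10:18)
  pca_core(X, rows, labels, kind = "triad", group_map = group_map,
           units = "rad")
}

#' PCA of the V-C bead-on-chain
#'
#' The configuration vector of a frame is the 18 Cartesian coordinates of
#' the six beads (already expressed in the C-module reference frame by
#' [build_boc()]); mode amplitudes are in Angstrom.
#'
#' @param boc A `boc_model` from [build_boc()].
#' @param windows An [analysis_windows()].
#' @return A `pca_result`.
#' @export
pca_boc <- function(boc, windows = analysis_windows()) {
  stopifnot(inherits(boc, "boc_model"))
  nf <- dim(boc$beads)[3]
  beads <- dimnames(boc$beads)[[1]]
  X <- t(apply(boc$beads, 3, function(m) as.vector(t(m))))
  labels <- as.vector(t(outer(beads, c("x", "y", "z"), paste, sep = ".")))
  colnames(X) <- labels
  t <- (seq_len(nf) - 1) * boc$dt_save
  rows <- which(t >= windows$equilibration_cut - 1e-9)
  alpha_beads <- which(beads %in% c("Va", "Ca", "Ha"))
  beta_beads <- which(beads %in% c("Vb", "Cb", "Hb"))
  dims_of <- function(b) as.vector(vapply(b, function(k) (k - 1) * 3 + 1:3,
                                          numeric(3)))
  group_map <- list(alpha = dims_of(alpha_beads), beta = dims_of(beta_beads))
  pca_core(X, rows, labels, kind = "boc", group_map = group_map, units = "A")
}

#' @export
tidy.pca_result <- function(x, ...) {
  tibble(
    mode = seq_along(x$amplitudes),
    amplitude = as.numeric(x$amplitudes),
    variance = as.numeric(x$eigenvalues),
    variance_fraction = as.numeric(x$eigenvalues) / sum(x$eigenvalues)
  )
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble(
    kind = x$kind,
    n_dims = length(x$mean),
    n_frames = nrow(x$projections),
    n_analysed = length(x$analysis_rows),
    total_variance = sum(x$eigenvalues),
    pc1_amplitude = as.numeric(x$amplitudes[1]),
    pc1_variance_fraction = as.numeric(x$eigenvalues[1]) / sum(x$eigenvalues)
  )
}

#' Scree-style plot of PCA amplitudes
#' @param object A `pca_result`.
#' @param n_modes Number of leading modes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_result <- function(object, n_modes = 10, ...) {
  d <- head(tidy(object), n_modes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mode, y = .data$amplitude)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mode", y = paste0("amplitude (", object$units, ")"))
}

#' Similarity of two principal-component directions
#'
#' The absolute dot product of the two unit mode vectors, in \[0, 1\]
#' (1 for identical or sign-flipped directions, 0 for orthogonal).
#'
#' @param a,b Unit vectors, or `pca_result` objects.
#' @param mode_a,mode_b Mode index taken from each `pca_result`.
#' @return A number in \[0, 1\].
#' @export
mode_similarity <- function(a, b, mode_a = 1, mode_b = 1) {
  va <- if (inherits(a, "pca_result")) a$modes[, mode_a] else a
  vb <- if (inherits(b, "pca_result")) b$modes[, mode_b] else b
  if (length(va) != length(vb)) {
    abort("mode vectors differ in dimension", class = "tcrmech_value_error")
  }
  abs(sum(va * vb))
}

#' Project configurations onto a mode
#'
#' Subtracts the PCA's post-equilibration mean configuration and forms the
#' dot product with the requested mode vector.
#'
#' @param pca A `pca_result`.
#' @param configs A `frames x d` configuration matrix, a single
#'   configuration vector, or `NULL` for the frames the PCA was built from.
#' @param mode Mode index.
#' @return Numeric vector of per-frame projections.
#' @export
project_onto_mode <- function(pca, configs = NULL, mode = 1) {
  stopifnot(inherits(pca, "pca_result"))
  if (is.null(configs)) return(as.numeric(pca$projections[, mode]))
  if (is.vector(configs)) configs <- matrix(configs, nrow = 1)
  if (ncol(configs) != length(pca$mean)) {
    abort("configuration dimension mismatch", class = "tcrmech_value_error")
  }
  as.numeric(sweep(configs, 2, pca$mean) %*% pca$modes[, mode])
}

#' Alpha-beta amplitude asymmetry per mode
#'
#' For each mode, the root-mean-square displacement of the alpha-chain
#' beads/arms within the unit mode vector minus that of the matched
#' beta-chain group, scaled by the mode amplitude. Positive values mean
#' the alpha chain moves more in that mode. Swapping the group labels
#' negates the report.
#'
#' @param pca A `pca_result`.
#' @param group_map List with integer dimension indices `alpha` and `beta`
#'   (defaults to the map stored in the `pca_result`). Groups must be
#'   disjoint and of equal size, each a whole number of 3-vectors.
#' @param n_modes How many leading modes to report.
#' @return A tibble `mode`, `amplitude`, `alpha_rms`, `beta_rms`,
#'   `asymmetry`.
#' @export
amplitude_asymmetry <- function(pca, group_map = NULL, n_modes = 6) {
  stopifnot(inherits(pca, "pca_result"))
  gm <- group_map %||% pca$group_map
  if (is.null(gm$alpha) || is.null(gm$beta) ||
      length(gm$alpha) != length(gm$beta) ||
      length(intersect(gm$alpha, gm$beta)) > 0 ||
      length(gm$alpha) %% 3 != 0) {
    abort("group map must give disjoint, equal-sized alpha/beta dimension sets (whole 3-vectors)",
          class = "tcrmech_configuration_error")
  }
  unit_rms <- function(v, dims) {
    disp2 <- colSums(matrix(v[dims]^2, nrow = 3))
    sqrt(mean(disp2))
  }
  n_modes <- min(n_modes, ncol(pca$modes))
  out <- purrr::map(seq_len(n_modes), function(m) {
    v <- pca$modes[, m]
    a <- unit_rms(v, gm$alpha)
    b <- unit_rms(v, gm$beta)
    amp <- as.numeric(pca$amplitudes[m])
    tibble(mode = m, amplitude = amp,
           alpha_rms = amp * a, beta_rms = amp * b,
           asymmetry = amp * (a - b))
  })
  bind_rows(out)
}

#' Conditional statistics of a scalar against an angle
#'
#' Bins the scalar series by the angle series (equal-width bins over the
#' observed angle range) and reports the per-bin mean and standard
#' deviation. Sparse bins -- the thin large- and small-angle tails where
#' statistics deteriorate -- are flagged.
#'
#' @param angle,scalar Equal-length numeric vectors (or tibbles with a
#'   `value` column).
#' @param n_bins Number of bins (>= 2).
#' @param min_count Bins with fewer samples are flagged `sparse`.
#' @return A tibble `bin`, `angle_mid`, `mean`, `sd`, `n`, `sparse`.
#' @export
angle_conditional_stats <- function(angle, scalar, n_bins = 18,
                                    min_count = 10) {
  if (is.data.frame(angle)) angle <- angle$value
  if (is.data.frame(scalar)) scalar <- scalar$value
  if (length(angle) != length(scalar)) {
    abort("angle and scalar series differ in length",
          class = "tcrmech_value_error")
  }
  if (n_bins < 2) abort("need n_bins >= 2", class = "tcrmech_value_error")
  rng <- range(angle)
  if (diff(rng) < 1e-12) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(angle, edges, rightmost.closed = TRUE), n_bins)
  out <- tibble(bin = bin, angle = angle, scalar = scalar) |>
    group_by(.data$bin) |>
    summarise(mean = mean(.data$scalar),
              sd = if (n() > 1) sd(.data$scalar) else 0,
              n = n(), .groups = "drop") |>
    mutate(angle_mid = (edges[.data$bin] + edges[.data$bin + 1]) / 2,
           sparse = .data$n < min_count) |>
    select("bin", "angle_mid", "mean", "sd", "n", "sparse")
  out
}
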