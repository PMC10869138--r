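#' Variable-domain triad specification
#'
#' A triad is an orthonormal frame {e1, e2, e3} plus centroid fitted to the
#' backbone C-alpha atoms of the four central beta-strands (six residues
#' each) of an immunoglobulin variable domain. `e3` runs along the major
#' axis of the least-squares plane of the core (parallel to the strands,
#' signed towards the CDR3 loop), `e1` from the inner to the outer
#' beta-sheet (orthogonalised against e3), and `e2 = e3 x e1`.
#'
#' The default core segments are the renumbered V-domain strands of the A6
#' TCR: Valpha S19-Y24, F32-Q37, Y70-I75, Y86-T91; Vbeta T20-Q25, S33-D38,
#' F74-L79, V88-S93. Segments 1 and 4 form the inner sheet, 2 and 3 the
#' outer sheet (configurable).
#'
#' @param chain Chain id of the domain.
#' @param segments List of four `c(first, last)` renumbered residue ranges.
#' @param inner,outer Which segments (1-4) form the inner / outer sheet.
#' @param cdr3 Two renumbered residue indices at the base of the domain's
#'   CDR3 loop (used to sign e3 at the first frame).
#' @return A `triad_spec` object.
#' @export
triad_spec <- function(chain, segments, inner = c(1, 4), outer = c(2, 3),
                       cdr3 = NULL) {
  stopifnot(length(segments) == 4,
            all(vapply(segments, length, 1L) == 2))
  if (length(intersect(inner, outer)) > 0 ||
      !setequal(sort(c(inner, outer)), 1:4)) {
    abort("inner/outer must partition segments 1:4",
          class = "tcrmech_configuration_error")
  }
  structure(list(chain = chain, segments = segments, inner = inner,
                 outer = outer, cdr3 = cdr3),
            class = "triad_spec")
}

#' @rdname triad_spec
#' @export
triad_spec_valpha <- function(chain = "D") {
  triad_spec(chain,
             list(c(19, 24), c(32, 37), c(70, 75), c(86, 91)),
             cdr3 = c(92, 97))
}

#' @rdname triad_spec
#' @export
triad_spec_vbeta <- function(chain = "E") {
  triad_spec(chain,
             list(c(20, 25), c(33, 38), c(74, 79), c(88, 93)),
             cdr3 = c(94, 103))
}

spec_resnos <- function(spec, which = 1:4) {
  unlist(lapply(spec$segments[which], function(s) seq(s[1], s[2])))
}

#' Fit one triad to core coordinates
#'
#' @param core_coords `n x 3` matrix of core C-alpha coordinates, ordered
#'   segment by segment (six residues per segment).
#' @param inner_rows,outer_rows Row indices of the inner / outer sheet.
#' @param cdr3_point Optional 3-vector towards which e3 is signed.
#' @param prev Optional previous-frame `triad` for sign continuity.
#' @return A `triad`: list with unit vectors `e1`, `e2`, `e3` and
#'   `centroid`.
#' @export
fit_triad <- function(core_coords, inner_rows, outer_rows,
                      cdr3_point = NULL, prev = NULL) {
  stopifnot(is.matrix(core_coords), ncol(core_coords) == 3,
            nrow(core_coords) >= 6)
  centroid <- colMeans(core_coords)
  centred <- sweep(core_coords, 2, centroid)
  ev <- eigen(crossprod(centred) / nrow(core_coords), symmetric = TRUE)
  if (ev$values[2] < 1e-10 * ev$values[1]) {
    abort("degenerate (collinear) core coordinates",
          class = "tcrmech_geometry_error")
  }
  e3 <- ev$vectors[, 1]
  if (!is.null(prev)) {
    if (sum(e3 * prev$e3) < 0) e3 <- -e3
  } else if (!is.null(cdr3_point)) {
    if (sum(e3 * (cdr3_point - centroid)) < 0) e3 <- -e3
  }
  v <- colMeans(core_coords[outer_rows, , drop = FALSE]) -
    colMeans(core_coords[inner_rows, , drop = FALSE])
  v <- v - sum(v * e3) * e3
  if (vec_norm(v) < 1e-9) {
    abort("inner->outer sheet direction degenerate with e3",
          class = "tcrmech_geometry_error")
  }
  e1 <- unit(v)
  e2 <- cross3(e3, e1)
  structure(list(e1 = e1, e2 = e2, e3 = e3, centroid = centroid),
            class = "triad")
}

#' @export
print.triad <- function(x, ...) {
  cat("<triad> centroid:", sprintf("%.2f", x$centroid), "\n")
  for (k in c("e1", "e2", "e3")) {
    cat(" ", k, ":", sprintf("%+.3f", x[[k]]), "\n")
  }
  invisible(x)
}

# Row indices within the ordered core-coordinate matrix for a sheet.
sheet_rows <- function(spec, which) {
  lens <- vapply(spec$segments, function(s) as.integer(s[2] - s[1] + 1),
                 integer(1))
  offsets <- cumsum(c(0L, lens))
  unlist(lapply(which, function(k) offsets[k] + seq_len(lens[k])))
}

#' Fit triads over a trajectory
#'
#' Fits one triad per frame. The e3 sign is set towards the CDR3 base
#' midpoint at the first frame, then kept continuous frame to frame.
#'
#' @param traj A [trajectory()].
#' @param spec A [triad_spec()].
#' @return A `triad_series`: list of matrices `e1`, `e2`, `e3`, `centroid`
#'   (`n_frames x 3`) plus `dt_save`.
#' @export
fit_triads <- function(traj, spec) {
  stopifnot(inherits(traj, "trajectory"), inherits(spec, "triad_spec"))
  core_idx <- ca_indices(traj$structure, spec$chain, spec_resnos(spec))
  cdr3_idx <- if (!is.null(spec$cdr3)) {
    ca_indices(traj$structure, spec$chain, spec$cdr3)
  }
  inner_rows <- sheet_rows(spec, spec$inner)
  outer_rows <- sheet_rows(spec, spec$outer)
  nf <- n_frames(traj)
  out <- list(e1 = matrix(0, nf, 3), e2 = matrix(0, nf, 3),
              e3 = matrix(0, nf, 3), centroid = matrix(0, nf, 3))
  prev <- NULL
  for (i in seq_len(nf)) {
    m <- traj$coords[, , i, drop = TRUE]
    cdr3_point <- if (!is.null(cdr3_idx)) colMeans(m[cdr3_idx, , drop = FALSE])
    tr <- fit_triad(m[core_idx, , drop = FALSE], inner_rows, outer_rows,
                    cdr3_point = cdr3_point, prev = prev)
    out$e1[i, ] <- tr$e1
    out$e2[i, ] <- tr$e2
    out$e3[i, ] <- tr$e3
    out$centroid[i, ] <- tr$centroid
    prev <- tr
  }
  structure(c(out, list(dt_save = traj$dt_save, spec = spec)),
            class = "triad_series")
}

#' @export
print.triad_series <- function(x, ...) {
  cat(sprintf("<triad_series> %d frames (chain %s)\n",
              nrow(x$e1), x$spec$chain %||% "?"))
  invisible(x)
}

# Extract one frame of a triad_series as a triad.
triad_at <- function(series, i) {
  structure(list(e1 = series$e1[i, ], e2 = series$e2[i, ],
                 e3 = series$e3[i, ], centroid = series$centroid[i, ]),
            class = "triad")
}

#' Angles between matching triad arms
#'
#' The angle between arm ek of two triads is `arccos(ekA . ekB)` in
#' degrees, in \[0, 180\].
#'
#' @param a,b Two `triad` objects, or two `triad_series` of equal length.
#' @return For single triads, a named vector `c(e1, e2, e3)`; for series, a
#'   tibble `frame`, `time`, `angle_e1`, `angle_e2`, `angle_e3`.
#' @export
triad_angles <- function(a, b) {
  if (inherits(a, "triad") && inherits(b, "triad")) {
    return(c(e1 = acos_deg(sum(a$e1 * b$e1)),
             e2 = acos_deg(sum(a$e2 * b$e2)),
             e3 = acos_deg(sum(a$e3 * b$e3))))
  }
  stopifnot(inherits(a, "triad_series"), inherits(b, "triad_series"),
            nrow(a$e1) == nrow(b$e1))
  nf <- nrow(a$e1)
  tibble(
    frame = seq_len(nf),
    time = (seq_len(nf) - 1) * a$dt_save,
    angle_e1 = acos_deg(rowSums(a$e1 * b$e1)),
    angle_e2 = acos_deg(rowSums(a$e2 * b$e2)),
    angle_e3 = acos_deg(rowSums(a$e3 * b$e3))
  )
}
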