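# Shared fixtures built in code. The synthetic template is deterministic,
# so build it once per test session.
template <- make_domain_template()
iface <- synthetic_interface(template)

# Short analysis windows matched to desk-scale synthetic runs.
short_windows <- function(nf = NULL, cut = 0) {
  analysis_windows(equilibration_cut = cut, window = 1, step = 0.5,
                   window_start = 0, rolling_frames = 40)
}

# A tiny hand-built structure for contact-criterion unit tests: atoms are
# placed explicitly and annotated explicitly.
toy_contact_structure <- function(atoms) {
  mod <- structure_model(atoms, renumber = FALSE)
  assign_donors_acceptors(mod, donors = which(atoms$donor %||% rep(FALSE, nrow(atoms))),
                          acceptors = which(atoms$acceptor %||% rep(FALSE, nrow(atoms))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Triads of a trajectory after aligning on both V cores (the standard
# pre-alignment for triad PCA).
aligned_v_triads <- function(traj) {
  st <- traj$structure
  v_idx <- c(tcrmech:::ca_indices(st, "D", tcrmech:::spec_resnos(triad_spec_valpha("D"))),
             tcrmech:::ca_indices(st, "E", tcrmech:::spec_resnos(triad_spec_vbeta("E"))))
  al <- align_trajectory(traj, v_idx)
  list(alpha = fit_triads(al, triad_spec_valpha("D")),
       beta = fit_triads(al, triad_spec_vbeta("E")))
}

# Random rotation matrix from a fixed RNG stream.
random_rotation <- function() {
  axis <- rnorm(3)
  tcrmech:::rotation_matrix(axis, runif(1, 0, pi))
}
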