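#' Structure models
#'
#' A `structure_model` holds the atoms of one molecular structure: identity
#' (chain, residue, atom name, element), reference coordinates in Angstrom,
#' optional per-atom partial charges (units of elementary charge e) and
#' optional hydrogen-bond donor/acceptor annotations. Residues are always
#' renumbered sequentially from 1 within each chain; the numbering found in
#' the input file is kept in `orig_resno`. All residue selections elsewhere
#' in the package use the renumbered index.
#'
#' @param atoms A data frame with columns `chain`, `resno`, `resid`, `name`,
#'   `element`, `x`, `y`, `z`; optionally `charge`, `is_donor`,
#'   `is_acceptor`, `is_hydrogen`, `atom_id`, `orig_resno`.
#' @param renumber Renumber residues sequentially per chain (default `TRUE`).
#'
#' @return A `structure_model` object: a list with elements `atoms`
#'   (a tibble, one row per atom) and `chains` (chain ids in order of
#'   appearance).
#' @export
structure_model <- function(atoms, renumber = TRUE) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resno", "resid", "name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atoms table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "tcrmech_structure_error")
  }
  if (nrow(atoms) == 0) {
    abort("structure has no atoms", class = "tcrmech_parse_error")
  }
  if (!"atom_id" %in% names(atoms)) atoms$atom_id <- seq_len(nrow(atoms))
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"is_donor" %in% names(atoms)) atoms$is_donor <- FALSE
  if (!"is_acceptor" %in% names(atoms)) atoms$is_acceptor <- FALSE
  if (!"is_hydrogen" %in% names(atoms)) {
    atoms$is_hydrogen <- toupper(atoms$element) == "H"
  }
  if (renumber) {
    atoms$orig_resno <- atoms$resno
    atoms <- atoms |>
      group_by(.data$chain) |>
      mutate(resno = match(.data$orig_resno, unique(.data$orig_resno))) |>
      ungroup()
  } else if (!"orig_resno" %in% names(atoms)) {
    atoms$orig_resno <- atoms$resno
  }
  dup <- atoms |>
    dplyr::count(.data$chain, .data$resno, .data$name) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate atom '%s' in residue %s%d",
                  dup$name[1], dup$chain[1], dup$resno[1]),
          class = "tcrmech_structure_error")
  }
  q <- atoms$charge[!is.na(atoms$charge)]
  if (length(q) > 0 && (any(!is.finite(q)) || any(abs(q) >= 3))) {
    abort("partial charges must be finite with |q| < 3 e",
          class = "tcrmech_structure_error")
  }
  structure(
    list(atoms = atoms, chains = unique(atoms$chain)),
    class = "structure_model"
  )
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records with [bio3d::read.pdb()], renumbers residues
#' sequentially within each chain (keeping the file's numbering as
#' `orig_resno`), and optionally attaches per-atom partial charges from a
#' two-column table and donor/acceptor annotations from an element
#' heuristic.
#'
#' @param path Path to a PDB file.
#' @param charge_table Optional path to a whitespace-delimited two-column
#'   file (atom id, charge in e) or a data frame with columns `atom_id`,
#'   `charge`. Atom ids refer to the order of atoms in the file (1-based).
#' @param annotate If `TRUE` (default), mark hydrogen-bond donors and
#'   acceptors by the element heuristic of [assign_donors_acceptors()].
#' @return A [structure_model()].
#' @export
read_structure <- function(path, charge_table = NULL, annotate = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("structure file not found: %s", path),
          class = "tcrmech_parse_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) {
      abort(sprintf("failed to parse PDB '%s': %s", path, conditionMessage(e)),
            class = "tcrmech_parse_error")
    }
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    abort(sprintf("no ATOM/HETATM records in '%s'", path),
          class = "tcrmech_parse_error")
  }
  elem <- at$elesy
  bad <- is.na(elem) | trimws(elem) == ""
  if (any(bad)) {
    # fall back to the first alphabetic character of the atom name
    elem[bad] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[bad])
  }
  chain <- ifelse(is.na(at$chain) | at$chain == "", "_", at$chain)
  atoms <- tibble(
    chain = chain,
    resno = at$resno,
    resid = at$resid,
    name = at$elety,
    element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z
  )
  mod <- structure_model(atoms, renumber = TRUE)
  if (!is.null(charge_table)) mod <- attach_charges(mod, charge_table)
  if (annotate) mod <- assign_donors_acceptors(mod)
  mod
}

#' Attach partial charges to a structure
#'
#' @param structure A [structure_model()].
#' @param charge_table Path to a two-column whitespace-delimited file
#'   (atom id, charge) or a data frame with columns `atom_id` and `charge`.
#' @return The structure with its `charge` column filled.
#' @export
attach_charges <- function(structure, charge_table) {
  stopifnot(inherits(structure, "structure_model"))
  if (is.character(charge_table)) {
    charge_table <- utils::read.table(charge_table, header = FALSE,
                                      col.names = c("atom_id", "charge"))
  }
  charge_table <- as_tibble(charge_table)
  if (!all(c("atom_id", "charge") %in% names(charge_table))) {
    abort("charge table needs columns atom_id and charge",
          class = "tcrmech_configuration_error")
  }
  idx <- match(structure$atoms$atom_id, charge_table$atom_id)
  q <- charge_table$charge[idx]
  if (any(!is.finite(q[!is.na(q)])) || any(abs(q) >= 3, na.rm = TRUE)) {
    abort("partial charges must be finite with |q| < 3 e",
          class = "tcrmech_structure_error")
  }
  structure$atoms$charge <- q
  structure
}

#' Annotate hydrogen-bond donors and acceptors
#'
#' Default heuristic: nitrogen atoms are donors and acceptors, oxygen atoms
#' are acceptors, and hydroxyl/thiol oxygens-sulfurs (names OG, OG1, OH, SG)
#' are also donors. Real force-field topologies are more discriminating;
#' pass explicit `donors`/`acceptors` (logical vectors or atom-id vectors)
#' to override, as the synthetic generator does.
#'
#' @param structure A [structure_model()].
#' @param donors,acceptors Optional explicit annotations: logical vectors of
#'   length `nrow(atoms)` or integer vectors of atom ids.
#' @return The structure with `is_donor`/`is_acceptor` set.
#' @export
assign_donors_acceptors <- function(structure, donors = NULL, acceptors = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms
  as_flag <- function(x) {
    if (is.logical(x)) {
      stopifnot(length(x) == nrow(a))
      x
    } else {
      a$atom_id %in% x
    }
  }
  if (is.null(donors)) {
    donors <- a$element == "N" | a$name %in% c("OG", "OG1", "OH", "SG")
  } else {
    donors <- as_flag(donors)
  }
  if (is.null(acceptors)) {
    acceptors <- a$element %in% c("O", "N")
  } else {
    acceptors <- as_flag(acceptors)
  }
  structure$atoms$is_donor <- donors
  structure$atoms$is_acceptor <- acceptors
  structure
}

#' Resolve an atom selection
#'
#' @param structure A [structure_model()].
#' @param chain,resno,name Optional filters; `NULL` means no constraint.
#' @param required If `TRUE`, an empty result is a selection error.
#' @return Integer row indices into `structure$atoms`.
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL, name = NULL,
                         required = TRUE) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  idx <- which(keep)
  if (required && length(idx) == 0) {
    abort(sprintf(
      "selection matched no atoms (chain %s, resno %s, name %s)",
      paste(chain %||% "*", collapse = ","),
      paste(resno %||% "*", collapse = ","),
      paste(name %||% "*", collapse = ",")
    ), class = "tcrmech_selection_error")
  }
  idx
}

# Indices of the C-alpha atom of given residues, in the order requested.
ca_indices <- function(structure, chain, resno) {
  idx <- vapply(resno, function(r) {
    i <- select_atoms(structure, chain = chain, resno = r, name = "CA",
                      required = FALSE)
    if (length(i) == 0) {
      abort(sprintf("missing CA atom for residue %s%d", chain, r),
            class = "tcrmech_selection_error")
    }
    i[1]
  }, integer(1))
  idx
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("<structure_model> ", nrow(a), " atoms, ",
      length(x$chains), " chain(s)\n", sep = "")
  per <- a |>
    group_by(.data$chain) |>
    summarise(residues = dplyr::n_distinct(.data$resno), atoms = n())
  for (i in seq_len(nrow(per))) {
    cat(sprintf("  chain %s: %d residues, %d atoms\n",
                per$chain[i], per$residues[i], per$atoms[i]))
  }
  if (any(!is.na(a$charge))) cat("  partial charges attached\n")
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param structure A [structure_model()].
#' @return Numeric matrix with one row per atom (Angstrom).
#' @export
structure_coords <- function(structure) {
  stopifnot(inherits(structure, "structure_model"))
  as.matrix(structure$atoms[, c("x", "y", "z")])
}
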