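#' Build an atom table
#'
#' Constructs and validates the atom table shared by all analysis stages.
#' Each row is one atom; roles distinguish the nanocluster (gold core,
#' inner gold, sulfur anchors, ligand heavy atoms) from analyte molecules
#' (heavy atoms and the backbone C-alpha), hydrogens and solvent.
#'
#' @param element Chemical symbols (character).
#' @param role One of `"core_gold"`, `"inner_gold"`, `"sulfur"`,
#'   `"ligand_heavy"`, `"analyte_heavy"`, `"analyte_calpha"`,
#'   `"hydrogen"`, `"solvent"`.
#' @param analyte_id Integer analyte molecule id (`NA` for non-analyte
#'   atoms). Ids must form a contiguous set starting at 1.
#' @param charge Partial charge in elementary charges (optional, `NA` allowed).
#' @param lj_sigma,lj_epsilon Lennard-Jones parameters, nm and kJ/mol
#'   (optional).
#' @param mass Atomic mass in amu; looked up from `element` when missing.
#' @return A tibble with one row per atom.
#' @export
atom_table <- function(element, role, analyte_id = NA_integer_,
                       charge = NA_real_, lj_sigma = NA_real_,
                       lj_epsilon = NA_real_, mass = NULL) {
  n <- length(element)
  role <- as.character(role)
  bad <- setdiff(unique(role), .roles)
  if (length(bad) > 0) {
    abort(paste0("unknown atom role(s): ", paste(bad, collapse = ", ")),
          class = "nanocd_validation_error")
  }
  if (is.null(mass)) {
    mass <- unname(.default_masses[element])
    if (anyNA(mass)) {
      abort("mass missing and element not in the built-in mass table",
            class = "nanocd_validation_error")
    }
  }
  atoms <- tibble::tibble(
    element = element,
    role = role,
    analyte_id = vctrs_int(analyte_id, n),
    charge = rep_len(charge, n),
    lj_sigma = rep_len(lj_sigma, n),
    lj_epsilon = rep_len(lj_epsilon, n),
    mass = rep_len(as.numeric(mass), n)
  )
  validate_atoms(atoms)
  atoms
}

vctrs_int <- function(x, n) rep_len(as.integer(x), n)

validate_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  if (any(!atoms$role %in% .roles)) {
    abort("unknown atom role", class = "nanocd_validation_error")
  }
  if (any(atoms$mass <= 0 | !is.finite(atoms$mass))) {
    abort("atom masses must be positive and finite",
          class = "nanocd_validation_error")
  }
  ca <- atoms$role == "analyte_calpha"
  if (any(ca & is.na(atoms$analyte_id))) {
    abort("analyte_calpha atoms must carry an analyte_id",
          class = "nanocd_validation_error")
  }
  if (any(ca & atoms$element != "C")) {
    abort("analyte_calpha atoms must be carbon",
          class = "nanocd_validation_error")
  }
  ids <- sort(unique(atoms$analyte_id[!is.na(atoms$analyte_id)]))
  if (length(ids) > 0 && !identical(as.integer(ids), seq_along(ids))) {
    abort("analyte ids must be contiguous starting at 1",
          class = "nanocd_validation_error")
  }
  invisible(atoms)
}

#' Molecular system: atoms plus a periodic box
#'
#' @param atoms Atom table from [atom_table()].
#' @param box Orthorhombic box lengths in nm, length 3, all positive.
#' @param donors Optional donor/hydrogen bonded pairs for hydrogen-bond
#'   analysis: a data frame with integer columns `donor` and `hydrogen`
#'   (atom indices).
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, box, donors = NULL) {
  validate_atoms(atoms)
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    abort("box must be 3 positive lengths (nm)",
          class = "nanocd_validation_error")
  }
  if (!is.null(donors)) {
    donors <- tibble::as_tibble(donors)
    stopifnot(all(c("donor", "hydrogen") %in% names(donors)))
    if (any(atoms$role[donors$hydrogen] != "hydrogen")) {
      abort("donor 'hydrogen' indices must point at hydrogen atoms",
            class = "nanocd_validation_error")
    }
  }
  structure(list(atoms = atoms, box = box, donors = donors),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", nrow(x$atoms), " atoms, box ",
      paste(signif(x$box, 4), collapse = " x "), " nm\n", sep = "")
  print(dplyr::count(x$atoms, .data$role))
  invisible(x)
}

#' Select atom indices by role and analyte
#'
#' @param x A `molecular_system` or `trajectory`.
#' @param roles Character vector of roles to keep (default: all).
#' @param analyte Restrict to this analyte id; `NA` keeps only atoms with
#'   no analyte id; `NULL` (default) does not filter on analyte.
#' @param heavy If `TRUE`, drop hydrogens and solvent.
#' @return Integer atom indices.
#' @export
select_atoms <- function(x, roles = NULL, analyte = NULL, heavy = FALSE) {
  atoms <- if (inherits(x, "trajectory")) x$system$atoms else x$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(roles)) keep <- keep & atoms$role %in% roles
  if (!is.null(analyte)) {
    keep <- keep & if (is.na(analyte)) is.na(atoms$analyte_id) else
      !is.na(atoms$analyte_id) & atoms$analyte_id == analyte
  }
  if (heavy) keep <- keep & !atoms$role %in% c("hydrogen", "solvent")
  which(keep)
}

analyte_ids <- function(x) {
  atoms <- if (inherits(x, "trajectory")) x$system$atoms else x$atoms
  sort(unique(atoms$analyte_id[!is.na(atoms$analyte_id)]))
}
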