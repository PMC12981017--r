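#' Count hydrogen bonds between donors and acceptors in one frame
#'
#' Uses the standard geometric criterion: donor-acceptor distance at most
#' `dist_cutoff` and hydrogen-donor-acceptor angle at most `angle_cutoff`.
#' One bond is counted per satisfying (donor, hydrogen, acceptor) triple.
#' Donor-hydrogen covalent pairs must be declared (via the roles sidecar's
#' `donors` field or the `donors` argument).
#'
#' @param traj A [trajectory()].
#' @param frame_index Frame to evaluate.
#' @param donors A data frame with integer columns `donor` and `hydrogen`
#'   (atom indices); defaults to the pairs declared in the system.
#' @param acceptors Integer indices of acceptor atoms.
#' @param dist_cutoff Donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_cutoff H-donor-acceptor angle cutoff, degrees (default 30).
#' @return Integer hydrogen-bond count.
#' @export
hydrogen_bonds <- function(traj, frame_index, donors = NULL, acceptors,
                           dist_cutoff = 0.35, angle_cutoff = 30) {
  donors <- donors %||% traj$system$donors
  if (is.null(donors) || nrow(donors) == 0) {
    abort("no donor/hydrogen pairs declared",
          class = "nanocd_validation_error")
  }
  donors <- tibble::as_tibble(donors)
  if (!all(c("donor", "hydrogen") %in% names(donors)) ||
      anyNA(donors$hydrogen)) {
    abort("each donor needs a declared bonded hydrogen",
          class = "nanocd_validation_error")
  }
  roles <- traj$system$atoms$role
  if (any(roles[donors$hydrogen] != "hydrogen")) {
    abort("declared hydrogen index is not a hydrogen atom",
          class = "nanocd_validation_error")
  }
  xyz <- frame_coords(traj, frame_index)
  box <- traj$system$box
  n <- 0L
  for (i in seq_len(nrow(donors))) {
    d <- donors$donor[i]; h <- donors$hydrogen[i]
    for (a in setdiff(acceptors, d)) {
      v_da <- mi_disp(xyz[a, ], xyz[d, ], box)
      r_da <- sqrt(sum(v_da^2))
      if (r_da > dist_cutoff) next
      v_dh <- mi_disp(xyz[h, ], xyz[d, ], box)
      cosang <- sum(v_da * v_dh) / (r_da * sqrt(sum(v_dh^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang <= angle_cutoff) n <- n + 1L
    }
  }
  n
}

#' Per-frame hydrogen-bond count series
#'
#' @inheritParams hydrogen_bonds
#' @return Tibble with `frame`, `time_ns`, `hb_count`.
#' @export
hbond_series <- function(traj, donors = NULL, acceptors,
                         dist_cutoff = 0.35, angle_cutoff = 30) {
  tibble::tibble(
    frame = seq_len(n_frames(traj)), time_ns = traj$times,
    hb_count = purrr::map_int(seq_len(n_frames(traj)), hydrogen_bonds,
                              traj = traj, donors = donors,
                              acceptors = acceptors,
                              dist_cutoff = dist_cutoff,
                              angle_cutoff = angle_cutoff)
  )
}

#' Pairwise Coulomb and Lennard-Jones interaction energies
#'
#' Diagnostic interaction energies between two atom groups: a plain
#' cutoff Coulomb sum `f q_i q_j / r` with
#' `f = 138.935 kJ mol^-1 nm e^-2` (relative permittivity 1, no Ewald
#' long-range part) and Lennard-Jones `4 eps [(sigma/r)^12 - (sigma/r)^6]`
#' with Lorentz-Berthelot combination rules (arithmetic-mean sigma,
#' geometric-mean epsilon). Intended as a qualitative diagnostic of which
#' interaction dominates, not a force-field-accurate energy.
#'
#' @param traj A [trajectory()].
#' @param frame_index Frame to evaluate.
#' @param group_a,group_b Integer atom indices.
#' @param cutoff Pair cutoff in nm (default 1.0).
#' @return A tibble with columns `coulomb_kjmol` and `lj_kjmol`.
#' @export
interaction_energies <- function(traj, frame_index, group_a, group_b,
                                 cutoff = 1.0) {
  atoms <- traj$system$atoms
  need <- c(group_a, group_b)
  if (anyNA(atoms$charge[need]) || anyNA(atoms$lj_sigma[need]) ||
      anyNA(atoms$lj_epsilon[need])) {
    abort("charges and LJ parameters required for all atoms in both groups",
          class = "nanocd_validation_error")
  }
  xyz <- frame_coords(traj, frame_index)
  d2 <- cross_dist2(xyz[group_a, , drop = FALSE],
                    xyz[group_b, , drop = FALSE], traj$system$box)
  within <- d2 <= cutoff^2 & d2 > 0
  if (!any(within)) {
    return(tibble::tibble(coulomb_kjmol = 0, lj_kjmol = 0))
  }
  r <- sqrt(d2[within])
  qq <- outer(atoms$charge[group_a], atoms$charge[group_b])[within]
  sig <- outer(atoms$lj_sigma[group_a], atoms$lj_sigma[group_b], "+")[within] / 2
  eps <- sqrt(outer(atoms$lj_epsilon[group_a],
                    atoms$lj_epsilon[group_b]))[within]
  sr6 <- (sig / r)^6
  tibble::tibble(
    coulomb_kjmol = sum(.f_coulomb * qq / r),
    lj_kjmol = sum(4 * eps * (sr6^2 - sr6))
  )
}

#' Per-frame interaction-energy series
#'
#' @inheritParams interaction_energies
#' @return Tibble with `frame`, `time_ns`, `coulomb_kjmol`, `lj_kjmol`.
#' @export
energy_series <- function(traj, group_a, group_b, cutoff = 1.0) {
  purrr::map_dfr(seq_len(n_frames(traj)), function(f) {
    e <- interaction_energies(traj, f, group_a, group_b, cutoff)
    tibble::tibble(frame = f, time_ns = traj$times[f],
                   coulomb_kjmol = e$coulomb_kjmol, lj_kjmol = e$lj_kjmol)
  })
}
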