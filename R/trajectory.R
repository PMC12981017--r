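#' Trajectory: a molecular system with coordinates over time
#'
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in nm. Times
#' are in ns and must be strictly increasing. `replica_id` identifies the
#' independent simulation replica the frames came from.
#'
#' @param system A [molecular_system()].
#' @param coords Numeric array `n_atoms x 3 x n_frames` (nm), or a list of
#'   `n_atoms x 3` matrices (one per frame).
#' @param times Frame times in ns, strictly increasing.
#' @param replica_id Integer replica label (default 1).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(system, coords, times, replica_id = 1L) {
  stopifnot(inherits(system, "molecular_system"))
  if (is.list(coords)) {
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3, length(coords)))
  }
  n_atoms <- nrow(system$atoms)
  if (length(dim(coords)) != 3 || dim(coords)[1] != n_atoms ||
      dim(coords)[2] != 3) {
    abort("coords must be an n_atoms x 3 x n_frames array",
          class = "nanocd_format_error")
  }
  if (any(!is.finite(coords))) {
    abort("all coordinates must be finite", class = "nanocd_validation_error")
  }
  times <- as.numeric(times)
  if (length(times) != dim(coords)[3]) {
    abort("length(times) must equal the number of frames",
          class = "nanocd_validation_error")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("times must be strictly increasing",
          class = "nanocd_validation_error")
  }
  structure(list(system = system, coords = coords, times = times,
                 replica_id = as.integer(replica_id)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames, ",
      nrow(x$system$atoms), " atoms, t = [",
      signif(min(x$times), 4), ", ", signif(max(x$times), 4),
      "] ns, replica ", x$replica_id, "\n", sep = "")
  invisible(x)
}

#' @export
n_frames <- function(traj) UseMethod("n_frames")

#' @export
n_frames.trajectory <- function(traj) dim(traj$coords)[3]

frame_coords <- function(traj, frame_index) {
  nf <- n_frames(traj)
  if (frame_index < 1 || frame_index > nf) {
    abort(sprintf("frame_index %d out of range [1, %d]", frame_index, nf),
          class = "nanocd_validation_error")
  }
  traj$coords[, , frame_index, drop = FALSE][, , 1]
}

#' Discard the equilibration portion of a trajectory
#'
#' Drops every frame with time at or below `t_cut`, mirroring the standard
#' practice of discarding the initial equilibration window (100 ns by
#' default in the pipeline configuration) before computing statistics.
#'
#' @param traj A [trajectory()].
#' @param t_cut Equilibration cutoff in ns (frames with `time > t_cut` are
#'   retained).
#' @return A trajectory with the remaining frames; `replica_id` preserved.
#' @export
discard_equilibration <- function(traj, t_cut) {
  stopifnot(inherits(traj, "trajectory"), t_cut >= 0)
  keep <- traj$times > t_cut
  if (!any(keep)) {
    abort("all frames fall within the equilibration window",
          class = "nanocd_empty_error")
  }
  trajectory(traj$system, traj$coords[, , keep, drop = FALSE],
             traj$times[keep], traj$replica_id)
}

#' Tidy a trajectory into long per-atom coordinates
#'
#' @param x A trajectory.
#' @param frames Optional frame indices to keep (default all).
#' @param ... Unused.
#' @return A tibble with columns `frame`, `time_ns`, `atom`, `element`,
#'   `role`, `analyte_id`, `x_nm`, `y_nm`, `z_nm`.
#' @export
tidy.trajectory <- function(x, frames = NULL, ...) {
  frames <- frames %||% seq_len(n_frames(x))
  atoms <- x$system$atoms
  purrr::map_dfr(frames, function(f) {
    xyz <- frame_coords(x, f)
    tibble::tibble(
      frame = f, time_ns = x$times[f], atom = seq_len(nrow(atoms)),
      element = atoms$element, role = atoms$role,
      analyte_id = atoms$analyte_id,
      x_nm = xyz[, 1], y_nm = xyz[, 2], z_nm = xyz[, 3]
    )
  })
}
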