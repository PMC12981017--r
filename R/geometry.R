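# Minimum-image convention for orthorhombic boxes. `d` is a displacement
# (vector/matrix/array with the box dimension varying fastest along `dim`).
min_image <- function(d, box_len) d - box_len * round(d / box_len)

# Squared minimum-image distances between two coordinate sets in one frame.
# a: na x 3, b: nb x 3, box: length-3 nm. Returns na x nb matrix (nm^2).
cross_dist2 <- function(a, b, box) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- min_image(outer(a[, k], b[, k], "-"), box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

# Minimum-image displacement between two points (length-3 vectors).
mi_disp <- function(a, b, box) {
  d <- a - b
  d - box * round(d / box)
}

#' Center-of-mass distance between two atom groups
#'
#' Mass-weighted centers of mass are computed for each group (molecules are
#' assumed whole, i.e. not wrapped across the box mid-molecule) and the
#' minimum-image convention is applied to the displacement between the two
#' centers.
#'
#' @param traj A [trajectory()].
#' @param frame_index Frame to evaluate.
#' @param group_a,group_b Integer atom indices (see [select_atoms()]).
#' @return Distance in nm.
#' @export
com_distance <- function(traj, frame_index, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("atom groups must be non-empty", class = "nanocd_selection_error")
  }
  xyz <- frame_coords(traj, frame_index)
  m <- traj$system$atoms$mass
  com <- function(idx) colSums(xyz[idx, , drop = FALSE] * m[idx]) / sum(m[idx])
  sqrt(sum(mi_disp(com(group_a), com(group_b), traj$system$box)^2))
}

#' Per-frame center-of-mass distance series
#'
#' @inheritParams com_distance
#' @return A tibble with columns `frame`, `time_ns`, `com_distance_nm`.
#' @export
com_series <- function(traj, group_a, group_b) {
  tibble::tibble(
    frame = seq_len(n_frames(traj)),
    time_ns = traj$times,
    com_distance_nm = purrr::map_dbl(
      seq_len(n_frames(traj)), com_distance,
      traj = traj, group_a = group_a, group_b = group_b)
  )
}
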