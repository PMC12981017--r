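#' Least-squares superposition onto a reference frame
#'
#' Rigid-body fits every frame onto a reference frame by minimising the
#' RMSD of the selected atoms (Kabsch algorithm: optimal rotation from the
#' SVD of the covariance between centred coordinate sets, with a
#' reflection guard). The fitted rotation/translation is applied to all
#' atoms of the frame. Periodic images are not unwrapped; the selection is
#' assumed whole.
#'
#' @param traj A [trajectory()].
#' @param reference_frame Frame index used as reference (default 1).
#' @param selection Integer atom indices to fit on (>= 3 non-collinear
#'   atoms); default: all nanocluster heavy atoms.
#' @return A trajectory with superposed coordinates.
#' @export
superpose <- function(traj, reference_frame = 1, selection = NULL) {
  selection <- selection %||% select_atoms(traj, roles = .cluster_roles)
  if (length(selection) < 3) {
    abort("superposition needs at least 3 atoms",
          class = "nanocd_degenerate_error")
  }
  ref <- frame_coords(traj, reference_frame)[selection, , drop = FALSE]
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_c)
  sv <- svd(ref0)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30)) {
    abort("selection is collinear; superposition is degenerate",
          class = "nanocd_degenerate_error")
  }
  coords <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    mob <- coords[, , f][selection, , drop = FALSE]
    mob_c <- colMeans(mob)
    R <- kabsch_rotation(sweep(mob, 2, mob_c), ref0)
    coords[, , f] <- sweep(sweep(coords[, , f], 2, mob_c) %*% R, 2,
                           ref_c, "+")
  }
  trajectory(traj$system, coords, traj$times, traj$replica_id)
}

# Optimal rotation R (applied as x %*% R) aligning centred `mob` onto
# centred `ref`, det(R) = +1.
kabsch_rotation <- function(mob, ref) {
  h <- crossprod(mob, ref)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' RMSD between two frames over a selection
#'
#' @param traj A [trajectory()] (already superposed; no fitting is done
#'   here).
#' @param frame_i,frame_j Frame indices.
#' @param selection Integer atom indices (default: all atoms).
#' @return RMSD in nm.
#' @export
frame_rmsd <- function(traj, frame_i, frame_j, selection = NULL) {
  selection <- selection %||% seq_len(nrow(traj$system$atoms))
  a <- frame_coords(traj, frame_i)[selection, , drop = FALSE]
  b <- frame_coords(traj, frame_j)[selection, , drop = FALSE]
  sqrt(sum((a - b)^2) / length(selection))
}

# frames x (3 * n_sel) coordinate matrix for a selection
coord_matrix <- function(traj, selection, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  sub <- traj$coords[selection, , frames, drop = FALSE]
  matrix(aperm(sub, c(3, 1, 2)), nrow = length(frames))
}

#' Principal component analysis of a trajectory
#'
#' Mean-centred PCA of the Cartesian coordinates of the selected atoms
#' (by convention, the heavy atoms of the nanocluster), typically after
#' [superpose()]. Eigenvalues are coordinate variances in nm^2;
#' projections of every frame onto the first two components feed the
#' free-energy landscape.
#'
#' @param traj A superposed [trajectory()].
#' @param selection Integer atom indices; default: nanocluster heavy
#'   atoms.
#' @param mass_weighted Use mass-weighted coordinates (default `FALSE`,
#'   plain Cartesian PCA).
#' @return A `trajectory_pca` object with `eigenvalues`, `components`
#'   (columns are orthonormal directions), and `projections` (tibble with
#'   `frame`, `time_ns`, `PC1`, `PC2`).
#' @export
pca_trajectory <- function(traj, selection = NULL, mass_weighted = FALSE) {
  selection <- selection %||% select_atoms(traj, roles = .cluster_roles)
  if (n_frames(traj) < 3) {
    abort("PCA needs at least 3 frames", class = "nanocd_empty_error")
  }
  x <- coord_matrix(traj, selection)
  if (mass_weighted) {
    w <- sqrt(rep(traj$system$atoms$mass[selection], times = 3))
    x <- sweep(x, 2, w, "*")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  # prcomp divides by n-1; keep that convention for the variances
  eig <- pc$sdev^2
  proj <- tibble::tibble(frame = seq_len(n_frames(traj)),
                         time_ns = traj$times,
                         PC1 = pc$x[, 1],
                         PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0)
  structure(list(eigenvalues = eig, components = pc$rotation,
                 center = pc$center, projections = proj,
                 selection = selection),
            class = "trajectory_pca")
}

#' @export
print.trajectory_pca <- function(x, ...) {
  frac <- x$eigenvalues / sum(x$eigenvalues)
  cat("<trajectory_pca> ", nrow(x$projections), " frames; PC1+PC2 carry ",
      round(100 * sum(frac[1:2]), 1), "% of the variance\n", sep = "")
  invisible(x)
}

#' Tidy PCA projections
#' @param x A `trajectory_pca`.
#' @param ... Unused.
#' @export
tidy.trajectory_pca <- function(x, ...) x$projections

#' One-row PCA summary
#' @param x A `trajectory_pca`.
#' @param ... Unused.
#' @export
glance.trajectory_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(n_frames = nrow(x$projections),
                 total_variance_nm2 = tot,
                 pc1_fraction = x$eigenvalues[1] / tot,
                 pc2_fraction = x$eigenvalues[2] / tot)
}

#' Two-dimensional free-energy landscape on (PC1, PC2)
#'
#' Bins the projections into an `n_bins x n_bins` histogram over the
#' bounding box (padded by 1\%) and converts counts to free energies via
#' Boltzmann inversion, `dG = -ln(h / h_max)` in units of kT, so the
#' densest bin sits at dG = 0. Unvisited bins are flagged (`NA` free
#' energy).
#'
#' @param projections A `trajectory_pca` or a tibble with `PC1`, `PC2`
#'   (and optionally `frame`).
#' @param n_bins Bins per axis (default 32, minimum 2).
#' @param temperature Temperature in K (default 300); only used when
#'   exporting energies in kJ/mol.
#' @return A `fes_landscape` with a `grid` tibble (`pc1_center`,
#'   `pc2_center`, `count`, `delta_g_kT`), bin edges, and a
#'   `frame_assignment` tibble.
#' @export
free_energy_landscape <- function(projections, n_bins = 32,
                                  temperature = 300) {
  if (n_bins < 2) {
    abort("n_bins must be >= 2", class = "nanocd_validation_error")
  }
  if (inherits(projections, "trajectory_pca")) {
    projections <- projections$projections
  }
  stopifnot(all(c("PC1", "PC2") %in% names(projections)))
  if (nrow(projections) < 1) {
    abort("no frames to bin", class = "nanocd_empty_error")
  }
  frame <- projections$frame %||% seq_len(nrow(projections))
  edges <- lapply(c("PC1", "PC2"), function(v) {
    r <- range(projections[[v]])
    pad <- max(diff(r), 1e-12) * 0.01
    seq(r[1] - pad, r[2] + pad, length.out = n_bins + 1)
  })
  b1 <- findInterval(projections$PC1, edges[[1]], all.inside = TRUE)
  b2 <- findInterval(projections$PC2, edges[[2]], all.inside = TRUE)
  counts <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(b1)) counts[b1[i], b2[i]] <- counts[b1[i], b2[i]] + 1L
  h_max <- max(counts)
  centers1 <- (head(edges[[1]], -1) + tail(edges[[1]], -1)) / 2
  centers2 <- (head(edges[[2]], -1) + tail(edges[[2]], -1)) / 2
  grid <- tidyr::expand_grid(bin1 = seq_len(n_bins), bin2 = seq_len(n_bins)) |>
    dplyr::mutate(
      pc1_center = centers1[.data$bin1],
      pc2_center = centers2[.data$bin2],
      count = counts[cbind(.data$bin1, .data$bin2)],
      delta_g_kT = ifelse(.data$count > 0,
                          -log(.data$count / h_max), NA_real_)
    )
  structure(list(
    grid = grid,
    edges = edges,
    temperature = temperature,
    frame_assignment = tibble::tibble(frame = frame, bin1 = b1, bin2 = b2)
  ), class = "fes_landscape")
}

#' @export
print.fes_landscape <- function(x, ...) {
  vis <- sum(x$grid$count > 0)
  cat("<fes_landscape> ", nrow(x$frame_assignment), " frames in ", vis,
      " visited bins; max dG = ",
      round(max(x$grid$delta_g_kT, na.rm = TRUE), 2), " kT\n", sep = "")
  invisible(x)
}

#' Tidy the free-energy grid
#' @param x A `fes_landscape`.
#' @param ... Unused.
#' @export
tidy.fes_landscape <- function(x, ...) x$grid

#' Free energy (kT) of the bin a frame falls in
#' @keywords internal
frame_delta_g <- function(fes, frame) {
  fa <- fes$frame_assignment
  i <- match(frame, fa$frame)
  g <- fes$grid
  g$delta_g_kT[(fa$bin1[i] - 1) * max(g$bin2) + fa$bin2[i]]
}

#' Select frames in the minimum free-energy regions
#'
#' Returns all frames whose landscape bin lies within `depth` kT of the
#' global minimum (dG = 0). At `depth = 0` this is the densest bin(s);
#' the result grows monotonically with depth.
#'
#' @param fes A `fes_landscape`.
#' @param depth Free-energy depth in kT (default 0.5).
#' @return Integer frame ids.
#' @export
select_minimum_frames <- function(fes, depth = 0.5) {
  stopifnot(inherits(fes, "fes_landscape"), depth >= 0)
  g <- fes$grid |> dplyr::filter(!is.na(.data$delta_g_kT),
                                 .data$delta_g_kT <= depth)
  fa <- fes$frame_assignment
  keep <- paste(fa$bin1, fa$bin2) %in% paste(g$bin1, g$bin2)
  sort(fa$frame[keep])
}

#' RMSD-based geometric clustering to representative structures
#'
#' Gromos-style neighbour counting over the pairwise RMSD matrix of the
#' selected atoms (by convention the analyte C-alpha plus the nanocluster
#' heavy atoms, frames already superposed): the frame with the most
#' neighbours within the cutoff seeds a cluster, the cluster is removed,
#' and the procedure repeats. Ties in neighbour count break to the lowest
#' frame index. The representative of each cluster is its centre; its
#' free energy is read from the landscape bin it falls in when `fes` is
#' supplied.
#'
#' @param traj A superposed [trajectory()].
#' @param frame_ids Frames to cluster (e.g. from
#'   [select_minimum_frames()]).
#' @param selection Integer atom indices; default: analyte C-alpha +
#'   nanocluster heavy atoms.
#' @param cutoff RMSD cutoff in Angstrom; the conventional range is
#'   0.6-1.5 (default 1.5).
#' @param fes Optional `fes_landscape` supplying per-representative free
#'   energies.
#' @return A `representative_set` with a `representatives` tibble
#'   (`cluster`, `center_frame`, `size`, `mean_rmsd_A`, `delta_g_kT`) and
#'   a `membership` tibble (`frame`, `cluster`).
#' @export
rmsd_cluster <- function(traj, frame_ids, selection = NULL, cutoff = 1.5,
                         fes = NULL) {
  stopifnot(cutoff > 0)
  if (length(frame_ids) == 0) {
    abort("no frames to cluster", class = "nanocd_empty_error")
  }
  selection <- selection %||% c(select_atoms(traj, roles = "analyte_calpha"),
                                select_atoms(traj, roles = .cluster_roles))
  x <- coord_matrix(traj, selection, frames = frame_ids)
  # pairwise RMSD (Angstrom) from Euclidean distance of flattened coords
  rmsd <- as.matrix(dist(x)) / sqrt(length(selection)) * 10
  adj <- rmsd <= cutoff
  remaining <- seq_along(frame_ids)
  assignment <- integer(length(frame_ids))
  reps <- list()
  k <- 0
  while (length(remaining) > 0) {
    k <- k + 1
    counts <- rowSums(adj[remaining, remaining, drop = FALSE])
    center <- remaining[which.max(counts)]  # which.max: first max, lowest idx
    members <- remaining[adj[center, remaining]]
    assignment[members] <- k
    reps[[k]] <- tibble::tibble(
      cluster = k,
      center_frame = frame_ids[center],
      size = length(members),
      mean_rmsd_A = mean(rmsd[center, members])
    )
    remaining <- setdiff(remaining, members)
  }
  representatives <- dplyr::bind_rows(reps)
  representatives$delta_g_kT <- if (!is.null(fes)) {
    frame_delta_g(fes, representatives$center_frame)
  } else NA_real_
  structure(list(
    representatives = representatives,
    membership = tibble::tibble(frame = frame_ids, cluster = assignment),
    rmsd_cutoff_A = cutoff,
    selection = selection
  ), class = "representative_set")
}

#' @export
print.representative_set <- function(x, ...) {
  cat("<representative_set> ", nrow(x$representatives),
      " cluster(s) at cutoff ", x$rmsd_cutoff_A, " A\n", sep = "")
  print(x$representatives)
  invisible(x)
}

#' Tidy cluster representatives
#' @param x A `representative_set`.
#' @param ... Unused.
#' @export
tidy.representative_set <- function(x, ...) x$representatives

#' One-row clustering summary
#' @param x A `representative_set`.
#' @param ... Unused.
#' @export
glance.representative_set <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$representatives),
                 n_frames = nrow(x$membership),
                 largest_cluster = max(x$representatives$size),
                 rmsd_cutoff_A = x$rmsd_cutoff_A)
}
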