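#' Count analyte-nanocluster heavy-atom contacts in one frame
#'
#' The number of contacts (NOC) is the number of atom pairs within the
#' cutoff between heavy atoms (hydrogens and solvent excluded) of one
#' analyte and heavy atoms of the nanocluster (gold, sulfur, ligand).
#' Distances use the minimum-image convention; the cutoff is inclusive.
#'
#' @param traj A [trajectory()].
#' @param frame_index Frame to evaluate.
#' @param analyte_id Which analyte molecule to count contacts for.
#' @param cutoff Contact cutoff in nm (default 0.6).
#' @return Integer contact count.
#' @export
count_contacts <- function(traj, frame_index, analyte_id, cutoff = 0.6) {
  stopifnot(cutoff > 0)
  if (!analyte_id %in% analyte_ids(traj)) {
    abort(paste0("unknown analyte_id: ", analyte_id),
          class = "nanocd_lookup_error")
  }
  ai <- select_atoms(traj, roles = .analyte_heavy_roles, analyte = analyte_id)
  ci <- select_atoms(traj, roles = .cluster_roles)
  if (length(ai) == 0 || length(ci) == 0) return(0L)
  xyz <- frame_coords(traj, frame_index)
  d2 <- cross_dist2(xyz[ai, , drop = FALSE], xyz[ci, , drop = FALSE],
                    traj$system$box)
  sum(d2 <= cutoff^2)
}

#' Per-frame contact-number series
#'
#' Vectorised over frames (per atom pair, across all frames at once); the
#' result matches calling [count_contacts()] frame by frame.
#'
#' @inheritParams count_contacts
#' @param analyte_id Analyte ids to compute series for (default: all).
#' @return A tibble with columns `replica`, `analyte_id`, `frame`,
#'   `time_ns`, `noc`, carrying the cutoff as an attribute.
#' @export
contact_series <- function(traj, analyte_id = NULL, cutoff = 0.6) {
  stopifnot(cutoff > 0)
  ids <- analyte_id %||% analyte_ids(traj)
  ci <- select_atoms(traj, roles = .cluster_roles)
  nf <- n_frames(traj)
  box <- traj$system$box
  c2 <- cutoff^2
  cl <- traj$coords[ci, , , drop = FALSE]   # nc x 3 x nf
  out <- purrr::map_dfr(ids, function(id) {
    if (!id %in% analyte_ids(traj)) {
      abort(paste0("unknown analyte_id: ", id), class = "nanocd_lookup_error")
    }
    ai <- select_atoms(traj, roles = .analyte_heavy_roles, analyte = id)
    noc <- integer(nf)
    for (a in ai) {
      d2 <- matrix(0, length(ci), nf)
      for (k in 1:3) {
        m <- matrix(cl[, k, , drop = FALSE], nrow = length(ci))
        dk <- min_image(sweep(m, 2, traj$coords[a, k, ], "-"), box[k])
        d2 <- d2 + dk * dk
      }
      noc <- noc + colSums(d2 <= c2)
    }
    tibble::tibble(replica = traj$replica_id, analyte_id = id,
                   frame = seq_len(nf), time_ns = traj$times, noc = noc)
  })
  attr(out, "cutoff_nm") <- cutoff
  out
}

#' Adsorption probability from contact-number series
#'
#' Pools frames across replicas (and analytes, if several are present) and
#' classifies a frame as bound when its NOC strictly exceeds the
#' threshold. The adsorption probability is `P = 100 * N / N_total`
#' percent, where `N` is the number of bound frames and `N_total` the
#' pooled frame count; `P = 100` indicates continuous adsorption across
#' all replicas.
#'
#' @param series A contact-series tibble (from [contact_series()], with at
#'   least columns `noc` and optionally `replica`), or a list of such
#'   tibbles (one per replica).
#' @param threshold Integer NOC threshold; frames with `noc > threshold`
#'   count as bound (default 5, strict inequality).
#' @return A `binding_summary` object; see [tidy.binding_summary()] and
#'   [glance.binding_summary()].
#' @export
adsorption_probability <- function(series, threshold = 5L) {
  if (is.data.frame(series)) series <- list(series)
  tbl <- purrr::imap_dfr(series, function(s, i) {
    stopifnot("noc" %in% names(s))
    if (!"replica" %in% names(s)) s$replica <- i
    s
  })
  if (nrow(tbl) == 0) {
    abort("no frames in contact series", class = "nanocd_empty_error")
  }
  if (any(tbl$noc < 0)) {
    abort("contact counts must be non-negative",
          class = "nanocd_validation_error")
  }
  per_replica <- tbl |>
    dplyr::group_by(.data$replica) |>
    dplyr::summarise(n_bound_frames = sum(.data$noc > threshold),
                     n_total_frames = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(P_percent = round(100 * .data$n_bound_frames /
                                      .data$n_total_frames, 1))
  n_bound <- sum(per_replica$n_bound_frames)
  n_total <- sum(per_replica$n_total_frames)
  structure(list(
    P_percent = round(100 * n_bound / n_total, 1),
    n_bound_frames = n_bound,
    n_total_frames = n_total,
    threshold = as.integer(threshold),
    per_replica = per_replica
  ), class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat("<binding_summary> P = ", x$P_percent, "% (", x$n_bound_frames, "/",
      x$n_total_frames, " frames bound, NOC > ", x$threshold, ")\n",
      sep = "")
  invisible(x)
}

#' Tidy per-replica adsorption probabilities
#' @param x A `binding_summary`.
#' @param ... Unused.
#' @export
tidy.binding_summary <- function(x, ...) x$per_replica

#' One-row adsorption-probability summary
#' @param x A `binding_summary`.
#' @param ... Unused.
#' @export
glance.binding_summary <- function(x, ...) {
  tibble::tibble(P_percent = x$P_percent, n_bound_frames = x$n_bound_frames,
                 n_total_frames = x$n_total_frames, threshold = x$threshold)
}

#' Count analytes bound to the nanocluster core in one frame
#'
#' An analyte counts as bound when its backbone C-alpha atom lies within
#' the cutoff of any inner gold atom. The conventional cutoff range is
#' 1.5-2.5 nm, adjusted to analyte and nanocluster size; values outside
#' that range are allowed but flagged with a warning.
#'
#' @param traj A [trajectory()].
#' @param frame_index Frame to evaluate.
#' @param cutoff C-alpha to inner-gold cutoff in nm (default 2.0).
#' @return Integer number of bound analytes.
#' @export
count_bound_analytes <- function(traj, frame_index, cutoff = 2.0) {
  if (cutoff < 1.5 || cutoff > 2.5) {
    warn(sprintf("bound-analyte cutoff %.2f nm outside the usual 1.5-2.5 nm",
                 cutoff))
  }
  au <- select_atoms(traj, roles = "inner_gold")
  ca <- select_atoms(traj, roles = "analyte_calpha")
  if (length(ca) == 0) {
    abort("no analyte C-alpha atoms in system",
          class = "nanocd_validation_error")
  }
  if (length(au) == 0) {
    abort("no inner gold atoms in system", class = "nanocd_validation_error")
  }
  xyz <- frame_coords(traj, frame_index)
  d2 <- cross_dist2(xyz[ca, , drop = FALSE], xyz[au, , drop = FALSE],
                    traj$system$box)
  sum(apply(d2, 1, min) <= cutoff^2)
}

#' Per-frame bound-analyte count series
#'
#' @inheritParams count_bound_analytes
#' @return Tibble with `frame`, `time_ns`, `n_bound`.
#' @export
bound_count_series <- function(traj, cutoff = 2.0) {
  n <- suppressWarnings(purrr::map_int(seq_len(n_frames(traj)),
                                       count_bound_analytes, traj = traj,
                                       cutoff = cutoff))
  if (cutoff < 1.5 || cutoff > 2.5) {
    warn(sprintf("bound-analyte cutoff %.2f nm outside the usual 1.5-2.5 nm",
                 cutoff))
  }
  tibble::tibble(frame = seq_len(n_frames(traj)), time_ns = traj$times,
                 n_bound = n)
}

#' Convert mean bound-analyte counts to a binding probability
#'
#' In multi-analyte (concentration-effect) simulations the binding
#' probability is the mean number of simultaneously bound analytes divided
#' by the number of analytes in the box, as a percent rounded to the
#' nearest integer. For example, mean counts 6.4 and 6.6 of 10 analytes
#' give P = 65\%.
#'
#' @param mean_counts Mean bound-analyte counts (e.g. one per enantiomer
#'   or replica); each must not exceed `n_analytes`.
#' @param n_analytes Number of analytes in the box.
#' @return Integer percent.
#' @export
mean_bound_to_probability <- function(mean_counts, n_analytes) {
  stopifnot(n_analytes >= 1)
  if (any(mean_counts < 0) || any(mean_counts > n_analytes)) {
    abort("mean bound counts must lie in [0, n_analytes]",
          class = "nanocd_validation_error")
  }
  round(100 * mean(mean_counts) / n_analytes)
}

#' Spherical ligand-packing prediction
#'
#' For constant ligand surface density, the ligand count of a nanocluster
#' with `N` gold atoms should scale as the 2/3 power of the gold count
#' relative to a smaller cluster: `(N_large / N_small)^(2/3)`. Comparing
#' this prediction with [actual_ligand_ratio()] quantifies how ligand
#' density grows as the surface curvature decreases.
#'
#' Ratios are reported truncated to 2 decimals alongside the exact
#' value, following the truncation convention of the printed comparison
#' values (e.g. 144 vs 102 gold atoms predicts 1.2585, reported as
#' 1.25).
#'
#' @param n_gold_large,n_gold_small Gold atom counts of the two clusters.
#' @return A tibble with the reported (2-decimal) and exact ratio.
#' @export
ligand_ratio_model <- function(n_gold_large, n_gold_small) {
  if (n_gold_large < 1 || n_gold_small < 1) {
    abort("gold counts must be >= 1", class = "nanocd_validation_error")
  }
  exact <- (n_gold_large / n_gold_small)^(2 / 3)
  tibble::tibble(predicted_ratio = trunc2(exact), exact = exact)
}

# truncate to 2 decimals (with a guard against binary representation of
# exact decimal values landing a hair below the integer)
trunc2 <- function(x) trunc(100 * x + 1e-6) / 100

#' Observed ligand-count ratio
#'
#' @param n_ligands_large,n_ligands_small Ligand counts of the two
#'   clusters.
#' @return A tibble with the exact quotient and the value rounded to 2
#'   decimals.
#' @export
actual_ligand_ratio <- function(n_ligands_large, n_ligands_small) {
  if (n_ligands_large < 1 || n_ligands_small < 1) {
    abort("ligand counts must be >= 1", class = "nanocd_validation_error")
  }
  exact <- n_ligands_large / n_ligands_small
  tibble::tibble(actual_ratio = trunc2(exact), exact = exact)
}
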