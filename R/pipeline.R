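#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis chain with the
#' conventional defaults: 0.6 nm heavy-atom contact cutoff, NOC
#' threshold 5 (strict), 100 ns equilibration, 2.0 nm C-alpha/inner-gold
#' cutoff (midpoint of the customary 1.5-2.5 nm range), 400 ns PCA
#' window, 32x32 landscape bins, 0.5 kT minimum-region depth, 1.5
#' Angstrom RMSD clustering cutoff, 300 K, 4.0 Angstrom analyte
#' inclusion threshold, and a 300-600 nm sensing band.
#'
#' @param contact_cutoff_nm Heavy-atom contact cutoff (nm).
#' @param noc_threshold Bound-frame NOC threshold (strict `>`).
#' @param equilibration_ns Equilibration window to discard (ns).
#' @param bound_calpha_cutoff_nm C-alpha to inner-gold cutoff (nm).
#' @param pca_window_ns Analysis window measured back from the end of
#'   the trajectory (ns); `Inf` uses all post-equilibration frames.
#' @param fes_bins Free-energy-landscape bins per axis.
#' @param fes_depth_kT Minimum-region depth (kT).
#' @param rmsd_cutoff_A Clustering RMSD cutoff (Angstrom).
#' @param temperature_K Temperature (K).
#' @param inclusion_threshold_A Analyte-inclusion distance (Angstrom).
#' @param band_nm Sensing wavelength band (nm).
#' @param noise_floor_frac Sign-region noise floor as a fraction of the
#'   maximum absolute difference.
#' @param detectability_threshold Score above which the binding-sensing
#'   call is "Y".
#' @param enantio_threshold Score above which the enantiodiscrimination
#'   call is "Y".
#' @param seed Integer seed recorded in reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(contact_cutoff_nm = 0.6,
                            noc_threshold = 5L,
                            equilibration_ns = 100,
                            bound_calpha_cutoff_nm = 2.0,
                            pca_window_ns = 400,
                            fes_bins = 32L,
                            fes_depth_kT = 0.5,
                            rmsd_cutoff_A = 1.5,
                            temperature_K = 300,
                            inclusion_threshold_A = 4.0,
                            band_nm = c(300, 600),
                            noise_floor_frac = 0.05,
                            detectability_threshold = 0.05,
                            enantio_threshold = 0.1,
                            seed = 1L) {
  cfg <- list(contact_cutoff_nm = contact_cutoff_nm,
              noc_threshold = as.integer(noc_threshold),
              equilibration_ns = equilibration_ns,
              bound_calpha_cutoff_nm = bound_calpha_cutoff_nm,
              pca_window_ns = pca_window_ns,
              fes_bins = as.integer(fes_bins),
              fes_depth_kT = fes_depth_kT,
              rmsd_cutoff_A = rmsd_cutoff_A,
              temperature_K = temperature_K,
              inclusion_threshold_A = inclusion_threshold_A,
              band_nm = band_nm,
              noise_floor_frac = noise_floor_frac,
              detectability_threshold = detectability_threshold,
              enantio_threshold = enantio_threshold,
              seed = as.integer(seed))
  if (any(c(cfg$contact_cutoff_nm, cfg$bound_calpha_cutoff_nm,
            cfg$rmsd_cutoff_A, cfg$inclusion_threshold_A,
            cfg$temperature_K) <= 0) || cfg$equilibration_ns < 0) {
    abort("cutoffs and temperature must be positive",
          class = "nanocd_validation_error")
  }
  if (band_nm[1] >= band_nm[2]) {
    abort("band_nm must be an increasing interval",
          class = "nanocd_validation_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat("  ", format(nm, width = 24), paste(x[[nm]], collapse = ", "), "\n")
  }
  invisible(x)
}

as_trajectory_input <- function(x) {
  if (inherits(x, "trajectory")) return(x)
  if (is.list(x) && !is.null(x$structure) && !is.null(x$roles)) {
    return(read_trajectory(x$structure, x$roles))
  }
  abort("trajectory inputs must be trajectory objects or lists with $structure and $roles paths",
        class = "nanocd_validation_error")
}

#' Run the binding-analysis stage over replicas
#'
#' Reads (or accepts) one trajectory per replica, discards the
#' equilibration window, computes per-analyte contact-number series and
#' the pooled adsorption probability, and (for multi-analyte systems)
#' the bound-analyte count series and the mean-count binding
#' probability.
#'
#' @param config A [pipeline_config()].
#' @param trajectories A list of [trajectory()] objects or of lists with
#'   `$structure` and `$roles` file paths (one per replica).
#' @return A `binding_report`: `summary` ([adsorption_probability()]
#'   result pooled over replicas and analytes), `per_analyte` tibble,
#'   `series` (per-frame tibble), `bound_counts` (multi-analyte only),
#'   `mean_bound_probability_percent`, and the resolved `config`.
#' @export
run_binding <- function(config = pipeline_config(), trajectories) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(trajectories, "trajectory")) {
    trajectories <- list(trajectories)
  }
  trajs <- purrr::map(trajectories, as_trajectory_input)
  trajs <- purrr::imap(trajs, function(tr, i) {
    tr$replica_id <- tr$replica_id %||% i
    discard_equilibration(tr, config$equilibration_ns)
  })
  series <- purrr::map_dfr(trajs, contact_series,
                           cutoff = config$contact_cutoff_nm)
  summary <- adsorption_probability(series,
                                    threshold = config$noc_threshold)
  per_analyte <- series |>
    dplyr::group_by(.data$analyte_id) |>
    dplyr::summarise(
      n_bound_frames = sum(.data$noc > config$noc_threshold),
      n_total_frames = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(P_percent = round(100 * .data$n_bound_frames /
                                      .data$n_total_frames, 1))
  n_analytes <- length(analyte_ids(trajs[[1]]))
  bound_counts <- NULL
  mean_bound_p <- NULL
  if (n_analytes > 1) {
    bound_counts <- purrr::imap_dfr(trajs, function(tr, i) {
      dplyr::mutate(bound_count_series(
        tr, cutoff = config$bound_calpha_cutoff_nm),
        replica = tr$replica_id)
    })
    mean_bound_p <- mean_bound_to_probability(mean(bound_counts$n_bound),
                                              n_analytes)
  }
  structure(list(summary = summary, per_analyte = per_analyte,
                 series = series, bound_counts = bound_counts,
                 mean_bound_probability_percent = mean_bound_p,
                 n_analytes = n_analytes, config = config),
            class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  cat("<binding_report> pooled P = ", x$summary$P_percent, "% over ",
      x$summary$n_total_frames, " frames (", x$n_analytes,
      " analyte(s))\n", sep = "")
  if (!is.null(x$mean_bound_probability_percent)) {
    cat("  mean bound-count probability: ",
        x$mean_bound_probability_percent, "%\n", sep = "")
  }
  invisible(x)
}

#' Run the conformational-sampling stage
#'
#' Superposes the trajectory on the nanocluster heavy atoms, restricts
#' to the configured analysis window, performs PCA, builds the
#' free-energy landscape, selects minimum-region frames and clusters
#' them by RMSD into representative structures.
#'
#' @param config A [pipeline_config()].
#' @param traj A [trajectory()] (equilibration not yet discarded).
#' @return A `sampling_report` with `pca`, `fes`, `minimum_frames`,
#'   `representatives` and the resolved `config`.
#' @export
run_sampling <- function(config = pipeline_config(), traj) {
  stopifnot(inherits(config, "pipeline_config"))
  traj <- as_trajectory_input(traj)
  t_end <- max(traj$times)
  t_start <- max(config$equilibration_ns, t_end - config$pca_window_ns)
  traj <- discard_equilibration(traj, min(t_start, t_end - 1e-9))
  traj <- superpose(traj)
  pca <- pca_trajectory(traj)
  fes <- free_energy_landscape(pca, n_bins = config$fes_bins,
                               temperature = config$temperature_K)
  frames <- select_minimum_frames(fes, depth = config$fes_depth_kT)
  reps <- rmsd_cluster(traj, frames, cutoff = config$rmsd_cutoff_A,
                       fes = fes)
  structure(list(pca = pca, fes = fes, minimum_frames = frames,
                 representatives = reps, trajectory = traj,
                 config = config),
            class = "sampling_report")
}

#' Run the spectral-sensing stage
#'
#' Forms Boltzmann-weighted average spectra for the bare nanocluster and
#' both enantiomer hybrids, computes the hybrid-minus-bare difference
#' spectra, scores binding detectability and enantiodiscrimination over
#' the configured band, and issues Table-style Y/N calls at the
#' configured thresholds (SB: does binding change the spectrum; SE: do
#' the enantiomers differ).
#'
#' @param config A [pipeline_config()].
#' @param hybrid_L,hybrid_D [weighted_ensemble()]s of
#'   nanocluster-analyte hybrid spectra for the two enantiomers.
#' @param bare A [weighted_ensemble()] of bare-nanocluster spectra.
#' @return A `sensing_report` with the average spectra, difference
#'   spectra, a one-row `scores` tibble (including `SB_call` and
#'   `SE_call`), and the resolved `config`.
#' @export
run_sensing <- function(config = pipeline_config(), hybrid_L, hybrid_D,
                        bare) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(hybrid_D) || is.null(hybrid_D)) {
    abort("enantiodiscrimination requires both enantiomer ensembles",
          class = "nanocd_validation_error")
  }
  avg <- list(L = weighted_average_spectrum(hybrid_L),
              D = weighted_average_spectrum(hybrid_D),
              bare = weighted_average_spectrum(bare))
  diff_L <- difference_spectrum(avg$L, avg$bare,
                                noise_floor_frac = config$noise_floor_frac,
                                band = config$band_nm)
  diff_D <- difference_spectrum(avg$D, avg$bare,
                                noise_floor_frac = config$noise_floor_frac,
                                band = config$band_nm)
  scores <- sensing_scores(diff_L, diff_D, band = config$band_nm)
  scores$SB_call <- ifelse(
    scores$binding_detectability >= config$detectability_threshold, "Y", "N")
  scores$SE_call <- ifelse(
    scores$SB_call == "Y" &
      scores$enantiodiscrimination >= config$enantio_threshold, "Y", "N")
  structure(list(averages = avg, diff_L = diff_L, diff_D = diff_D,
                 scores = scores, config = config),
            class = "sensing_report")
}

#' @export
print.sensing_report <- function(x, ...) {
  cat("<sensing_report> detectability = ",
      signif(x$scores$binding_detectability, 3),
      " (SB ", x$scores$SB_call, "), enantiodiscrimination = ",
      signif(x$scores$enantiodiscrimination, 3),
      " (SE ", x$scores$SE_call, ")\n", sep = "")
  invisible(x)
}

#' Tidy sensing scores
#' @param x A `sensing_report`.
#' @param ... Unused.
#' @export
tidy.sensing_report <- function(x, ...) x$scores

#' Write a report's tables and resolved configuration to a directory
#'
#' @param report A `binding_report` or `sensing_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(report$config))
  if (inherits(report, "binding_report")) {
    readr::write_tsv(report$series, file.path(dir, "contact_series.tsv"))
    if (!is.null(report$bound_counts)) {
      readr::write_tsv(report$bound_counts,
                       file.path(dir, "bound_counts.tsv"))
    }
    manifest$P_percent <- report$summary$P_percent
    manifest$per_replica <- report$summary$per_replica
    manifest$per_analyte <- report$per_analyte
    manifest$mean_bound_probability_percent <-
      report$mean_bound_probability_percent
  } else if (inherits(report, "sensing_report")) {
    write_spectrum(report$averages$L, file.path(dir, "hybrid_L_avg.csv"))
    write_spectrum(report$averages$D, file.path(dir, "hybrid_D_avg.csv"))
    write_spectrum(report$averages$bare, file.path(dir, "bare_avg.csv"))
    readr::write_tsv(tidy(report$diff_L), file.path(dir, "diff_L.tsv"))
    readr::write_tsv(tidy(report$diff_D), file.path(dir, "diff_D.tsv"))
    manifest$scores <- report$scores
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
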