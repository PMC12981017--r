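#' Analytes close enough to the nanocluster to perturb its spectrum
#'
#' Returns the ids of analyte molecules whose minimum any-atom distance
#' (hydrogens included) to any nanocluster atom is strictly below the
#' threshold. This is the inclusion rule deciding which analytes enter a
#' hybrid spectrum calculation.
#'
#' @param traj A [trajectory()].
#' @param frame_index Frame to evaluate.
#' @param threshold Distance threshold in Angstrom (default 4.0).
#' @return Sorted integer analyte ids (possibly empty).
#' @export
analyte_inclusion <- function(traj, frame_index, threshold = 4.0) {
  thr_nm <- threshold / 10
  atoms <- traj$system$atoms
  cluster <- which(is.na(atoms$analyte_id) & atoms$role != "solvent")
  xyz <- frame_coords(traj, frame_index)
  box <- traj$system$box
  keep <- purrr::keep(analyte_ids(traj), function(id) {
    ai <- which(!is.na(atoms$analyte_id) & atoms$analyte_id == id)
    d2 <- cross_dist2(xyz[ai, , drop = FALSE],
                      xyz[cluster, , drop = FALSE], box)
    min(d2) < thr_nm^2
  })
  sort(keep)
}

#' Boltzmann weights from conformational free energies
#'
#' `w_i = exp(-dG_i) / sum_j exp(-dG_j)` for free energies in kT units
#' (or in kJ/mol, converted at the given temperature). Computed stably by
#' shifting by the minimum free energy, which leaves the weights
#' unchanged.
#'
#' @param delta_g Per-structure conformational free energies.
#' @param temperature Temperature in K (default 300; only used for
#'   kJ/mol input).
#' @param units `"kT"` (default) or `"kJ/mol"`.
#' @return Numeric weights summing to 1.
#' @export
boltzmann_weights <- function(delta_g, temperature = 300,
                              units = c("kT", "kJ/mol")) {
  units <- match.arg(units)
  if (length(delta_g) == 0) {
    abort("no free energies supplied", class = "nanocd_empty_error")
  }
  if (any(!is.finite(delta_g))) {
    abort("free energies must be finite", class = "nanocd_validation_error")
  }
  g <- if (units == "kJ/mol") delta_g / (.kB_kJmol * temperature) else delta_g
  w <- exp(-(g - min(g)))
  w / sum(w)
}

#' A Boltzmann-weighted spectrum ensemble
#'
#' Bundles per-conformation CD spectra with their conformational free
#' energies and the resulting normalized Boltzmann weights.
#'
#' @param spectra A list of [cd_spectrum()] objects.
#' @param delta_g_kT Free energies in kT, one per spectrum.
#' @param temperature Temperature in K (default 300).
#' @return A `weighted_ensemble` object.
#' @export
weighted_ensemble <- function(spectra, delta_g_kT, temperature = 300) {
  if (length(spectra) == 0) {
    abort("ensemble needs at least one spectrum",
          class = "nanocd_empty_error")
  }
  if (length(spectra) != length(delta_g_kT)) {
    abort("one free energy per spectrum required",
          class = "nanocd_validation_error")
  }
  structure(list(
    spectra = spectra,
    delta_g_kT = as.numeric(delta_g_kT),
    weights = boltzmann_weights(delta_g_kT, temperature),
    temperature = temperature
  ), class = "weighted_ensemble")
}

#' @export
print.weighted_ensemble <- function(x, ...) {
  cat("<weighted_ensemble> ", length(x$spectra), " spectra; weights ",
      paste(signif(x$weights, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy ensemble weights
#' @param x A `weighted_ensemble`.
#' @param ... Unused.
#' @export
tidy.weighted_ensemble <- function(x, ...) {
  tibble::tibble(
    spectrum = purrr::map_chr(seq_along(x$spectra), function(i) {
      attr(x$spectra[[i]], "label") %||% as.character(i)
    }),
    delta_g_kT = x$delta_g_kT,
    weight = x$weights
  )
}

# Common wavelength grid: union of all sample points inside the
# intersection of the spectral ranges.
common_grid <- function(spectra) {
  lo <- max(purrr::map_dbl(spectra, ~ min(.x$wavelength_nm)))
  hi <- min(purrr::map_dbl(spectra, ~ max(.x$wavelength_nm)))
  if (lo >= hi) {
    abort("spectra have no overlapping wavelength range",
          class = "nanocd_grid_error")
  }
  grid <- sort(unique(unlist(purrr::map(spectra, "wavelength_nm"))))
  grid[grid >= lo & grid <= hi]
}

resample_spectrum <- function(spectrum, grid) {
  approx(spectrum$wavelength_nm, spectrum$intensity, xout = grid,
         rule = 1)$y
}

#' Boltzmann-weighted ensemble-average spectrum
#'
#' Resamples every spectrum onto the common wavelength grid (linear
#' interpolation on the intersection of ranges; no extrapolation) and
#' takes the pointwise weighted mean.
#'
#' @param ensemble A [weighted_ensemble()].
#' @return A [cd_spectrum()].
#' @export
weighted_average_spectrum <- function(ensemble) {
  stopifnot(inherits(ensemble, "weighted_ensemble"))
  grid <- common_grid(ensemble$spectra)
  mat <- vapply(ensemble$spectra, resample_spectrum, numeric(length(grid)),
                grid = grid)
  cd_spectrum(grid, as.vector(mat %*% ensemble$weights),
              label = "weighted_average")
}

#' Hybrid-minus-bare difference spectrum
#'
#' The sensing signal: the Boltzmann-weighted average spectrum of the
#' nanocluster-analyte hybrid minus that of the bare nanocluster, on
#' their common wavelength grid. Contiguous sign regions above a noise
#' floor (a fraction of the maximum absolute difference) are annotated as
#' positive/negative contributions relative to the bare reference.
#'
#' @param hybrid_avg,bare_avg [cd_spectrum()] averages.
#' @param noise_floor_frac Noise floor as a fraction of `max(abs(delta))`
#'   (default 0.05).
#' @param band Wavelength band of interest in nm (default `c(300, 600)`).
#' @return A `difference_spectrum` with `data` (tibble `wavelength_nm`,
#'   `delta`, `hybrid`, `bare`), `positive_regions`, `negative_regions`
#'   tibbles of wavelength intervals, `band` and `noise_floor`.
#' @export
difference_spectrum <- function(hybrid_avg, bare_avg,
                                noise_floor_frac = 0.05,
                                band = c(300, 600)) {
  grid <- common_grid(list(hybrid_avg, bare_avg))
  hy <- resample_spectrum(hybrid_avg, grid)
  ba <- resample_spectrum(bare_avg, grid)
  delta <- hy - ba
  floor_abs <- noise_floor_frac * max(abs(delta), 0)
  regions <- function(keep) {
    if (!any(keep)) {
      return(tibble::tibble(from_nm = numeric(), to_nm = numeric()))
    }
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    tibble::tibble(from_nm = grid[starts[r$values]],
                   to_nm = grid[ends[r$values]])
  }
  structure(list(
    data = tibble::tibble(wavelength_nm = grid, delta = delta,
                          hybrid = hy, bare = ba),
    positive_regions = regions(delta > floor_abs & floor_abs > 0),
    negative_regions = regions(delta < -floor_abs & floor_abs > 0),
    band = band,
    noise_floor = floor_abs
  ), class = "difference_spectrum")
}

#' @export
print.difference_spectrum <- function(x, ...) {
  cat("<difference_spectrum> ", nrow(x$data), " points; ",
      nrow(x$positive_regions), " positive / ",
      nrow(x$negative_regions), " negative region(s)\n", sep = "")
  invisible(x)
}

#' Tidy a difference spectrum
#' @param x A `difference_spectrum`.
#' @param ... Unused.
#' @export
tidy.difference_spectrum <- function(x, ...) x$data

# Trapezoidal integral of y over x restricted to [band[1], band[2]]
band_integral <- function(x, y, band) {
  keep <- x >= band[1] & x <= band[2]
  if (sum(keep) < 2) {
    abort("band of interest not covered by the spectral grid",
          class = "nanocd_validation_error")
  }
  xs <- x[keep]; ys <- y[keep]
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Binding-detectability and enantiodiscrimination scores
#'
#' Scores a pair of enantiomer difference spectra over the band of
#' interest. Binding detectability is the band-integrated absolute
#' difference signal, averaged over the two enantiomers and normalised by
#' the band-integrated absolute bare spectrum (0 when the hybrid equals
#' the bare reference). Enantiodiscrimination is
#' `int |delta_L - delta_D| / (int |delta_L| + int |delta_D|)`: 0 when the
#' enantiomer responses are identical, 1 when they are opposite or
#' disjoint.
#'
#' @param diff_L,diff_D [difference_spectrum()] objects for the L and D
#'   enantiomers (sharing the bare reference).
#' @param band Wavelength band in nm; defaults to the band stored in
#'   `diff_L`.
#' @return One-row tibble with `binding_detectability` and
#'   `enantiodiscrimination`.
#' @export
sensing_scores <- function(diff_L, diff_D, band = NULL) {
  stopifnot(inherits(diff_L, "difference_spectrum"),
            inherits(diff_D, "difference_spectrum"))
  band <- band %||% diff_L$band
  if (band[1] >= band[2]) {
    abort("band must be an increasing interval",
          class = "nanocd_validation_error")
  }
  grid <- intersect(diff_L$data$wavelength_nm, diff_D$data$wavelength_nm)
  dl <- diff_L$data$delta[match(grid, diff_L$data$wavelength_nm)]
  dd <- diff_D$data$delta[match(grid, diff_D$data$wavelength_nm)]
  bare <- diff_L$data$bare[match(grid, diff_L$data$wavelength_nm)]
  int_l <- band_integral(grid, abs(dl), band)
  int_d <- band_integral(grid, abs(dd), band)
  int_bare <- band_integral(grid, abs(bare), band)
  int_gap <- band_integral(grid, abs(dl - dd), band)
  tibble::tibble(
    binding_detectability = if (int_bare > 0)
      (int_l + int_d) / 2 / int_bare else (int_l + int_d) / 2,
    enantiodiscrimination = if (int_l + int_d > 0)
      int_gap / (int_l + int_d) else 0
  )
}
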