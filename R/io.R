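#' Read a trajectory from a structure file and a roles sidecar
#'
#' The structure file is either a multi-frame XYZ file (blocks of
#' `n_atoms` / comment / `element x y z`, coordinates in Angstrom) or a
#' multi-model PDB (read through bio3d). Atom roles, the periodic box, and
#' optional charges/Lennard-Jones parameters come from a JSON sidecar,
#' because role distinctions (inner vs surface gold, ligand vs analyte)
#' are not encodable in coordinate formats. Internally everything is in nm
#' and ns.
#'
#' @param structure_path Path to a `.xyz` or `.pdb` file.
#' @param roles_path Path to the JSON sidecar (see Details).
#' @return A [trajectory()].
#' @details The sidecar is a JSON object with fields `box_nm` (3 lengths),
#'   optional `replica_id`, `atoms` (array of objects with `role` and
#'   optional `analyte_id`, `charge`, `lj_sigma`, `lj_epsilon`, `mass`,
#'   in file atom order) and optional `donors` (array of
#'   `{donor, hydrogen}` 1-based index pairs for hydrogen-bond analysis).
#' @export
read_trajectory <- function(structure_path, roles_path) {
  if (!file.exists(structure_path)) {
    abort(paste0("structure file not found: ", structure_path),
          class = "nanocd_io_error")
  }
  if (!file.exists(roles_path)) {
    abort(paste0("roles sidecar not found: ", roles_path),
          class = "nanocd_io_error")
  }
  sidecar <- jsonlite::fromJSON(roles_path, simplifyDataFrame = TRUE)
  if (is.null(sidecar$box_nm)) {
    abort("roles sidecar is missing box_nm", class = "nanocd_validation_error")
  }
  ext <- tolower(tools::file_ext(structure_path))
  parsed <- switch(ext,
    xyz = read_xyz_frames(structure_path),
    pdb = read_pdb_frames(structure_path),
    abort(paste0("unsupported structure format: .", ext),
          class = "nanocd_format_error")
  )
  at <- sidecar$atoms
  if (is.null(at)) {
    abort("roles sidecar is missing the atoms array",
          class = "nanocd_validation_error")
  }
  at <- tibble::as_tibble(at)
  if (nrow(at) != nrow(parsed$elements_frame)) {
    abort("sidecar atom count does not match the structure file",
          class = "nanocd_format_error")
  }
  col <- function(nm, default) {
    if (nm %in% names(at)) at[[nm]] else rep(default, nrow(at))
  }
  atoms <- atom_table(
    element = parsed$elements_frame$element,
    role = at$role,
    analyte_id = col("analyte_id", NA_integer_),
    charge = col("charge", NA_real_),
    lj_sigma = col("lj_sigma", NA_real_),
    lj_epsilon = col("lj_epsilon", NA_real_),
    mass = if ("mass" %in% names(at) && !anyNA(at$mass)) at$mass else NULL
  )
  donors <- if (!is.null(sidecar$donors)) tibble::as_tibble(sidecar$donors)
  sys <- molecular_system(atoms, sidecar$box_nm, donors = donors)
  trajectory(sys, parsed$coords, parsed$times,
             replica_id = sidecar$replica_id %||% 1L)
}

# Multi-frame XYZ parser. Coordinates in Angstrom (converted to nm); frame
# times taken from a "time_ns= <t>" token on the comment line when present.
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  i <- 1
  frames <- list(); times <- numeric(); elements <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0) {
      abort(sprintf("bad atom-count line at line %d of %s", i, path),
            class = "nanocd_format_error")
    }
    if (i + 1 + n > length(lines)) {
      abort("truncated XYZ frame", class = "nanocd_format_error")
    }
    comment <- lines[i + 1]
    body <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    if (any(lengths(toks) < 4)) {
      abort("XYZ atom lines need: element x y z", class = "nanocd_format_error")
    }
    el <- vapply(toks, `[[`, "", 1)
    xyz <- matrix(suppressWarnings(as.numeric(
      t(vapply(toks, function(t) t[2:4], character(3))))), ncol = 3,
      byrow = FALSE)
    if (anyNA(xyz)) {
      abort("non-numeric coordinate in XYZ file", class = "nanocd_format_error")
    }
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      abort("frames disagree on atom count", class = "nanocd_format_error")
    }
    frames[[length(frames) + 1]] <- xyz / 10  # Angstrom -> nm
    tm <- regmatches(comment,
                     regexpr("time_ns=\\s*[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm) == 1)
      as.numeric(sub("time_ns=\\s*", "", tm)) else NA_real_)
    i <- i + 2 + n
  }
  if (anyNA(times)) times <- seq_along(frames) - 1
  list(elements_frame = tibble::tibble(element = elements),
       coords = array(unlist(frames), dim = c(length(elements), 3,
                                              length(frames))),
       times = times)
}

read_pdb_frames <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB requires the bio3d package",
          class = "nanocd_io_error")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                      # n_models x 3n matrix, Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n <- ncol(xyz) / 3
  coords <- array(0, dim = c(n, 3, nrow(xyz)))
  for (f in seq_len(nrow(xyz))) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  }
  el <- pdb$atom$elesy
  if (is.null(el) || all(!nzchar(trimws(el)))) el <- pdb$atom$elety
  list(elements_frame = tibble::tibble(element = trimws(el)),
       coords = coords, times = seq_len(nrow(xyz)) - 1)
}

#' Write a trajectory as multi-frame XYZ plus a roles sidecar
#'
#' @param traj A [trajectory()].
#' @param structure_path Output `.xyz` path (coordinates written in
#'   Angstrom, 4 decimals).
#' @param roles_path Optional output path for the JSON sidecar.
#' @return Invisibly, the structure path.
#' @export
write_trajectory <- function(traj, structure_path, roles_path = NULL) {
  atoms <- traj$system$atoms
  con <- file(structure_path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f) * 10   # nm -> Angstrom
    writeLines(as.character(nrow(atoms)), con)
    writeLines(sprintf("frame %d time_ns= %.6f", f, traj$times[f]), con)
    writeLines(sprintf("%-3s %12.4f %12.4f %12.4f", atoms$element,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  if (!is.null(roles_path)) write_roles_sidecar(traj, roles_path)
  invisible(structure_path)
}

write_roles_sidecar <- function(traj, roles_path) {
  atoms <- traj$system$atoms
  sidecar <- list(
    box_nm = traj$system$box,
    replica_id = traj$replica_id,
    atoms = atoms[, c("role", "analyte_id", "charge", "lj_sigma",
                      "lj_epsilon", "mass")]
  )
  if (!is.null(traj$system$donors)) sidecar$donors <- traj$system$donors
  jsonlite::write_json(sidecar, roles_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(roles_path)
}

#' Write one frame as a single-model PDB
#'
#' Used to export representative structures selected by the sampling chain.
#'
#' @param traj A [trajectory()].
#' @param frame_index Frame to write.
#' @param path Output path.
#' @export
write_frame_pdb <- function(traj, frame_index, path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("writing PDB requires the bio3d package", class = "nanocd_io_error")
  }
  xyz <- as.vector(t(frame_coords(traj, frame_index))) * 10
  el <- traj$system$atoms$element
  bio3d::write.pdb(file = path, xyz = xyz, elety = el, resno = rep(1,
                   length(el)), resid = rep("MOL", length(el)),
                   elesy = el)
  invisible(path)
}

#' Read a CD spectrum from a two-column CSV
#'
#' Expects columns wavelength (nm) then intensity; a header row is
#' optional. Wavelengths are sorted ascending (with a warning) if needed;
#' duplicate wavelengths are an error.
#'
#' @param path CSV file path.
#' @param label Optional label attached to the spectrum.
#' @return A `cd_spectrum` tibble with columns `wavelength_nm`, `intensity`.
#' @export
read_spectrum <- function(path, label = basename(path)) {
  first <- readLines(path, n = 1)
  toks <- strsplit(first, ",")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks[1:2])))
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("wavelength_nm", "intensity"))
  if (anyNA(df$wavelength_nm) || anyNA(df$intensity) ||
      !is.numeric(df$wavelength_nm) || !is.numeric(df$intensity)) {
    abort("non-numeric rows in spectrum CSV", class = "nanocd_format_error")
  }
  cd_spectrum(df$wavelength_nm, df$intensity, label = label)
}

#' Construct a CD spectrum
#'
#' @param wavelengths Wavelength grid in nm (strictly increasing after
#'   sorting; duplicates are an error).
#' @param intensities Signed CD intensities (arbitrary units).
#' @param label Free-text label (e.g. a conformation id).
#' @return A tibble of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, intensities, label = NULL) {
  if (length(wavelengths) != length(intensities)) {
    abort("wavelengths and intensities must have equal length",
          class = "nanocd_validation_error")
  }
  if (any(!is.finite(wavelengths)) || any(!is.finite(intensities))) {
    abort("spectrum values must be finite", class = "nanocd_validation_error")
  }
  if (anyDuplicated(wavelengths)) {
    abort("duplicate wavelengths in spectrum",
          class = "nanocd_validation_error")
  }
  if (is.unsorted(wavelengths)) {
    warn("wavelengths not ascending; sorting")
    o <- order(wavelengths)
    wavelengths <- wavelengths[o]
    intensities <- intensities[o]
  }
  out <- tibble::tibble(wavelength_nm = as.numeric(wavelengths),
                        intensity = as.numeric(intensities))
  attr(out, "label") <- label
  class(out) <- c("cd_spectrum", class(out))
  out
}

#' Write a CD spectrum to CSV
#'
#' @param spectrum A `cd_spectrum` (or any tibble with `wavelength_nm` and
#'   `intensity`).
#' @param path Output CSV path.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_csv(spectrum[, c("wavelength_nm", "intensity")], path)
  invisible(path)
}
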