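# Ground-truth-known generators for every pipeline stage. The generators
# make the bound/unbound geometry unambiguous by construction (no grey
# zone around the contact cutoff), so estimator error isolates the
# estimator, not the geometry.

#' Two-state adsorption kinetics parameters
#'
#' Parameters of the discrete-time two-state (bound/unbound) chain used
#' by [simulate_binding_trajectory()]. Per-frame transition probabilities
#' are `1 - exp(-k dt)`; when both rates are positive the stationary
#' bound probability is `k_on / (k_on + k_off)`.
#'
#' @param k_on,k_off Transition rates in 1/ns (unbound->bound and
#'   bound->unbound). Non-negative; not both zero unless an initial state
#'   is supplied to the simulator.
#' @param dt Frame spacing in ns.
#' @param n_frames Number of frames to simulate.
#' @param seed Integer seed; split into per-analyte substreams.
#' @return A `kinetic_parameters` list.
#' @export
kinetic_parameters <- function(k_on, k_off, dt = 0.1, n_frames = 1000,
                               seed = 1L) {
  if (k_on < 0 || k_off < 0 || dt <= 0 || n_frames < 1) {
    abort("rates must be >= 0, dt > 0, n_frames >= 1",
          class = "nanocd_validation_error")
  }
  structure(list(k_on = k_on, k_off = k_off, dt = dt,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "kinetic_parameters")
}

#' Stationary bound fraction of the two-state chain
#' @param k_on,k_off Rates in 1/ns, not both zero.
#' @return Probability in `[0, 1]`.
#' @export
stationary_bound_fraction <- function(k_on, k_off) {
  if (k_on + k_off <= 0) {
    abort("k_on + k_off must be positive", class = "nanocd_validation_error")
  }
  k_on / (k_on + k_off)
}

#' Autocorrelation-corrected standard error of a bound-fraction estimate
#'
#' Successive frames of a two-state chain are correlated with lag-1
#' autocorrelation `rho = exp(-(k_on + k_off) dt)`; the effective sample
#' size of `n` frames is `n (1 - rho) / (1 + rho)` and the standard error
#' of the estimated bound fraction `p` is `sqrt(p (1 - p) / n_eff)`.
#'
#' @param p Stationary bound probability.
#' @param n_frames Total pooled frames (over replicas/analytes).
#' @param k_on,k_off Rates in 1/ns.
#' @param dt Frame spacing in ns.
#' @return Standard error on the probability scale.
#' @export
bound_fraction_se <- function(p, n_frames, k_on, k_off, dt) {
  rho <- exp(-(k_on + k_off) * dt)
  n_eff <- n_frames * (1 - rho) / (1 + rho)
  sqrt(p * (1 - p) / n_eff)
}

# Deterministic quasi-uniform points on the unit sphere
fibonacci_sphere <- function(n) {
  if (n == 1) return(matrix(c(0, 0, 1), 1))
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate an idealised ligand-protected nanocluster
#'
#' Builds a gold core on concentric shells (the innermost 13-atom
#' icosahedral core is flagged `inner_gold`, remaining gold `core_gold`),
#' with sulfur anchors and 3-heavy-atom ligand chains pointing radially
#' outward. Geometry is idealised plumbing for the synthetic studies, not
#' a physical cluster model. Deterministic for a fixed seed.
#'
#' @param n_gold Number of gold atoms (>= 13).
#' @param n_ligands Number of ligands (>= 1); each contributes one sulfur
#'   and 3 ligand heavy atoms.
#' @param seed Integer seed for the small tangential jitter of the ligand
#'   chains.
#' @return A [molecular_system()] centred at the origin with a generous
#'   default box (re-boxed by the simulator).
#' @export
generate_nanocluster <- function(n_gold = 25, n_ligands = 18, seed = 1L) {
  if (n_gold < 13 || n_ligands < 1) {
    abort("need n_gold >= 13 and n_ligands >= 1",
          class = "nanocd_validation_error")
  }
  set.seed(seed)
  core <- rbind(c(0, 0, 0), 0.29 * fibonacci_sphere(12))
  outer_n <- n_gold - 13
  gold <- rbind(core,
                if (outer_n > 0) 0.55 * fibonacci_sphere(outer_n))
  s_pos <- 0.78 * fibonacci_sphere(n_ligands)
  lig <- do.call(rbind, lapply(seq_len(n_ligands), function(i) {
    dir <- s_pos[i, ] / sqrt(sum(s_pos[i, ]^2))
    t(vapply(1:3, function(k) {
      s_pos[i, ] + dir * 0.15 * k + runif(3, -0.02, 0.02)
    }, numeric(3)))
  }))
  coords <- rbind(gold, s_pos, lig)
  atoms <- atom_table(
    element = c(rep("Au", n_gold), rep("S", n_ligands),
                rep("C", 3 * n_ligands)),
    role = c(rep("inner_gold", 13), rep("core_gold", outer_n),
             rep("sulfur", n_ligands), rep("ligand_heavy", 3 * n_ligands)),
    charge = c(rep(0, n_gold), rep(-0.1, n_ligands),
               rep(c(0.02, 0.02, -0.04), n_ligands)),
    lj_sigma = c(rep(0.29, n_gold), rep(0.35, n_ligands),
                 rep(0.34, 3 * n_ligands)),
    lj_epsilon = c(rep(2.0, n_gold), rep(1.0, n_ligands),
                   rep(0.4, 3 * n_ligands))
  )
  sys <- molecular_system(atoms, box = c(12, 12, 12))
  sys$coords <- coords
  sys
}

# analyte template: C-alpha first, then 5 heavy atoms, offsets in nm
.analyte_template <- rbind(
  c(0, 0, 0),
  c(0.08, 0, 0), c(-0.06, 0.05, 0), c(0, -0.07, 0.03),
  c(0.04, 0.04, -0.06), c(-0.03, -0.03, -0.05)
)

#' Simulate a nanocluster-analyte binding trajectory
#'
#' Each analyte independently follows a discrete-time two-state chain
#' with per-frame transition probabilities `1 - exp(-k dt)`. In bound
#' frames its 6 heavy atoms (C-alpha first) are placed within 0.45 nm of
#' a randomly chosen ligand heavy atom, guaranteeing NOC > 5 at the
#' 0.6 nm contact cutoff; in unbound frames the analyte is placed
#' uniformly in the box with a minimum surface distance of more than
#' 1.2 nm from the ligand shell and more than 2.5 nm between its C-alpha
#' and the inner gold, so both the contact rule and the bound-analyte
#' counting rule classify frames unambiguously. The global seed is split
#' into independent per-analyte substreams.
#'
#' @param system A nanocluster [molecular_system()] from
#'   [generate_nanocluster()].
#' @param n_analytes Number of analyte molecules in the box.
#' @param params A [kinetic_parameters()] object.
#' @param box Cubic box lengths in nm (default `c(12, 12, 12)`).
#' @param initial_state Optional per-analyte initial states
#'   (`"bound"`/`"unbound"`, recycled); required when both rates are 0,
#'   otherwise drawn from the stationary distribution.
#' @param replica_id Replica label for the resulting trajectory.
#' @return A [trajectory()] whose `ground_truth` attribute records the
#'   kinetic parameters, the stationary bound fraction, and the simulated
#'   state matrix (frames x analytes).
#' @export
simulate_binding_trajectory <- function(system, n_analytes = 1, params,
                                        box = c(12, 12, 12),
                                        initial_state = NULL,
                                        replica_id = 1L) {
  stopifnot(inherits(params, "kinetic_parameters"))
  cl_xyz <- system$coords
  r_cl <- sqrt(max(rowSums(cl_xyz^2)))
  r_unbind <- max(r_cl + 1.35, 2.65)
  r_max <- min(box) / 2 - 0.1
  if (r_max <= r_unbind) {
    abort("box too small to place unbound analytes clear of the cluster",
          class = "nanocd_geometry_error")
  }
  if (params$k_on + params$k_off == 0 && is.null(initial_state)) {
    abort("initial_state required when both rates are zero",
          class = "nanocd_validation_error")
  }
  nf <- params$n_frames
  p_on <- 1 - exp(-params$k_on * params$dt)
  p_off <- 1 - exp(-params$k_off * params$dt)
  set.seed(params$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, n_analytes)
  lig_idx <- which(system$atoms$role == "ligand_heavy")
  center <- box / 2
  n_cl <- nrow(cl_xyz)
  n_at <- nrow(.analyte_template)
  coords <- array(0, dim = c(n_cl + n_analytes * n_at, 3, nf))
  for (k in 1:3) coords[seq_len(n_cl), k, ] <- cl_xyz[, k] + center[k]
  states <- matrix(FALSE, nf, n_analytes)
  init <- if (!is.null(initial_state)) {
    rep_len(initial_state == "bound", n_analytes)
  }
  for (a in seq_len(n_analytes)) {
    set.seed(sub_seeds[a])
    s <- logical(nf)
    s0 <- if (!is.null(init)) init[a] else
      runif(1) < stationary_bound_fraction(params$k_on, params$k_off)
    u <- runif(nf)
    prev <- s0
    for (f in seq_len(nf)) {
      p_flip <- if (prev) p_off else p_on
      prev <- xor(prev, u[f] < p_flip)
      s[f] <- prev
    }
    states[, a] <- s
    nb <- sum(s); nu <- nf - nb
    pos <- matrix(0, nf, 3)
    if (nb > 0) {
      pick <- lig_idx[sample.int(length(lig_idx), nb, replace = TRUE)]
      anchors <- cl_xyz[pick, , drop = FALSE]
      dirs <- anchors / sqrt(rowSums(anchors^2))
      pos[s, ] <- anchors + 0.30 * dirs
    }
    if (nu > 0) {
      d <- matrix(rnorm(3 * nu), nu, 3)
      d <- d / sqrt(rowSums(d^2))
      pos[!s, ] <- d * runif(nu, r_unbind, r_max)
    }
    jit <- array(runif(nf * n_at * 3, -0.05, 0.05), dim = c(nf, n_at, 3))
    rows <- n_cl + (a - 1) * n_at + seq_len(n_at)
    for (j in seq_len(n_at)) {
      for (k in 1:3) {
        coords[rows[j], k, ] <- pos[, k] + .analyte_template[j, k] +
          jit[, j, k] + center[k]
      }
    }
  }
  analyte_atoms <- atom_table(
    element = rep(c("C", "C", "N", "O", "C", "C"), n_analytes),
    role = rep(c("analyte_calpha", rep("analyte_heavy", 5)), n_analytes),
    analyte_id = rep(seq_len(n_analytes), each = n_at),
    charge = rep(c(0.1, 0, -0.3, -0.3, 0.25, 0.25), n_analytes),
    lj_sigma = 0.33, lj_epsilon = 0.4
  )
  atoms <- dplyr::bind_rows(system$atoms, analyte_atoms)
  traj <- trajectory(molecular_system(atoms, box), coords,
                     times = params$dt * seq_len(nf),
                     replica_id = replica_id)
  attr(traj, "ground_truth") <- list(
    k_on = params$k_on, k_off = params$k_off, dt = params$dt,
    seed = params$seed,
    p_bound = if (params$k_on + params$k_off > 0)
      stationary_bound_fraction(params$k_on, params$k_off) else
        mean(states[1, ]),
    states = states
  )
  traj
}

#' Simulate a trajectory with planted conformational basins
#'
#' Frames are drawn from Gaussian blobs in configuration space at the
#' stated occupancies; basin centres are displaced along random
#' directions in configuration space such that the RMSD between basin
#' centres equals `basin_separation`. Ground truth (per-frame basin
#' labels) is attached for validation of the PCA / free-energy-landscape
#' / clustering chain.
#'
#' @param n_frames Number of frames.
#' @param occupancies Basin occupancy probabilities (sum to 1).
#' @param basin_separation RMSD between basin centres, Angstrom.
#' @param seed Integer seed.
#' @param n_atoms Number of (gold) atoms in the toy system (>= 2).
#' @param thermal_noise Per-coordinate Gaussian sd within a basin,
#'   Angstrom (default 0.3).
#' @return A [trajectory()] with a `ground_truth` attribute
#'   (`states`, `occupancies`, `basin_separation_A`).
#' @export
generate_basin_trajectory <- function(n_frames, occupancies = c(0.7, 0.3),
                                      basin_separation = 3, seed = 1L,
                                      n_atoms = 40, thermal_noise = 0.3) {
  if (abs(sum(occupancies) - 1) > 1e-8 || any(occupancies < 0)) {
    abort("occupancies must be non-negative and sum to 1",
          class = "nanocd_validation_error")
  }
  if (basin_separation <= 0) {
    abort("basin separation must be positive",
          class = "nanocd_validation_error")
  }
  if (n_atoms < 2) {
    abort("need at least 2 atoms", class = "nanocd_validation_error")
  }
  set.seed(seed)
  base <- 0.5 * fibonacci_sphere(n_atoms) *
    runif(n_atoms, 0.5, 1)           # compact blob, radius <= 0.5 nm
  nb <- length(occupancies)
  sep_nm <- basin_separation / 10
  centers <- list(as.vector(base))
  for (b in seq_len(nb - 1)) {
    u <- rnorm(3 * n_atoms)
    u <- u / sqrt(sum(u^2))
    centers[[b + 1]] <- as.vector(base) + sep_nm * sqrt(n_atoms) * u
  }
  states <- sample.int(nb, n_frames, replace = TRUE, prob = occupancies)
  noise_nm <- thermal_noise / 10
  coords <- array(0, dim = c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(centers[[states[f]]] +
                              rnorm(3 * n_atoms, sd = noise_nm), n_atoms)
  }
  atoms <- atom_table(element = rep("Au", n_atoms),
                      role = rep("core_gold", n_atoms))
  traj <- trajectory(molecular_system(atoms, box = c(50, 50, 50)),
                     coords, times = 0.1 * seq_len(n_frames))
  attr(traj, "ground_truth") <- list(states = states,
                                     occupancies = occupancies,
                                     basin_separation_A = basin_separation)
  traj
}

#' Gaussian-band CD spectrum model
#'
#' Each synthetic spectrum is a sum of Gaussian bands on a 200-800 nm
#' grid (1 nm step) plus independent Gaussian noise. When an analyte is
#' bound, each band's centre is shifted and its amplitude changed by the
#' `analyte_effect`; for the D enantiomer the perturbation is scaled by
#' `1 + enantiomer_asymmetry`, so an asymmetry of 0 makes the L and D
#' responses identical.
#'
#' @param bands Data frame with columns `center_nm`, `width_nm`,
#'   `amplitude`; defaults to three signed bands in the 300-600 nm
#'   sensing window.
#' @param analyte_effect Data frame (one row per band) with
#'   `center_shift_nm` and `amplitude_change`.
#' @param enantiomer_asymmetry Scalar asymmetry epsilon (default 0).
#' @param noise_sd Per-point intensity noise sd (default 0.01).
#' @param seed Integer seed.
#' @return A `spectrum_model` list.
#' @export
spectrum_model <- function(bands = NULL, analyte_effect = NULL,
                           enantiomer_asymmetry = 0, noise_sd = 0.01,
                           seed = 1L) {
  bands <- bands %||% tibble::tibble(
    center_nm = c(320, 420, 520),
    width_nm = c(25, 35, 45),
    amplitude = c(1, -0.8, 0.5)
  )
  analyte_effect <- analyte_effect %||% tibble::tibble(
    center_shift_nm = c(4, -3, 2),
    amplitude_change = c(0.12, -0.08, 0.05)
  )
  if (any(bands$width_nm <= 0) || noise_sd < 0) {
    abort("band widths must be positive and noise_sd >= 0",
          class = "nanocd_validation_error")
  }
  if (nrow(analyte_effect) != nrow(bands)) {
    abort("analyte_effect needs one row per band",
          class = "nanocd_validation_error")
  }
  structure(list(bands = bands, analyte_effect = analyte_effect,
                 enantiomer_asymmetry = enantiomer_asymmetry,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spectrum_model")
}

#' Generate an ensemble of synthetic CD spectra
#'
#' @param model A [spectrum_model()].
#' @param n_conformations Number of spectra to generate.
#' @param bound Apply the analyte perturbation (`TRUE`) or produce bare
#'   nanocluster spectra (`FALSE`).
#' @param enantiomer `"L"` or `"D"`; the D perturbation is scaled by
#'   `1 + enantiomer_asymmetry`. The RNG stream depends only on the
#'   model seed, so at asymmetry 0 the L and D ensembles are bitwise
#'   identical.
#' @return A list of [cd_spectrum()] objects.
#' @export
generate_spectra <- function(model, n_conformations, bound = TRUE,
                             enantiomer = c("L", "D")) {
  stopifnot(inherits(model, "spectrum_model"), n_conformations >= 1)
  enantiomer <- match.arg(enantiomer)
  grid <- seq(200, 800, by = 1)
  s <- if (!bound) 0 else if (enantiomer == "L") 1 else
    1 + model$enantiomer_asymmetry
  centers <- model$bands$center_nm + s * model$analyte_effect$center_shift_nm
  amps <- model$bands$amplitude + s * model$analyte_effect$amplitude_change
  base <- rowSums(vapply(seq_len(nrow(model$bands)), function(b) {
    amps[b] * exp(-(grid - centers[b])^2 / (2 * model$bands$width_nm[b]^2))
  }, numeric(length(grid))))
  set.seed(model$seed)
  lapply(seq_len(n_conformations), function(i) {
    cd_spectrum(grid, base + rnorm(length(grid), sd = model$noise_sd),
                label = sprintf("conf_%d_%s%s", i,
                                if (bound) "bound_" else "bare_",
                                enantiomer))
  })
}
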