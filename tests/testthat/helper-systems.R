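# Builders and independent oracles shared across tests.

# Minimal trajectory from positions (list of n x 3 matrices, nm)
toy_traj <- function(positions, roles, elements = NULL, analyte_id = NA,
                     box = c(100, 100, 100), times = NULL, masses = NULL,
                     charge = NA_real_, lj_sigma = NA_real_,
                     lj_epsilon = NA_real_, donors = NULL) {
  if (is.matrix(positions)) positions <- list(positions)
  n <- nrow(positions[[1]])
  elements <- elements %||% rep("C", n)
  atoms <- atom_table(elements, roles, analyte_id = analyte_id,
                      charge = charge, lj_sigma = lj_sigma,
                      lj_epsilon = lj_epsilon, mass = masses)
  sys <- molecular_system(atoms, box, donors = donors)
  trajectory(sys, positions, times %||% seq_along(positions))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive all-pairs contact count: plain double loop, minimum image.
oracle_contacts <- function(traj, frame_index, analyte_id, cutoff = 0.6) {
  atoms <- traj$system$atoms
  xyz <- traj$coords[, , frame_index]
  box <- traj$system$box
  ai <- which(atoms$role %in% c("analyte_heavy", "analyte_calpha") &
                !is.na(atoms$analyte_id) & atoms$analyte_id == analyte_id)
  ci <- which(atoms$role %in% c("core_gold", "inner_gold", "sulfur",
                                "ligand_heavy"))
  n <- 0L
  for (i in ai) {
    for (j in ci) {
      d <- xyz[i, ] - xyz[j, ]
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= cutoff) n <- n + 1L
    }
  }
  n
}

# Exhaustive minimum-distance analyte inclusion (hydrogens included).
oracle_inclusion <- function(traj, frame_index, threshold_A = 4.0) {
  atoms <- traj$system$atoms
  xyz <- traj$coords[, , frame_index]
  box <- traj$system$box
  cl <- which(is.na(atoms$analyte_id) & atoms$role != "solvent")
  ids <- sort(unique(atoms$analyte_id[!is.na(atoms$analyte_id)]))
  keep <- integer()
  for (id in ids) {
    ai <- which(!is.na(atoms$analyte_id) & atoms$analyte_id == id)
    mind <- Inf
    for (i in ai) {
      for (j in cl) {
        d <- xyz[i, ] - xyz[j, ]
        d <- d - box * round(d / box)
        mind <- min(mind, sqrt(sum(d^2)))
      }
    }
    if (mind < threshold_A / 10) keep <- c(keep, id)
  }
  keep
}

# Random mixed-role system for oracle-equivalence property tests
random_contact_system <- function(seed, max_atoms = 200) {
  set.seed(seed)
  n_analytes <- sample(1:3, 1)
  n_cluster <- sample(10:60, 1)
  n_hyd <- sample(0:20, 1)
  per_analyte <- sample(3:8, n_analytes, replace = TRUE)
  n <- n_cluster + n_hyd + sum(per_analyte)
  stopifnot(n <= max_atoms)
  roles <- c(
    sample(c("core_gold", "inner_gold", "sulfur", "ligand_heavy"),
           n_cluster, replace = TRUE),
    rep("hydrogen", n_hyd),
    unlist(lapply(per_analyte, function(k) {
      c("analyte_calpha", rep("analyte_heavy", k - 1))
    }))
  )
  ids <- c(rep(NA, n_cluster),
           sample(c(NA, seq_len(n_analytes)), n_hyd, replace = TRUE),
           rep(seq_len(n_analytes), per_analyte))
  elements <- ifelse(roles == "analyte_calpha", "C",
                     ifelse(roles == "hydrogen", "H", "C"))
  box <- runif(3, 2, 4)
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
               runif(n, 0, box[3]))
  toy_traj(pos, roles, elements = elements, analyte_id = ids, box = box)
}
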