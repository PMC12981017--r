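test_that("contact counting follows the heavy-atom cutoff rule", {
  mk <- function(d, analyte_role = "analyte_heavy",
                 analyte_element = "C") {
    toy_traj(matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE),
             roles = c("ligand_heavy", analyte_role),
             elements = c("C", analyte_element),
             analyte_id = c(NA, 1))
  }
  expect_equal(count_contacts(mk(0.5), 1, 1), 1)
  expect_equal(count_contacts(mk(0.7), 1, 1), 0)
  expect_equal(count_contacts(mk(0.6), 1, 1), 1)   # inclusive cutoff
  # analyte hydrogen right on a gold atom never counts
  h <- toy_traj(matrix(c(0, 0, 0, 0.01, 0, 0), 2, byrow = TRUE),
                roles = c("core_gold", "hydrogen"),
                elements = c("Au", "H"), analyte_id = c(NA, 1))
  expect_equal(count_contacts(h, 1, 1), 0)
  expect_error(count_contacts(mk(0.5), 1, 99),
               class = "nanocd_lookup_error")
})

test_that("contact counts match the exhaustive all-pairs oracle", {
  for (seed in 1:15) {
    traj <- random_contact_system(seed)
    for (id in unique(na.omit(traj$system$atoms$analyte_id))) {
      expect_equal(count_contacts(traj, 1, id),
                   oracle_contacts(traj, 1, id),
                   info = paste("seed", seed, "analyte", id))
    }
  }
})

test_that("contact series equals per-frame counting, across the box edge", {
  # analyte wrapped across the periodic boundary still contacts
  pos1 <- matrix(c(0.1, 0.5, 0.5, 4.9, 0.5, 0.5), 2, byrow = TRUE)
  pos2 <- matrix(c(0.1, 0.5, 0.5, 2.5, 0.5, 0.5), 2, byrow = TRUE)
  traj <- toy_traj(list(pos1, pos2), roles = c("ligand_heavy",
                                               "analyte_heavy"),
                   analyte_id = c(NA, 1), box = c(5, 5, 5))
  cs <- contact_series(traj)
  expect_equal(cs$noc, c(1, 0))   # minimum image: 0.2 nm, then 2.4 nm
  expect_equal(cs$noc,
               purrr::map_int(1:2, count_contacts, traj = traj,
                              analyte_id = 1))
})

test_that("adsorption probability pools replicas with a strict threshold", {
  mk_series <- function(noc, replica = 1) {
    tibble::tibble(replica = replica, analyte_id = 1,
                   frame = seq_along(noc), time_ns = seq_along(noc),
                   noc = noc)
  }
  expect_equal(adsorption_probability(mk_series(rep(6, 50)))$P_percent, 100)
  expect_equal(adsorption_probability(mk_series(rep(5, 50)))$P_percent, 0)
  three <- list(mk_series(c(rep(6, 30), rep(0, 70)), 1),
                mk_series(c(rep(9, 60), rep(1, 40)), 2),
                mk_series(c(rep(7, 90), rep(5, 10)), 3))
  bs <- adsorption_probability(three)
  expect_equal(bs$P_percent, 60.0)
  expect_equal(bs$n_bound_frames, 180)
  expect_equal(tidy(bs)$P_percent, c(30, 60, 90))
  expect_equal(glance(bs)$n_total_frames, 300)
  # frame reordering and pooling vs pre-concatenation are invariant
  pooled <- adsorption_probability(dplyr::bind_rows(three))
  expect_equal(pooled$P_percent, bs$P_percent)
  shuffled <- purrr::map(three, ~ .x[sample(nrow(.x)), ])
  expect_equal(adsorption_probability(shuffled)$P_percent, bs$P_percent)
  # monotone non-increasing in threshold
  p_at <- purrr::map_dbl(0:10, ~ adsorption_probability(three, .x)$P_percent)
  expect_true(all(diff(p_at) <= 0))
  expect_error(adsorption_probability(list(mk_series(integer(0)))),
               class = "nanocd_empty_error")
})

test_that("COM distances are mass-weighted and minimum-imaged", {
  # unit-mass pair at (0,0,0),(0,0,2) vs single atom at (0,0,5): COM gap 4
  traj <- toy_traj(matrix(c(0, 0, 0, 0, 0, 2, 0, 0, 5), 3, byrow = TRUE),
                   roles = c("ligand_heavy", "ligand_heavy",
                             "analyte_heavy"),
                   analyte_id = c(NA, NA, 1), masses = c(1, 1, 1))
  expect_equal(com_distance(traj, 1, 1:2, 3), 4.0)
  expect_equal(com_distance(traj, 1, 3, 3), 0)              # coincident
  expect_equal(com_distance(traj, 1, 3, 1:2),
               com_distance(traj, 1, 1:2, 3))               # symmetric
  # single atoms at z = 0.5 and 10.5 in an 11 nm box: image distance 1
  tr2 <- toy_traj(matrix(c(0, 0, 0.5, 0, 0, 10.5), 2, byrow = TRUE),
                  roles = c("ligand_heavy", "analyte_heavy"),
                  analyte_id = c(NA, 1), box = c(11, 11, 11))
  expect_equal(com_distance(tr2, 1, 1, 2), 1.0)
  # invariant under a global translation (with wrap)
  tr3 <- tr2
  tr3$coords <- tr2$coords + 3.7
  expect_equal(com_distance(tr3, 1, 1, 2), 1.0)
  expect_error(com_distance(tr2, 1, integer(0), 2),
               class = "nanocd_selection_error")
  cser <- com_series(tr2, 1, 2)
  expect_equal(cser$com_distance_nm, 1.0)
})

test_that("hydrogen bonds use the distance-and-angle criterion", {
  # linear O-H...O at varying geometry; donor O at origin, H on +x
  mk <- function(o_o, angle_deg) {
    a <- angle_deg * pi / 180
    pos <- matrix(c(0, 0, 0,
                    0.1, 0, 0,
                    o_o * cos(a), o_o * sin(a), 0), 3, byrow = TRUE)
    toy_traj(pos, roles = c("ligand_heavy", "hydrogen", "analyte_heavy"),
             elements = c("O", "H", "O"), analyte_id = c(NA, NA, 1),
             donors = data.frame(donor = 1, hydrogen = 2))
  }
  expect_equal(hydrogen_bonds(mk(0.28, 0), 1, acceptors = 3), 1)
  expect_equal(hydrogen_bonds(mk(0.40, 0), 1, acceptors = 3), 0)
  expect_equal(hydrogen_bonds(mk(0.30, 60), 1, acceptors = 3), 0)
  expect_equal(hbond_series(mk(0.30, 10), acceptors = 3)$hb_count, 1)
  bad <- mk(0.28, 0)
  expect_error(hydrogen_bonds(bad, 1, donors = data.frame(donor = 1,
                                                          hydrogen = 3),
                              acceptors = 3),
               class = "nanocd_validation_error")
  no_donors <- toy_traj(matrix(0, 1, 3), roles = "analyte_heavy",
                        elements = "O", analyte_id = 1)
  expect_error(hydrogen_bonds(no_donors, 1, donors = NULL, acceptors = 1),
               class = "nanocd_validation_error")
})

test_that("interaction energies follow Coulomb and Lennard-Jones forms", {
  mk <- function(r, q = c(1, -1), sigma = 0.3, eps = 0.5) {
    toy_traj(matrix(c(0, 0, 0, r, 0, 0), 2, byrow = TRUE),
             roles = c("ligand_heavy", "analyte_heavy"),
             analyte_id = c(NA, 1), charge = q, lj_sigma = sigma,
             lj_epsilon = eps)
  }
  e <- interaction_energies(mk(1.0), 1, 1, 2, cutoff = 2)
  expect_equal(e$coulomb_kjmol, -138.935)
  expect_equal(interaction_energies(mk(1.0, q = c(0, 0)), 1, 1, 2,
                                    cutoff = 2)$coulomb_kjmol, 0)
  # LJ zero at r = sigma, minimum -eps at r = 2^(1/6) sigma
  expect_equal(interaction_energies(mk(0.3), 1, 1, 2,
                                    cutoff = 2)$lj_kjmol, 0)
  expect_equal(interaction_energies(mk(2^(1 / 6) * 0.3), 1, 1, 2,
                                    cutoff = 2)$lj_kjmol, -0.5,
               tolerance = 1e-12)
  # Coulomb linear in q_i q_j
  e2 <- interaction_energies(mk(1.0, q = c(2, -1)), 1, 1, 2, cutoff = 2)
  expect_equal(e2$coulomb_kjmol, 2 * e$coulomb_kjmol)
  # beyond the cutoff nothing contributes
  expect_equal(interaction_energies(mk(1.5), 1, 1, 2,
                                    cutoff = 1)$coulomb_kjmol, 0)
  expect_error(interaction_energies(mk(1, q = c(NA, 1)), 1, 1, 2),
               class = "nanocd_validation_error")
})

test_that("bound-analyte counting uses the C-alpha / inner-gold rule", {
  mk <- function(d) {
    toy_traj(matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE),
             roles = c("inner_gold", "analyte_calpha"),
             elements = c("Au", "C"), analyte_id = c(NA, 1))
  }
  expect_equal(count_bound_analytes(mk(1.0), 1, cutoff = 1.5), 1)
  expect_equal(count_bound_analytes(mk(3.0), 1, cutoff = 1.5), 0)
  expect_warning(count_bound_analytes(mk(1.0), 1, cutoff = 3.0),
                 "outside the usual")
  # 10 analytes all within cutoff
  pos <- rbind(c(0, 0, 0),
               cbind(runif(10, -1, 1), runif(10, -1, 1), 0) * 0.5)
  tr <- toy_traj(pos, roles = c("inner_gold", rep("analyte_calpha", 10)),
                 elements = c("Au", rep("C", 10)),
                 analyte_id = c(NA, 1:10))
  expect_equal(count_bound_analytes(tr, 1), 10)
  no_ca <- toy_traj(matrix(0, 1, 3), roles = "inner_gold",
                    elements = "Au")
  expect_error(count_bound_analytes(no_ca, 1),
               class = "nanocd_validation_error")
})

test_that("mean bound counts convert to integer percent probabilities", {
  expect_equal(mean_bound_to_probability(c(6.4, 6.6), 10), 65)
  expect_equal(mean_bound_to_probability(14.8, 20), 74)
  expect_equal(mean_bound_to_probability(c(0, 0), 10), 0)
  expect_error(mean_bound_to_probability(12, 10),
               class = "nanocd_validation_error")
})

test_that("ligand packing ratios reproduce the spherical-model arithmetic", {
  expect_equal(ligand_ratio_model(144, 102)$predicted_ratio, 1.25)
  expect_equal(ligand_ratio_model(50, 50)$predicted_ratio, 1.00)
  expect_equal(ligand_ratio_model(800, 100)$predicted_ratio, 4.00)
  expect_equal(actual_ligand_ratio(60, 44)$actual_ratio, 1.36)
  expect_equal(actual_ligand_ratio(44, 44)$actual_ratio, 1.00)
  expect_equal(actual_ligand_ratio(120, 88)$actual_ratio, 1.36)
  expect_error(ligand_ratio_model(0, 10),
               class = "nanocd_validation_error")
})
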