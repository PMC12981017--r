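rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, byrow = TRUE)
}

test_that("superposition removes rigid-body motion exactly", {
  set.seed(11)
  ref <- matrix(rnorm(30, sd = 0.3), 10)
  rot <- ref %*% rotation_z(0.8)
  shifted <- sweep(ref, 2, c(1, -2, 0.5), "+")
  traj <- toy_traj(list(ref, rot, shifted),
                   roles = rep("core_gold", 10),
                   elements = rep("Au", 10))
  sup <- superpose(traj, 1, selection = 1:10)
  expect_lt(frame_rmsd(sup, 1, 2, 1:10), 1e-10)
  expect_lt(frame_rmsd(sup, 1, 3, 1:10), 1e-10)
})

test_that("superposition is a least-squares fit (never worse, bio3d agrees)", {
  set.seed(12)
  ref <- matrix(rnorm(24, sd = 0.3), 8)
  frames <- purrr::map(1:5, function(i) {
    (ref + matrix(rnorm(24, sd = 0.05), 8)) %*% rotation_z(0.3 * i) + i * 0.1
  })
  traj <- toy_traj(c(list(ref), frames), roles = rep("core_gold", 8),
                   elements = rep("Au", 8))
  sup <- superpose(traj, 1, selection = 1:8)
  for (f in 2:6) {
    expect_lte(frame_rmsd(sup, 1, f), frame_rmsd(traj, 1, f) + 1e-12)
  }
  skip_if_not_installed("bio3d")
  # independent oracle: bio3d's fitted RMSD on the same frames
  fixed <- as.vector(t(ref))
  for (f in 2:6) {
    mob <- as.vector(t(traj$coords[, , f]))
    oracle <- bio3d::rmsd(fixed, mob, fit = TRUE)   # rounded to 3 decimals
    expect_lt(abs(frame_rmsd(sup, 1, f) - oracle), 6e-4)
  }
})

test_that("a pure radial-scaling displacement yields the planted RMSD", {
  # atoms on a 0.1 nm sphere; doubling the radius displaces each atom by
  # 0.1 nm along a direction orthogonal to every rigid-body mode, so the
  # optimal fit leaves an RMSD of exactly 1 Angstrom
  sphere <- 0.1 * rbind(diag(3), -diag(3))
  traj <- toy_traj(list(sphere, 2 * sphere), roles = rep("core_gold", 6),
                   elements = rep("Au", 6))
  sup <- superpose(traj, 1, selection = 1:6)
  expect_equal(frame_rmsd(sup, 1, 2) * 10, 1, tolerance = 1e-10)
})

test_that("degenerate (collinear) selections are rejected", {
  line <- cbind(seq(0, 1, length.out = 5), 0, 0)
  traj <- toy_traj(list(line, line), roles = rep("core_gold", 5),
                   elements = rep("Au", 5))
  expect_error(superpose(traj, 1, selection = 1:5),
               class = "nanocd_degenerate_error")
  expect_error(superpose(traj, 1, selection = 1:2),
               class = "nanocd_degenerate_error")
})

test_that("PCA recovers planted orthogonal motion directions", {
  set.seed(21)
  n_atoms <- 12
  base <- matrix(rnorm(3 * n_atoms, sd = 0.2), n_atoms)
  v1 <- rnorm(3 * n_atoms); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(3 * n_atoms); v2 <- v2 - sum(v2 * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  a <- rnorm(400, sd = 0.08); b <- rnorm(400, sd = 0.03)
  frames <- purrr::map(1:400, function(f) {
    base + matrix(a[f] * v1 + b[f] * v2, n_atoms, byrow = FALSE)
  })
  traj <- toy_traj(frames, roles = rep("core_gold", n_atoms),
                   elements = rep("Au", n_atoms))
  pca <- pca_trajectory(traj, selection = seq_len(n_atoms))
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_equal(crossprod(pca$components[, 1:2]), diag(2),
               tolerance = 1e-8, ignore_attr = TRUE)
  # motion confined to a 2D plane in configuration space
  expect_lt(pca$eigenvalues[3], 1e-10 * sum(pca$eigenvalues))
  # eigenvalue sum equals total coordinate variance
  x <- nanocd:::coord_matrix(traj, seq_len(n_atoms))
  expect_equal(sum(pca$eigenvalues), sum(apply(x, 2, var)),
               tolerance = 1e-6)
  # projections correlate with the planted amplitudes
  expect_gt(abs(cor(pca$projections$PC1, a)), 0.999)
  expect_gt(abs(cor(pca$projections$PC2, b)), 0.999)
  expect_error(pca_trajectory(toy_traj(list(base, base),
                                       roles = rep("core_gold", n_atoms),
                                       elements = rep("Au", n_atoms)),
                              selection = 1:n_atoms),
               class = "nanocd_empty_error")
})

test_that("free-energy landscape is a Boltzmann inversion of the histogram", {
  proj <- tibble::tibble(
    frame = 1:30,
    PC1 = c(rep(0.1, 20), rep(0.9, 10)),
    PC2 = 0.5
  )
  fes <- free_energy_landscape(proj, n_bins = 2)
  g <- tidy(fes)
  visited <- g[!is.na(g$delta_g_kT), ]
  expect_equal(min(visited$delta_g_kT), 0)
  expect_equal(sort(visited$delta_g_kT), c(0, log(2)), tolerance = 1e-12)
  expect_true(all(is.na(g$delta_g_kT[g$count == 0])))
  # uniform histogram: dG = 0 in every visited bin
  u <- tibble::tibble(frame = 1:16, PC1 = rep(1:4, 4) / 4,
                      PC2 = rep(1:4, each = 4) / 4)
  fu <- free_energy_landscape(u, n_bins = 4)
  expect_true(all(tidy(fu)$delta_g_kT[tidy(fu)$count > 0] == 0))
  expect_error(free_energy_landscape(proj, n_bins = 1),
               class = "nanocd_validation_error")
})

test_that("minimum-region frame selection is monotone in depth", {
  proj <- tibble::tibble(
    frame = 1:100,
    PC1 = c(rep(0.1, 70), rep(0.9, 30)),
    PC2 = 0.5
  )
  fes <- free_energy_landscape(proj, n_bins = 2)
  expect_equal(select_minimum_frames(fes, 0), 1:70)
  expect_equal(select_minimum_frames(fes, Inf), 1:100)
  # ln(70/30) = 0.847 > 0.5: minor basin excluded at the default depth
  expect_equal(select_minimum_frames(fes, 0.5), 1:70)
  expect_equal(select_minimum_frames(fes, 0.9), 1:100)
  sizes <- purrr::map_int(seq(0, 2, 0.1),
                          ~ length(select_minimum_frames(fes, .x)))
  expect_true(all(diff(sizes) >= 0))
})

test_that("gromos clustering separates planted groups deterministically", {
  # two groups: intra-group RMSD 0, inter-group 3 Angstrom
  a <- matrix(0, 4, 3)
  b <- a; b[, 1] <- 0.3  # 3 A displacement per atom
  frames <- list(a, a, b, a, b)
  traj <- toy_traj(frames, roles = rep("core_gold", 4),
                   elements = rep("Au", 4))
  rs <- rmsd_cluster(traj, 1:5, selection = 1:4, cutoff = 1.5)
  expect_equal(nrow(tidy(rs)), 2)
  expect_equal(rs$membership$cluster, c(1, 1, 2, 1, 2))
  expect_equal(tidy(rs)$size, c(3, 2))
  # largest cluster first, centre is the earliest frame on ties
  expect_equal(tidy(rs)$center_frame, c(1, 3))
  # all frames identical: one cluster
  one <- rmsd_cluster(toy_traj(list(a, a, a), roles = rep("core_gold", 4),
                               elements = rep("Au", 4)),
                      1:3, selection = 1:4, cutoff = 1.5)
  expect_equal(nrow(tidy(one)), 1)
  expect_equal(tidy(one)$size, 3)
  # determinism
  rs2 <- rmsd_cluster(traj, 1:5, selection = 1:4, cutoff = 1.5)
  expect_identical(tidy(rs), tidy(rs2))
  expect_error(rmsd_cluster(traj, integer(0), selection = 1:4),
               class = "nanocd_empty_error")
})

test_that("brute-force neighbour counting agrees on small random sets", {
  set.seed(31)
  frames <- purrr::map(1:8, ~ matrix(rnorm(12, sd = 0.08), 4))
  traj <- toy_traj(frames, roles = rep("core_gold", 4),
                   elements = rep("Au", 4))
  cutoff <- 1.2
  rs <- rmsd_cluster(traj, 1:8, selection = 1:4, cutoff = cutoff)
  # oracle: first centre must be the frame with most neighbours
  rm <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    rm[i, j] <- sqrt(sum((frames[[i]] - frames[[j]])^2) / 4) * 10
  }
  counts <- rowSums(rm <= cutoff)
  expect_equal(tidy(rs)$center_frame[1], which.max(counts))
  expect_equal(tidy(rs)$size[1], max(counts))
})
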