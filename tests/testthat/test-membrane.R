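test_that("superposition recovers rigid motions exactly", {
  set.seed(61)
  x <- matrix(rnorm(15, sd = 5), 5, 3)
  fit <- superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  # rotation + translation leaves RMSD at zero
  R <- random_rotation()
  moved <- x %*% t(R) + matrix(c(10, -5, 3), 5, 3, byrow = TRUE)
  fit2 <- superpose(moved, x)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit2$transform(moved), x, tolerance = 1e-8)
  expect_true(abs(det(fit2$rotation) - 1) < 1e-8)
})

test_that("superposition RMSD matches the quaternion oracle on random pairs", {
  set.seed(62)
  for (r in 1:25) {
    a <- matrix(rnorm(15, sd = 3), 5, 3)
    b <- matrix(rnorm(15, sd = 3), 5, 3)
    expect_equal(superpose(a, b)$rmsd, oracle_quaternion_rmsd(a, b),
                 tolerance = 1e-8)
  }
})

test_that("degenerate superposition subsets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line + rnorm(15, sd = 1e-12), line), "collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 subset")
})

test_that("rmsd series is zero along rigid-motion trajectories", {
  set.seed(63)
  s <- random_structure(5, atoms_per_res = 3)
  coords <- lapply(1:8, function(f)
    s$xyz %*% t(random_rotation()) + matrix(rnorm(3, sd = 20), nrow(s$xyz),
                                            3, byrow = TRUE))
  traj <- trajectory_ensemble(s, coords)
  ser <- rmsd_series(traj, reference = s$xyz)
  expect_true(all(ser$values < 1e-8))
  expect_equal(rmsd_series(traj, reference = 1)$values[1], 0, tolerance = 1e-12)
})

test_that("rmsd under isotropic jitter matches its Monte-Carlo expectation", {
  set.seed(64)
  s <- random_structure(40, atoms_per_res = 5, spread = 50)
  sigma <- 0.8
  coords <- lapply(1:50, function(f) s$xyz + matrix(rnorm(3 * nrow(s$xyz),
                                                          sd = sigma),
                                                    nrow(s$xyz), 3))
  traj <- trajectory_ensemble(s, coords)
  ser <- rmsd_series(traj, reference = s$xyz)
  # for many atoms, fitted RMSD under 3-D jitter approaches sigma*sqrt(3)
  expect_equal(mean(ser$values), sigma * sqrt(3), tolerance = 0.1)
})

test_that("radius of gyration matches closed forms and the direct oracle", {
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1.0)
  expect_equal(radius_of_gyration(rbind(c(5, 5, 5))), 0)
  set.seed(65)
  x <- matrix(rnorm(300), 100, 3)
  w <- runif(100, 0.5, 16)
  com <- colSums(x * w) / sum(w)
  oracle <- sqrt(sum(w * rowSums(sweep(x, 2, com)^2)) / sum(w))
  expect_equal(radius_of_gyration(x, weights = w), oracle, tolerance = 1e-10)
  # rigid-motion invariance
  moved <- x %*% t(random_rotation()) + 100
  expect_equal(radius_of_gyration(moved), radius_of_gyration(x),
               tolerance = 1e-8)
  expect_error(radius_of_gyration(x, weights = rep(0, 100)), "positive")
})

test_that("protein-bilayer COM displacement tracks planted drift", {
  set.seed(66)
  s <- random_structure(4, atoms_per_res = 2)  # residues 1-2 protein, 3-4 bilayer
  prot <- which(s$residue_id <= 2)
  bil <- which(s$residue_id > 2)
  base <- s$xyz
  base[bil, ] <- sweep(base[bil, ], 2, colMeans(base[bil, ]))  # bilayer COM at 0
  base[prot, ] <- sweep(base[prot, ], 2, colMeans(base[prot, ]))
  # drift the protein from 0 to 22 Angstrom along z over 100 frames
  drift <- seq(0, 22, length.out = 100)
  coords <- lapply(seq_along(drift), function(f) {
    x <- base
    x[prot, 3] <- x[prot, 3] + drift[f]
    x
  })
  traj <- trajectory_ensemble(s, coords)
  ser <- com_displacement_along_normal(traj, prot, bil, axis = "z")
  expect_equal(ser$values[1], 0, tolerance = 1e-10)
  expect_equal(ser$values[100], 22, tolerance = 1e-10)
  final_window <- mean(ser$values[91:100])
  expect_true(final_window >= 20 && final_window <= 24)
  expect_equal(ser$magnitude, abs(ser$values))
  # shifted protein reports the signed offset
  expect_equal(com_displacement_along_normal(traj, prot, bil,
                                             axis = "x")$values[1], 0,
               tolerance = 1e-10)
  expect_error(com_displacement_along_normal(traj, integer(0), bil), "empty")
})

test_that("hydrogen bonds follow the donor-centered distance/angle criteria", {
  # collinear D-H...A at 3.0 Angstrom: ideal geometry
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  don <- cbind(1, 2)
  expect_equal(count_hbonds(coords, don, 3)$count, 1)
  # same geometry stretched to 3.6 Angstrom: beyond the 3.5 cutoff
  coords2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.6, 0, 0))
  expect_equal(count_hbonds(coords2, don, 3)$count, 0)
  # 25-degree donor angle: beyond the 20-degree cutoff
  a <- 3 * c(cos(25 * pi / 180), sin(25 * pi / 180), 0)
  expect_equal(count_hbonds(rbind(c(0, 0, 0), c(1, 0, 0), a), don, 3)$count, 0)
  # minimum image: hydrogen and acceptor sit across the boundary
  coords3 <- rbind(c(0.5, 0, 0), c(49.5, 0, 0), c(47.8, 0, 0))
  expect_equal(count_hbonds(coords3, don, 3, box = c(50, 50, 50))$count, 1)
  expect_equal(count_hbonds(coords3, don, 3)$count, 0)
  # donors without hydrogens are skipped with a warning
  expect_warning(r <- count_hbonds(coords, rbind(c(1, NA)), 3), "skipped")
  expect_equal(r$count, 0)
})

test_that("hbond fixtures hit their planned count; monotone in both cutoffs", {
  fx <- generate_hbond_fixture(n_triads = 50, satisfied_fraction = 0.4,
                               seed = 67)
  r <- count_hbonds(fx$coords, fx$donors, fx$acceptors, 3.5, 20)
  expect_equal(r$count, 20)
  expect_equal(r$count, fx$truth$n_satisfied)
  # the detected donors correspond exactly to the planned satisfying triads
  expect_setequal(r$bonds$donor, fx$donors[fx$truth$satisfied, 1])
  counts_d <- sapply(c(2.5, 3.0, 3.5, 4.5, 6.5), function(dc)
    count_hbonds(fx$coords, fx$donors, fx$acceptors, dc, 20)$count)
  counts_a <- sapply(c(5, 10, 20, 45, 75), function(ac)
    count_hbonds(fx$coords, fx$donors, fx$acceptors, 3.5, ac)$count)
  expect_true(all(diff(counts_d) >= 0))
  expect_true(all(diff(counts_a) >= 0))
})

test_that("unwrapping reconstructs continuous paths across the boundary", {
  expect_equal(unwrap_axis(c(9, 1), box = 10), c(9, 11))
  expect_equal(unwrap_axis(c(5, 5, 5), box = 10), c(5, 5, 5))
  set.seed(68)
  truth <- apply(matrix(rnorm(2000 * 3, sd = 1.5), 2000, 3), 2, cumsum)
  wrapped <- truth %% 25
  rec <- unwrap_axis(wrapped, box = 25)
  # recovered up to the initial wrap offset of each particle
  off <- truth[1, ] - wrapped[1, ]
  expect_equal(rec, sweep(truth, 2, off), tolerance = 1e-10)
})

test_that("crossing automaton counts complete traversals only", {
  # monotone pass through the slab: one +1 event
  z <- seq(-20, 20, length.out = 41)
  ev <- count_crossings(z + 30, box = 60, slab = c(15, 45))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, 1L)
  # entering and retreating: no event
  z2 <- c(seq(5, 25, 2), seq(25, 5, -2)) + 0.1
  expect_equal(nrow(count_crossings(z2, box = 60, slab = c(20, 40))), 0)
  # touching the boundary exactly then retreating: no event (ties inside)
  z3 <- c(10, 20, 10)
  expect_equal(nrow(count_crossings(z3, box = 60, slab = c(20, 40))), 0)
  # downward pass: one -1 event
  ev2 <- count_crossings(rev(z) + 30, box = 60, slab = c(15, 45))
  expect_equal(ev2$direction, -1L)
  # multiple box lengths of drift: one event per slab image traversed
  z4 <- seq(5, 5 + 3 * 60, by = 1.5)
  ev3 <- count_crossings(z4 %% 60, box = 60, slab = c(20, 40))
  expect_equal(nrow(ev3), 3)
})

test_that("slab worlds reproduce their ground-truth events exactly", {
  w <- generate_slab_world(n_particles = 120, n_frames = 600, drift = 0.4,
                           diffusion = 1.2, seed = 69)
  zw <- t(sapply(w$trajectory$coords, function(x) x[, 3]))
  ev <- count_crossings(zw, box = w$truth$box[3], slab = w$truth$slab)
  expect_true(nrow(ev) > 10)  # the regime actually produces events
  expect_equal(ev, w$truth$events)
  # wrap-then-analyze equals analyze-unwrapped
  ev2 <- count_crossings(w$truth$paths_z, box = w$truth$box[3],
                         slab = w$truth$slab, unwrap = FALSE)
  expect_equal(ev2, w$truth$events)
  # conservation: net events match net displacement across slab images
  for (p in unique(ev$particle_id)[1:10]) {
    net <- sum(ev$direction[ev$particle_id == p])
    disp <- w$truth$paths_z[nrow(w$truth$paths_z), p] - w$truth$paths_z[1, p]
    expect_lte(abs(net - disp / w$truth$box[3]), 1.5)
  }
  # deterministic regime: constant drift, no diffusion, one traversal
  w2 <- generate_slab_world(n_particles = 10, n_frames = 200,
                            box = c(20, 20, 60), slab = c(20, 40),
                            drift = 0.6, diffusion = 0, seed = 70)
  ev3 <- count_crossings(t(sapply(w2$trajectory$coords, function(x) x[, 3])),
                         box = 60, slab = c(20, 40))
  expect_equal(ev3, w2$truth$events)
})

test_that("lipid radial densities report per-shell number densities", {
  # one marker 5 Angstrom from a single-atom protein: shell 2 of (0,4,8)
  coords <- rbind(c(0, 0, 0), c(5, 0, 0))
  prof <- lipid_radial_density(coords, marker_subset = 2, protein_subset = 1,
                               shell_edges = c(0, 4, 8))
  expect_equal(prof$counts, c(0, 1))
  expect_equal(prof$density[2], 1 / (4 / 3 * pi * (8^3 - 4^3)))
  expect_error(lipid_radial_density(coords, 2, integer(0), c(0, 4, 8)),
               "non-empty")
  expect_error(lipid_radial_density(coords, 2, 1, c(0, 8, 4)), "increasing")
})

test_that("uniform markers give a flat profile; enrichment is recovered", {
  fx0 <- generate_lipid_shell_fixture(n_markers = 4000, enrichment_factor = 1,
                                      inner_radius = 10, box = 60, seed = 71)
  prof0 <- lipid_radial_density(fx0$coords, fx0$marker_subset,
                                fx0$protein_subset,
                                shell_edges = c(2, 10, 16, 22), box = fx0$box)
  expect_true(all(abs(prof0$density / mean(prof0$density) - 1) < 0.25))
  fx3 <- generate_lipid_shell_fixture(n_markers = 4000, enrichment_factor = 3,
                                      inner_radius = 10, box = 60, seed = 72)
  prof3 <- lipid_radial_density(fx3$coords, fx3$marker_subset,
                                fx3$protein_subset,
                                shell_edges = c(0, 10, 16, 22), box = fx3$box)
  ratio <- prof3$density[1] / mean(prof3$density[2:3])
  expect_equal(ratio, 3, tolerance = 0.2)
  # two-window contrast: uniform early window vs enriched late window
  early <- lipid_radial_density(fx0$coords, fx0$marker_subset, 1,
                                shell_edges = c(0, 10, 16, 22), box = fx0$box)
  expect_gt(prof3$density[1] / prof3$density[3],
            2 * early$density[1] / early$density[3])
})
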