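# Shared fixtures and independent oracles for the test suite.

# minimal structure: n_res residues, atoms_per_res atoms each, random coords
random_structure <- function(n_res, atoms_per_res = 3, spread = 20) {
  n <- n_res * atoms_per_res
  atoms <- data.frame(atom_id = seq_len(n),
                      atom_name = rep(paste0("A", seq_len(atoms_per_res)), n_res),
                      element = "C",
                      residue_index = rep(seq_len(n_res), each = atoms_per_res),
                      residue_name = "GLY", chain_id = "A")
  structure_model(atoms, matrix(runif(3 * n, 0, spread), n, 3))
}

# brute-force contact oracle: all-pairs double loop over atoms
oracle_contact_state <- function(coords, residue_id, cutoff, box = NULL) {
  nr <- max(residue_id)
  u <- matrix(0L, nr, nr)
  n <- nrow(coords)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (residue_id[a] == residue_id[b]) next
      d <- coords[a, ] - coords[b, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      if (sum(d^2) <= cutoff^2) {
        u[residue_id[a], residue_id[b]] <- 1L
        u[residue_id[b], residue_id[a]] <- 1L
      }
    }
  }
  u
}

# independent quaternion (Horn) superposition oracle: optimal RMSD only
oracle_quaternion_rmsd <- function(mobile, reference) {
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(m0, r0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(m0^2) + sum(r0^2) - 2 * lam) / nrow(mobile)
  sqrt(max(msd, 0))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# ready-made two-class redox-style spec: six independent 2-pair modes
redox_spec <- function(n_frames = 500, flip_noise = 0.01, seed = 11,
                       p_hi = 0.9, p_lo = 0.1) {
  # mode m owns residues 4m-3..4m as pairs (4m-3, 4m-1) and (4m-2, 4m)
  modes <- lapply(1:6, function(m)
    list(pairs = rbind(c(4 * m - 3, 4 * m - 1), c(4 * m - 2, 4 * m)),
         occupancy = c(wt = p_hi, analog = p_lo)))
  switching_spec(n_residues = 36, n_frames = n_frames, modes = modes,
                 trajectories = data.frame(id = c("wt_run", "an_run"),
                                           redox = c("wt", "analog")),
                 n_background = 4, flip_noise = flip_noise, seed = seed)
}

planted_pair_cols <- function(cp, truth_pairs) {
  # columns of the dynamic pair list matching the planted pairs
  key <- paste(cp$pair_index$i, cp$pair_index$j)
  match(paste(truth_pairs$i, truth_pairs$j), key)
}
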