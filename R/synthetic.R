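#' Specification for a synthetic contact-switching ensemble
#'
#' Describes a bead-resolution system whose residue-residue contacts switch
#' under a small number of latent modes with class-dependent occupancies.
#' Residues are rigid bead clusters laid out on a sparse lattice; each
#' dynamic pair (planted mode pairs and nuisance background pairs) is a
#' disjoint two-residue unit whose separation toggles between a contact
#' distance (3.8 Angstrom) and a broken distance (8.0 Angstrom), so that
#' recomputing contacts at the 4.2 Angstrom cutoff recovers the latent states
#' except at noise flips. Every residue participates in at most one dynamic
#' pair.
#'
#' @param n_residues total residue count.
#' @param atoms_per_residue beads per residue (1 to 8).
#' @param n_frames frames generated per trajectory.
#' @param modes list of modes; each mode is a list with `pairs` (2-column
#'   matrix/data.frame of residue pairs that switch together), `occupancy`
#'   (named numeric vector: class label -> contact probability in (0, 1)),
#'   and optionally `condition` (which manifest column the occupancies key
#'   on; default the first condition).
#' @param trajectories data.frame with column `id` plus one column per
#'   condition giving each trajectory's class labels.
#' @param n_background number of nuisance background pairs, each switching
#'   independently with an occupancy drawn uniformly in (0.2, 0.8).
#' @param flip_noise independent per-pair per-frame flip probability
#'   (0 <= eps < 0.5).
#' @param contact_dist,broken_dist pair separations (Angstrom) in the formed
#'   and broken state.
#' @param stride_ns frame spacing in ns (default 1.2).
#' @param seed integer RNG seed; generation is fully seed-deterministic.
#' @return validated list of class `SyntheticEnsembleSpec`.
#' @export
switching_spec <- function(n_residues, atoms_per_residue = 3, n_frames = 1000,
                           modes = list(), trajectories,
                           n_background = 0, flip_noise = 0,
                           contact_dist = 3.8, broken_dist = 8.0,
                           stride_ns = 1.2, seed = 1L) {
  stopifnot(n_residues >= 2, atoms_per_residue >= 1, atoms_per_residue <= 8,
            n_frames >= 1, flip_noise >= 0, flip_noise < 0.5,
            contact_dist > 0, broken_dist > contact_dist)
  stopifnot(is.data.frame(trajectories), "id" %in% names(trajectories),
            ncol(trajectories) >= 2)
  conditions <- setdiff(names(trajectories), "id")
  used <- integer(0)
  for (m in seq_along(modes)) {
    mode <- modes[[m]]
    p <- as.matrix(mode$pairs)
    stopifnot(ncol(p) == 2, all(p >= 1), all(p <= n_residues))
    if (any(p[, 1] >= p[, 2])) stop("mode pairs must have i < j")
    modes[[m]]$pairs <- p
    modes[[m]]$condition <- mode$condition %||% conditions[1]
    cls <- unique(trajectories[[modes[[m]]$condition]])
    if (!all(cls %in% names(mode$occupancy)))
      stop("mode ", m, " lacks an occupancy for class(es): ",
           paste(setdiff(cls, names(mode$occupancy)), collapse = ", "))
    if (any(mode$occupancy <= 0 | mode$occupancy >= 1))
      stop("occupancies must lie strictly in (0, 1)")
    used <- c(used, as.integer(p))
  }
  if (anyDuplicated(used))
    stop("planted contact sets must be disjoint (each residue in at most ",
         "one dynamic pair)")
  free <- setdiff(seq_len(n_residues), used)
  if (length(free) < 2 * n_background)
    stop("layout infeasible: ", n_background, " background pairs need ",
         2 * n_background, " unused residues but only ", length(free),
         " are available; increase n_residues")
  out <- list(n_residues = n_residues, atoms_per_residue = atoms_per_residue,
              n_frames = n_frames, modes = modes,
              trajectories = trajectories, conditions = conditions,
              n_background = n_background, flip_noise = flip_noise,
              contact_dist = contact_dist, broken_dist = broken_dist,
              stride_ns = stride_ns, seed = as.integer(seed))
  class(out) <- "SyntheticEnsembleSpec"
  out
}

# fixed bead offsets (radius 0.1 Angstrom) so any-atom distances track the
# residue separation to within 0.2 Angstrom
bead_offsets <- function(m) {
  dirs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1), c(1, 1, 1) / sqrt(3))
  0.1 * dirs[seq_len(m), , drop = FALSE]
}

#' Generate a labelled contact-switching ensemble with ground truth
#'
#' Realizes a [switching_spec()]: one block of `n_frames` frames per
#' trajectory row, pooled into a single `TrajectoryEnsemble` in row order.
#' Per frame, each mode draws one latent Bernoulli state from its occupancy
#' for the trajectory's class and places all of the mode's pairs accordingly;
#' background pairs switch independently; flip noise then toggles each
#' dynamic pair's geometric state independently with probability
#' `flip_noise`. All non-dynamic inter-residue distances exceed the broken
#' distance by construction.
#'
#' @param spec a `SyntheticEnsembleSpec`.
#' @return list with `trajectory` (`TrajectoryEnsemble`, pooled frames),
#'   `labeling` (per-frame data.frame: `trajectory_id` plus condition
#'   columns), and `truth` (list: `planted_pairs` data.frame with mode ids,
#'   `background_pairs` data.frame with drawn occupancies, `mode_states`
#'   frames x modes matrix of latent states, `pair_states` frames x pairs
#'   matrix of geometric states after noise, `pair_index` of all dynamic
#'   pairs in lexicographic order).
#' @export
generate_switching_ensemble <- function(spec) {
  stopifnot(inherits(spec, "SyntheticEnsembleSpec"))
  set.seed(spec$seed)
  nres <- spec$n_residues
  app <- spec$atoms_per_residue
  n_modes <- length(spec$modes)

  planted <- NULL
  for (m in seq_len(n_modes)) {
    p <- spec$modes[[m]]$pairs
    planted <- rbind(planted, data.frame(mode = m, i = p[, 1], j = p[, 2]))
  }
  used <- if (is.null(planted)) integer(0) else c(planted$i, planted$j)
  free <- setdiff(seq_len(nres), used)
  bg <- NULL
  if (spec$n_background > 0) {
    picks <- matrix(sample(free, 2 * spec$n_background), ncol = 2)
    bg <- data.frame(i = pmin(picks[, 1], picks[, 2]),
                     j = pmax(picks[, 1], picks[, 2]),
                     occupancy = stats::runif(spec$n_background, 0.2, 0.8))
  }
  dyn <- rbind(if (!is.null(planted)) planted[, c("i", "j")],
               if (!is.null(bg)) bg[, c("i", "j")])
  if (is.null(dyn) || nrow(dyn) == 0) stop("spec defines no dynamic pairs")

  # lattice layout: one site per dynamic pair and per unpaired residue
  anchored <- c(if (!is.null(planted)) planted$i, if (!is.null(bg)) bg$i)
  partner <- c(if (!is.null(planted)) planted$j, if (!is.null(bg)) bg$j)
  lone <- setdiff(seq_len(nres), c(anchored, partner))
  n_sites <- length(anchored) + length(lone)
  side <- ceiling(n_sites^(1 / 3))
  spacing <- 25
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(n_sites), ,
                                                    drop = FALSE] * spacing
  anchor_xyz <- matrix(NA_real_, nres, 3)
  anchor_xyz[anchored, ] <- grid[seq_along(anchored), , drop = FALSE]
  if (length(lone) > 0)
    anchor_xyz[lone, ] <- grid[length(anchored) + seq_along(lone), ,
                               drop = FALSE]
  # partners sit next to their anchor along +x; distance set per frame
  anchor_xyz[partner, ] <- anchor_xyz[anchored, , drop = FALSE]

  offs <- bead_offsets(app)
  base <- anchor_xyz[rep(seq_len(nres), each = app), ] +
    offs[rep(seq_len(app), nres), ]
  atoms <- data.frame(atom_id = seq_len(nres * app),
                      atom_name = paste0("B", rep(seq_len(app), nres)),
                      element = "C",
                      residue_index = rep(seq_len(nres), each = app),
                      residue_name = "BEA", chain_id = "A")
  struct <- structure_model(atoms, base)
  box <- rep(spacing * (side + 1) + 2 * spec$broken_dist, 3)

  traj_df <- spec$trajectories
  nt <- nrow(traj_df)
  nf_tot <- nt * spec$n_frames
  npair <- nrow(dyn)
  # latent mode states and geometric pair states, pooled over trajectories
  mode_states <- matrix(0L, nf_tot, max(n_modes, 1))
  pair_states <- matrix(0L, nf_tot, npair)
  labeling <- NULL
  for (t in seq_len(nt)) {
    rows <- (t - 1) * spec$n_frames + seq_len(spec$n_frames)
    for (m in seq_len(n_modes)) {
      cls <- as.character(traj_df[[spec$modes[[m]]$condition]][t])
      p <- spec$modes[[m]]$occupancy[[cls]]
      mode_states[rows, m] <- stats::rbinom(spec$n_frames, 1, p)
    }
    lab <- traj_df[rep(t, spec$n_frames), , drop = FALSE]
    names(lab)[names(lab) == "id"] <- "trajectory_id"
    labeling <- rbind(labeling, lab)
  }
  rownames(labeling) <- NULL
  col <- 0
  if (!is.null(planted))
    for (r in seq_len(nrow(planted)))
      pair_states[, (col <- col + 1)] <- mode_states[, planted$mode[r]]
  if (!is.null(bg))
    for (r in seq_len(nrow(bg)))
      pair_states[, (col <- col + 1)] <-
        stats::rbinom(nf_tot, 1, bg$occupancy[r])
  if (spec$flip_noise > 0) {
    flips <- matrix(stats::rbinom(nf_tot * npair, 1, spec$flip_noise),
                    nf_tot, npair)
    pair_states <- (pair_states + flips) %% 2L
  }

  # realize coordinates: partner residues shift along +x by the pair distance
  partner_atom_rows <- lapply(seq_len(npair), function(d)
    which(rep(seq_len(nres), each = app) == dyn$j[d]))
  coords <- vector("list", nf_tot)
  for (f in seq_len(nf_tot)) {
    x <- base
    sep <- ifelse(pair_states[f, ] == 1L, spec$contact_dist,
                  spec$broken_dist)
    for (d in seq_len(npair))
      x[partner_atom_rows[[d]], 1] <- x[partner_atom_rows[[d]], 1] + sep[d]
    coords[[f]] <- x
  }
  traj <- trajectory_ensemble(struct, coords, box = box,
                              stride_ns = spec$stride_ns)

  ord <- order(dyn$i, dyn$j)
  truth <- list(planted_pairs = planted, background_pairs = bg,
                mode_states = mode_states[, seq_len(n_modes), drop = FALSE],
                pair_states = pair_states,
                pair_index = dyn,
                pair_index_sorted = dyn[ord, , drop = FALSE],
                sort_order = ord)
  list(trajectory = traj, labeling = labeling, truth = truth)
}

#' Generate a solvated membrane-slab world with known crossing events
#'
#' Simulates continuous biased-random-walk particle paths first, extracts the
#' true crossing events from the continuous paths with a direct per-step
#' state machine, and only then wraps coordinates into the periodic box, so
#' the recorded events are ground truth for [count_crossings()] run on the
#' wrapped trajectory.
#'
#' @param n_particles,n_frames walk dimensions.
#' @param box length-3 box edges in Angstrom (membrane normal = z).
#' @param slab `c(z_low, z_high)` slab bounds along z, inside the box.
#' @param drift per-frame mean z displacement: scalar for all particles or a
#'   length-`n_particles` vector.
#' @param diffusion per-frame displacement standard deviation (Angstrom).
#' @param seed integer RNG seed.
#' @return list with `trajectory` (`TrajectoryEnsemble` of wrapped
#'   single-bead water particles), `truth` (list: `paths_z` frames x
#'   particles continuous z, `events` data.frame as in [count_crossings()]).
#' @export
generate_slab_world <- function(n_particles = 100, n_frames = 500,
                                box = c(40, 40, 60), slab = c(20, 40),
                                drift = 0.5, diffusion = 1.0, seed = 1L) {
  stopifnot(length(slab) == 2, slab[1] < slab[2], slab[1] >= 0,
            slab[2] <= box[3])
  step_bound <- abs(drift) + 6 * diffusion
  if (any(step_bound >= box[3] / 2))
    stop("step size can reach half the box edge; unwrapping would be ",
         "ambiguous by construction (reduce drift/diffusion)")
  set.seed(seed)
  if (length(drift) == 1) drift <- rep(drift, n_particles)
  stopifnot(length(drift) == n_particles)
  z0 <- stats::runif(n_particles, 0, box[3])
  steps <- matrix(stats::rnorm((n_frames - 1) * n_particles, mean = 0,
                               sd = diffusion), n_frames - 1, n_particles)
  steps <- sweep(steps, 2, drift, "+")
  paths <- apply(rbind(z0, steps), 2, cumsum)
  events <- extract_true_crossings(paths, slab, box[3])

  xy <- array(stats::runif(n_frames * n_particles * 2, 0, box[1]),
              dim = c(n_frames, n_particles, 2))
  zw <- paths %% box[3]
  atoms <- data.frame(atom_id = seq_len(n_particles), atom_name = "OW",
                      element = "O", residue_index = seq_len(n_particles),
                      residue_name = "WAT", chain_id = "W")
  coords <- lapply(seq_len(n_frames), function(f)
    cbind(xy[f, , 1], xy[f, , 2], zw[f, ]))
  struct <- structure_model(atoms, coords[[1]])
  traj <- trajectory_ensemble(struct, coords, box = box, stride_ns = 0.002)
  list(trajectory = traj,
       truth = list(paths_z = paths, events = events, slab = slab,
                    box = box))
}

# direct per-step state machine on the continuous (never wrapped) paths;
# slab images replicated every box length. Boundary ties count as inside.
extract_true_crossings <- function(paths, slab, box_z) {
  width <- slab[2] - slab[1]
  zone <- function(s) {
    k <- floor((s - slab[1]) / box_z)
    if (s - slab[1] - k * box_z <= width) c(2 * k, NA) else c(NA, 2 * k + 1)
  }
  events <- NULL
  for (p in seq_len(ncol(paths))) {
    s <- paths[, p]
    outside <- NA_real_   # last water level occupied
    pend_start <- NA_integer_
    pend_side <- NA_real_
    for (t in seq_along(s)) {
      z <- zone(s[t])
      if (!is.na(z[2])) {                      # in water level z[2]
        if (!is.na(pend_start) && pend_side != z[2]) {
          events <- rbind(events, data.frame(
            particle_id = p, start_frame = pend_start, end_frame = t,
            direction = if (z[2] > pend_side) 1L else -1L))
        }
        pend_start <- NA_integer_
        pend_side <- NA_real_
        outside <- z[2]
      } else {                                 # inside a slab image
        if (is.na(pend_start) && !is.na(outside)) {
          pend_start <- t
          pend_side <- outside
        }
      }
    }
  }
  if (is.null(events))
    events <- data.frame(particle_id = integer(0), start_frame = integer(0),
                         end_frame = integer(0), direction = integer(0))
  rownames(events) <- NULL
  events
}

#' Generate a hydrogen-bond triad fixture with a planned satisfied count
#'
#' Places `n_triads` donor-hydrogen-acceptor triads on a sparse lattice
#' (20 Angstrom spacing, so triads never interact). Exactly
#' `round(n_triads * satisfied_fraction)` triads are built to satisfy the
#' criteria (donor-acceptor distance below the distance cutoff and
#' donor-centered angle below the angle cutoff); the rest violate the
#' distance, the angle, or both.
#'
#' @param n_triads number of triads.
#' @param satisfied_fraction planned fraction in \code{[0, 1]}.
#' @param distance_cutoff_A,angle_cutoff_deg the criteria the plan targets
#'   (defaults 3.5 Angstrom, 20 degrees).
#' @param seed integer RNG seed.
#' @return list with `coords` (3 atoms per triad: donor, hydrogen,
#'   acceptor), `donors` (n x 2 matrix), `acceptors` (indices), `criteria`
#'   (list), `truth` (list: `satisfied` logical per triad, `n_satisfied`).
#' @export
generate_hbond_fixture <- function(n_triads = 50, satisfied_fraction = 0.4,
                                   distance_cutoff_A = 3.5,
                                   angle_cutoff_deg = 20, seed = 1L) {
  stopifnot(satisfied_fraction >= 0, satisfied_fraction <= 1)
  set.seed(seed)
  n_sat <- round(n_triads * satisfied_fraction)
  satisfied <- sample(rep(c(TRUE, FALSE), c(n_sat, n_triads - n_sat)))
  side <- ceiling(n_triads^(1 / 3))
  grid <- as.matrix(expand.grid(seq_len(side), seq_len(side),
                                seq_len(side)))[seq_len(n_triads), ,
                                                drop = FALSE] * 20
  rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  coords <- matrix(NA_real_, 3 * n_triads, 3)
  for (q in seq_len(n_triads)) {
    d <- grid[q, ]
    u <- rand_unit()
    if (satisfied[q]) {
      r <- stats::runif(1, 2.6, distance_cutoff_A - 0.1)
      theta <- stats::runif(1, 0, (angle_cutoff_deg - 2) * pi / 180)
    } else {
      kind <- sample(3, 1)
      r <- if (kind %in% c(1, 3)) stats::runif(1, distance_cutoff_A + 0.1, 6)
           else stats::runif(1, 2.6, distance_cutoff_A - 0.1)
      theta <- if (kind %in% c(2, 3))
        stats::runif(1, (angle_cutoff_deg + 2) * pi / 180, 70 * pi / 180)
      else stats::runif(1, 0, (angle_cutoff_deg - 2) * pi / 180)
    }
    a <- d + r * u
    perp <- rand_unit()
    perp <- perp - sum(perp * u) * u
    perp <- perp / sqrt(sum(perp^2))
    h <- d + 1.0 * (cos(theta) * u + sin(theta) * perp)
    coords[3 * (q - 1) + 1:3, ] <- rbind(d, h, a)
  }
  idx <- 3 * (seq_len(n_triads) - 1)
  list(coords = coords,
       donors = cbind(donor = idx + 1, hydrogen = idx + 2),
       acceptors = idx + 3,
       criteria = list(distance_cutoff_A = distance_cutoff_A,
                       angle_cutoff_deg = angle_cutoff_deg),
       truth = list(satisfied = satisfied, n_satisfied = n_sat))
}

#' Generate a lipid-shell fixture with planted radial enrichment
#'
#' Marker particles (e.g. lipid headgroup phosphorus beads) are placed by
#' thinned uniform sampling around a single central protein bead: candidate
#' positions are uniform in the box, and candidates farther than
#' `inner_radius` from the centre are kept with probability
#' `1 / enrichment_factor`, so the number density inside the inner shell is
#' `enrichment_factor` times the outside density in expectation.
#'
#' @param n_markers markers to place.
#' @param enrichment_factor density ratio inside vs outside (>= 1).
#' @param inner_radius enriched-shell radius, Angstrom.
#' @param box cubic box edge, Angstrom.
#' @param seed integer RNG seed.
#' @return list with `coords` (row 1 = protein bead at the box centre, then
#'   markers), `protein_subset`, `marker_subset`, `box`, `truth` (list:
#'   `enrichment_factor`, `inner_radius`, `n_inner`, `n_outer`).
#' @export
generate_lipid_shell_fixture <- function(n_markers = 2000,
                                         enrichment_factor = 3,
                                         inner_radius = 10, box = 80,
                                         seed = 1L) {
  stopifnot(enrichment_factor >= 1, inner_radius > 0, box > 4 * inner_radius)
  set.seed(seed)
  centre <- rep(box / 2, 3)
  got <- 0
  markers <- matrix(NA_real_, n_markers, 3)
  while (got < n_markers) {
    cand <- matrix(stats::runif(3000, 0, box), ncol = 3)
    r <- sqrt(rowSums(sweep(cand, 2, centre)^2))
    keep <- r <= inner_radius | stats::runif(nrow(cand)) < 1 / enrichment_factor
    cand <- cand[keep, , drop = FALSE]
    take <- min(nrow(cand), n_markers - got)
    if (take > 0) markers[got + seq_len(take), ] <- cand[seq_len(take), ]
    got <- got + take
  }
  r <- sqrt(rowSums(sweep(markers, 2, centre)^2))
  list(coords = rbind(centre, markers), protein_subset = 1,
       marker_subset = 1 + seq_len(n_markers), box = rep(box, 3),
       truth = list(enrichment_factor = enrichment_factor,
                    inner_radius = inner_radius,
                    n_inner = sum(r <= inner_radius),
                    n_outer = sum(r > inner_radius)))
}
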