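#' Per-frame binary residue-residue contact state
#'
#' Two residues i and j are in contact in a frame when any atom of residue i
#' lies within `cutoff_A` of any atom of residue j. All residue pairs are
#' evaluated, with no sequence-separation exclusion (covalently adjacent pairs
#' are near-permanent contacts and are removed later by the static filter).
#' With a periodic `box`, atom-atom distances use the minimum-image
#' convention.
#'
#' @param coords atoms x 3 coordinate matrix for one frame (Angstrom).
#' @param structure the `StructureModel` assigning atoms to residues.
#' @param cutoff_A contact distance cutoff (default 4.2 Angstrom).
#' @param box optional length-3 orthorhombic box; a warning is issued when an
#'   edge is shorter than twice the cutoff (minimum-image ambiguity).
#' @return object of class `ContactState`: list with `n_residues` and the
#'   symmetric binary matrix `u` (diagonal 0).
#' @export
compute_contact_state <- function(coords, structure, cutoff_A = 4.2,
                                  box = NULL) {
  stopifnot(cutoff_A > 0)
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  nr <- n_residues(structure)
  if (nr == 0) stop("structure has zero residues")
  box <- check_box(box)
  if (!is.null(box) && any(box < 2 * cutoff_A))
    warning("box edge shorter than twice the contact cutoff; ",
            "minimum-image contacts may be ambiguous")
  d2 <- pairwise_sq_dists(coords, box)
  close_atoms <- (d2 <= cutoff_A^2) * 1L
  g <- structure$residue_id
  # aggregate atom-level adjacency to residue level: any atom pair in range
  per_res <- rowsum(close_atoms, g)
  per_pair <- t(rowsum(t(per_res), g))
  u <- (per_pair > 0) * 1L
  diag(u) <- 0L
  dimnames(u) <- NULL
  out <- list(n_residues = nr, u = u)
  class(out) <- "ContactState"
  out
}

#' Contact states for every frame of a trajectory
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param cutoff_A contact cutoff in Angstrom.
#' @param periodic use each frame's box (minimum image) when available.
#' @return list of `ContactState`, one per frame.
#' @export
contact_states <- function(traj, cutoff_A = 4.2, periodic = TRUE) {
  lapply(seq_len(n_frames(traj)), function(f)
    compute_contact_state(traj$coords[[f]], traj$structure, cutoff_A,
                          box = if (periodic && !is.null(traj$box))
                            traj$box[f, ] else NULL))
}

#' Mean contact matrix over an ensemble of contact states
#'
#' Element (i, j) is the fraction of frames in which residues i and j are in
#' contact (the pair's contact frequency).
#'
#' @param states list of `ContactState` with equal residue counts.
#' @return object of class `MeanContactMatrix`: list with `n_residues`,
#'   `mean_u` (symmetric, entries in \code{[0, 1]}) and `n_frames`.
#' @export
compute_mean_contact_matrix <- function(states) {
  if (length(states) < 1) stop("need at least one contact state")
  nr <- states[[1]]$n_residues
  for (s in states)
    if (s$n_residues != nr)
      stop("contact states have mixed residue counts")
  acc <- matrix(0, nr, nr)
  for (s in states) acc <- acc + s$u
  out <- list(n_residues = nr, mean_u = acc / length(states),
              n_frames = length(states))
  class(out) <- "MeanContactMatrix"
  out
}

#' Select dynamic contacts by mean contact frequency
#'
#' Residue pairs whose contact frequency lies strictly between `u_low` and
#' `u_high` are the dynamic contact degrees of freedom; pairs at or beyond
#' the bounds (never/nearly-never or nearly-always formed) are static and
#' dropped. Boundary values are excluded: a pair formed in exactly 90% of
#' frames is static under the default `u_high = 0.9`.
#'
#' @param mean a `MeanContactMatrix`.
#' @param u_low,u_high frequency window, `0 <= u_low < u_high <= 1`.
#' @return data.frame `pair_index` with integer columns `i < j`, sorted
#'   lexicographically.
#' @export
select_dynamic_contacts <- function(mean, u_low = 0.1, u_high = 0.9) {
  stopifnot(u_low >= 0, u_high <= 1, u_low < u_high)
  m <- mean$mean_u
  idx <- which(upper.tri(m) & m > u_low & m < u_high, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
}

#' Assemble the frames x dynamic-contacts trajectory matrix
#'
#' Column d of `X` holds the binary state of `pair_index[d, ]` across frames;
#' this matrix is the input coordinate system for contact PCA.
#'
#' @param states list of `ContactState`, one per frame (frames may be pooled
#'   from several trajectories).
#' @param pair_index data.frame with columns `i`, `j` as returned by
#'   [select_dynamic_contacts()].
#' @param frame_ids optional provenance data.frame (e.g. trajectory_id,
#'   frame) with one row per frame.
#' @param labels optional per-frame class label data.frame (conditions as
#'   columns).
#' @return object of class `ContactTrajectory`: list with `X` (binary
#'   frames x D matrix), `pair_index`, `n_residues`, `frame_ids`, `labels`.
#' @export
build_contact_trajectory <- function(states, pair_index, frame_ids = NULL,
                                     labels = NULL) {
  if (is.null(pair_index) || nrow(pair_index) == 0)
    stop("empty dynamic pair list; widen the (u_low, u_high) bounds")
  stopifnot(all(pair_index$i < pair_index$j))
  nf <- length(states)
  nr <- states[[1]]$n_residues
  lin <- (pair_index$j - 1L) * nr + pair_index$i  # column-major index into u
  X <- t(vapply(states, function(s) s$u[lin], numeric(length(lin))))
  if (length(lin) == 1) X <- matrix(X, ncol = 1)
  if (!is.null(frame_ids)) stopifnot(nrow(frame_ids) == nf)
  if (!is.null(labels)) stopifnot(nrow(labels) == nf)
  out <- list(X = X, pair_index = pair_index, n_residues = nr,
              frame_ids = frame_ids, labels = labels)
  class(out) <- "ContactTrajectory"
  out
}

#' @export
print.ContactTrajectory <- function(x, ...) {
  cat(sprintf("ContactTrajectory: %d frames x %d dynamic contacts (%d residues)\n",
              nrow(x$X), ncol(x$X), x$n_residues))
  invisible(x)
}

#' Full contact pipeline for one or more trajectories
#'
#' Convenience wrapper: computes per-frame contact states over the pooled
#' frames of `trajs`, the pooled mean contact matrix, selects dynamic
#' contacts, and assembles the `ContactTrajectory`.
#'
#' @param trajs a `TrajectoryEnsemble` or list of them (pooled in order).
#' @param config a [run_config()].
#' @param labels optional per-trajectory label data.frame (one row per
#'   trajectory, condition columns); expanded to frames.
#' @return list with `states`, `mean` (`MeanContactMatrix`), `pair_index`,
#'   and `ct` (`ContactTrajectory`).
#' @export
contact_pipeline <- function(trajs, config = run_config(), labels = NULL) {
  if (inherits(trajs, "TrajectoryEnsemble")) trajs <- list(trajs)
  states <- list()
  frame_ids <- NULL
  frame_labels <- NULL
  for (t in seq_along(trajs)) {
    st <- contact_states(trajs[[t]], config$contact_cutoff_A)
    states <- c(states, st)
    fid <- data.frame(trajectory = t, frame = seq_along(st))
    frame_ids <- rbind(frame_ids, fid)
    if (!is.null(labels))
      frame_labels <- rbind(frame_labels,
                            labels[rep(t, length(st)), , drop = FALSE])
  }
  mcm <- compute_mean_contact_matrix(states)
  pairs <- select_dynamic_contacts(mcm, config$u_low, config$u_high)
  ct <- build_contact_trajectory(states, pairs, frame_ids, frame_labels)
  list(states = states, mean = mcm, pair_index = pairs, ct = ct)
}
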