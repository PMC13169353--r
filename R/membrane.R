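#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation that minimize the
#' mean squared deviation of `mobile[subset, ]` from `reference[subset, ]`.
#'
#' @param mobile,reference atoms x 3 coordinate matrices.
#' @param subset integer indices of atoms to superpose on (default all);
#'   needs >= 3 non-collinear atoms.
#' @return list with `rotation` (3 x 3, applied to centered mobile
#'   coordinates), `translation`, `rmsd` (Angstrom over the subset), and
#'   `transform(x)` applying the fit to arbitrary coordinates.
#' @export
superpose <- function(mobile, reference, subset = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  subset <- subset %||% seq_len(nrow(mobile))
  if (length(subset) < 3) stop("need at least 3 subset atoms")
  m <- mobile[subset, , drop = FALSE]
  r <- reference[subset, , drop = FALSE]
  cm <- colMeans(m)
  cr <- colMeans(r)
  m0 <- sweep(m, 2, cm)
  r0 <- sweep(r, 2, cr)
  sv <- svd(crossprod(m0, r0))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) atom subset: superposition ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- m0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - r0)^2)))
  list(rotation = R, translation = cr, center = cm, rmsd = rmsd,
       transform = function(x) sweep(sweep(as.matrix(x), 2, cm) %*% t(R),
                                     2, cr, "+"))
}

#' Per-frame RMSD after superposition to a reference
#'
#' Each frame is rigid-body superposed onto the reference over `subset`
#' before the RMSD is taken; no chain-swap minimization is attempted for
#' multimers.
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param reference reference coordinates (atoms x 3) or a frame index into
#'   `traj` (default frame 1, i.e. the initial structure).
#' @param subset atom indices used for both the fit and the RMSD (default
#'   all atoms).
#' @return a `ScalarSeries` list: `name`, `times` (ns), `values` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = 1, subset = NULL) {
  ref <- if (is.matrix(reference)) reference else traj$coords[[reference]]
  vals <- vapply(traj$coords, function(x) superpose(x, ref, subset)$rmsd,
                 numeric(1))
  scalar_series("rmsd", traj$times, vals)
}

scalar_series <- function(name, times, values) {
  stopifnot(length(times) == length(values), all(is.finite(values)))
  out <- list(name = name, times = times, values = values)
  class(out) <- "ScalarSeries"
  out
}

#' @export
print.ScalarSeries <- function(x, ...) {
  cat(sprintf("ScalarSeries '%s': %d points, mean %.4g, sd %.4g\n", x$name,
              length(x$values), mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Radius of gyration of a coordinate set
#'
#' `sqrt(sum_a w_a |r_a - r_com|^2 / sum_a w_a)` over the selected atoms.
#'
#' @param coords atoms x 3 matrix (Angstrom).
#' @param subset atom indices (default all).
#' @param weights per-subset-atom weights (e.g. masses); default uniform.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(coords, subset = NULL, weights = NULL) {
  coords <- as.matrix(coords)
  subset <- subset %||% seq_len(nrow(coords))
  x <- coords[subset, , drop = FALSE]
  w <- weights %||% rep(1, nrow(x))
  stopifnot(length(w) == nrow(x))
  if (sum(w) <= 0) stop("total weight must be positive")
  com <- colSums(x * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(x, 2, com)^2)) / sum(w))
}

#' Radius-of-gyration time series
#' @inheritParams rmsd_series
#' @param weights optional per-subset-atom weights.
#' @return a `ScalarSeries` in Angstrom.
#' @export
rg_series <- function(traj, subset = NULL, weights = NULL) {
  vals <- vapply(traj$coords, radius_of_gyration, numeric(1),
                 subset = subset, weights = weights)
  scalar_series("rg", traj$times, vals)
}

#' Protein-bilayer center-of-mass displacement along the membrane normal
#'
#' Per frame, the signed projection of (COM of the protein subset minus COM
#' of the bilayer subset) onto the membrane normal axis; the unsigned
#' magnitude is carried alongside.
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param protein_subset,bilayer_subset non-empty atom index vectors.
#' @param axis `"x"`, `"y"` or `"z"` (default `"z"`).
#' @param weights_protein,weights_bilayer optional per-atom weights.
#' @return a `ScalarSeries` (signed, Angstrom) with an extra `magnitude`
#'   field.
#' @export
com_displacement_along_normal <- function(traj, protein_subset,
                                          bilayer_subset,
                                          axis = c("z", "x", "y"),
                                          weights_protein = NULL,
                                          weights_bilayer = NULL) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  if (length(protein_subset) == 0 || length(bilayer_subset) == 0)
    stop("protein and bilayer subsets must be non-empty")
  wcom <- function(x, idx, w) {
    xs <- x[idx, , drop = FALSE]
    w <- w %||% rep(1, nrow(xs))
    colSums(xs * w) / sum(w)
  }
  vals <- vapply(traj$coords, function(x)
    (wcom(x, protein_subset, weights_protein) -
       wcom(x, bilayer_subset, weights_bilayer))[ai], numeric(1))
  out <- scalar_series(paste0("com_displacement_", axis), traj$times, vals)
  out$magnitude <- abs(vals)
  out
}

#' Count hydrogen bonds in one frame
#'
#' Donor-centered geometric criterion: a donor-acceptor pair is hydrogen
#' bonded when the donor-heavy-atom to acceptor distance is at most
#' `distance_cutoff_A` and the angle between the donor-to-hydrogen and
#' donor-to-acceptor vectors is at most `angle_cutoff_deg`. (Note other
#' conventions measure the D-H...A angle with a >= 160 degree cutoff; this
#' function uses the donor-centered deviation angle.) Minimum-image distances
#' are used when `box` is given.
#'
#' @param coords atoms x 3 coordinate matrix.
#' @param donors 2-column integer matrix or data.frame: donor heavy atom
#'   index, attached hydrogen index. Donors whose hydrogen index is missing
#'   (NA) are skipped with a warning.
#' @param acceptors integer vector of acceptor atom indices.
#' @param distance_cutoff_A,angle_cutoff_deg geometric cutoffs (defaults
#'   3.5 Angstrom, 20 degrees).
#' @param box optional periodic box.
#' @return list with `count` and `bonds` data.frame (`donor`, `hydrogen`,
#'   `acceptor`, `distance_A`, `angle_deg`).
#' @export
count_hbonds <- function(coords, donors, acceptors, distance_cutoff_A = 3.5,
                         angle_cutoff_deg = 20, box = NULL) {
  coords <- as.matrix(coords)
  donors <- as.matrix(donors)
  stopifnot(ncol(donors) == 2)
  box <- check_box(box)
  bad <- is.na(donors[, 2])
  if (any(bad)) {
    warning(sum(bad), " donor(s) without an attached hydrogen skipped")
    donors <- donors[!bad, , drop = FALSE]
  }
  res <- NULL
  for (r in seq_len(nrow(donors))) {
    d <- donors[r, 1]
    h <- donors[r, 2]
    da <- sweep(coords[acceptors, , drop = FALSE], 2, coords[d, ])
    if (!is.null(box)) for (k in 1:3) da[, k] <- min_image(da[, k], box[k])
    dist <- sqrt(rowSums(da^2))
    dh <- coords[h, ] - coords[d, ]
    if (!is.null(box)) dh <- min_image(dh, box)
    cosang <- (da %*% dh) / (dist * sqrt(sum(dh^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hit <- which(dist <= distance_cutoff_A & ang <= angle_cutoff_deg &
                   acceptors != d & acceptors != h)
    if (length(hit) > 0)
      res <- rbind(res, data.frame(donor = d, hydrogen = h,
                                   acceptor = acceptors[hit],
                                   distance_A = dist[hit],
                                   angle_deg = ang[hit]))
  }
  if (is.null(res))
    res <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance_A = numeric(0),
                      angle_deg = numeric(0))
  list(count = nrow(res), bonds = res)
}

#' Unwrap a periodically wrapped coordinate series
#'
#' Accumulates minimum-image frame-to-frame increments into a continuous
#' series; assumes true displacements between consecutive frames are smaller
#' than half the box (warns when a wrapped jump is exactly ambiguous).
#'
#' @param x numeric vector (one particle) or frames x particles matrix of
#'   wrapped coordinates along one axis.
#' @param box box edge along the axis: scalar or per-frame vector.
#' @return continuous series, same shape as `x`, anchored at the first frame.
#' @export
unwrap_axis <- function(x, box) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  nf <- nrow(x)
  if (length(box) == 1) box <- rep(box, nf)
  stopifnot(length(box) == nf)
  if (nf == 1) return(if (vec) x[, 1] else x)
  d <- diff(x)
  b <- box[-1]
  if (any(abs(abs(d) - b / 2) < 1e-9))
    warning("frame-to-frame jump of exactly half a box edge; ",
            "unwrap direction ambiguous, resolved toward the smaller jump")
  d <- d - b * round(d / b)
  out <- apply(rbind(x[1, ], d), 2, cumsum)
  if (vec) out[, 1] else out
}

# region level of an unwrapped coordinate relative to the periodically
# replicated slab [z_low, z_high] + k*box: even levels 2k = inside slab image
# k, odd levels 2k+1 = water between slab k and slab k+1. Boundary ties count
# as inside.
slab_region_level <- function(s, z_low, z_high, box) {
  width <- z_high - z_low
  k <- floor((s - z_low) / box)
  r <- s - z_low - k * box
  ifelse(r <= width, 2 * k, 2 * k + 1)
}

#' Count complete membrane crossing events
#'
#' Tracks each particle's unwrapped coordinate along the membrane normal and
#' records an event whenever the particle passes from strictly below the slab
#' lower bound to strictly above the upper bound (direction +1) or the
#' reverse (-1), with arbitrary residence inside the slab in between. A
#' particle that enters the slab and retreats out the same side produces no
#' event; positions exactly at a boundary count as inside. Periodic images of
#' the slab are honoured, so a particle drifting through several box lengths
#' is credited one event per traversal.
#'
#' @param z frames x particles matrix (or vector for one particle) of wrapped
#'   coordinates along the membrane normal, in Angstrom.
#' @param box box edge along the normal (scalar or per-frame).
#' @param slab length-2 vector `c(z_low, z_high)`, `z_low < z_high`.
#' @param unwrap set `FALSE` when `z` is already continuous.
#' @return data.frame of crossing events: `particle_id`, `start_frame`
#'   (first frame inside the slab), `end_frame` (first frame beyond the far
#'   boundary), `direction` (+1 with increasing coordinate, -1 otherwise).
#' @export
count_crossings <- function(z, box, slab, unwrap = TRUE) {
  stopifnot(length(slab) == 2, slab[1] < slab[2])
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  b0 <- if (length(box) == 1) box else box[1]
  s <- if (unwrap) unwrap_axis(z, box) else z
  if (is.null(dim(s))) s <- matrix(s, ncol = 1)
  events <- NULL
  for (p in seq_len(ncol(s))) {
    lev <- slab_region_level(s[, p], slab[1], slab[2], b0)
    rl <- rle(lev)
    ends <- cumsum(rl$lengths)
    starts <- as.integer(ends - rl$lengths + 1L)
    v <- rl$values
    for (q in seq_along(v)) {
      if (q == 1 || q == length(v)) next
      if (v[q] %% 2 == 0 && v[q - 1] != v[q + 1]) {  # slab run, sides differ
        dir <- if (v[q + 1] > v[q - 1]) 1L else -1L
        events <- rbind(events,
                       data.frame(particle_id = p, start_frame = starts[q],
                                  end_frame = starts[q + 1], direction = dir))
      }
    }
  }
  if (is.null(events))
    events <- data.frame(particle_id = integer(0), start_frame = integer(0),
                         end_frame = integer(0), direction = integer(0))
  rownames(events) <- NULL
  events
}

#' Lipid radial number density around a protein
#'
#' For each marker atom (e.g. a lipid headgroup phosphorus), the distance to
#' the nearest protein atom is computed (minimum image when `box` is given);
#' marker counts per radial shell are averaged over frames and divided by the
#' spherical-shell volume.
#'
#' @param frames list of atoms x 3 coordinate matrices (or a single matrix).
#' @param marker_subset,protein_subset atom index vectors.
#' @param shell_edges strictly increasing radial edges in Angstrom.
#' @param box optional periodic box.
#' @return object of class `RadialDensityProfile`: list with `shell_edges`,
#'   `counts` (mean per-frame marker count per shell), `density`
#'   (count / Angstrom^3), `n_frames`.
#' @export
lipid_radial_density <- function(frames, marker_subset, protein_subset,
                                 shell_edges, box = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(marker_subset) >= 1)
  if (length(protein_subset) == 0) stop("protein subset must be non-empty")
  if (any(diff(shell_edges) <= 0))
    stop("shell edges must be strictly increasing")
  box <- check_box(box)
  nsh <- length(shell_edges) - 1
  acc <- numeric(nsh)
  for (x in frames) {
    d2 <- cross_sq_dists(x[marker_subset, , drop = FALSE],
                         x[protein_subset, , drop = FALSE], box)
    dmin <- sqrt(apply(d2, 1, min))
    dmin <- dmin[dmin >= shell_edges[1] & dmin <= shell_edges[nsh + 1]]
    bin <- findInterval(dmin, shell_edges, rightmost.closed = TRUE)
    acc <- acc + tabulate(bin, nbins = nsh)
  }
  counts <- acc / length(frames)
  vol <- 4 / 3 * pi * diff(shell_edges^3)
  out <- list(shell_edges = shell_edges, counts = counts,
              density = counts / vol, n_frames = length(frames))
  class(out) <- "RadialDensityProfile"
  out
}
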