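#' Trajectory ensemble container
#'
#' A `TrajectoryEnsemble` is an ordered list of coordinate frames over a fixed
#' [structure_model()], each frame carrying an (optional) orthorhombic
#' periodic box and a time stamp in nanoseconds.
#'
#' @param structure a `StructureModel`.
#' @param coords list of atoms x 3 numeric matrices (Angstrom), one per frame.
#' @param box `NULL` (non-periodic), a length-3 vector applied to every frame,
#'   or a frames x 3 matrix of per-frame box edges (Angstrom).
#' @param times numeric vector of frame times in ns, strictly increasing.
#'   Defaults to `stride_ns * (1:n_frames)`.
#' @param stride_ns time between retained frames in ns (default 1, or inferred
#'   from `times` when given).
#' @return object of class `TrajectoryEnsemble`.
#' @export
trajectory_ensemble <- function(structure, coords, box = NULL, times = NULL,
                                stride_ns = NULL) {
  stopifnot(inherits(structure, "StructureModel"), is.list(coords),
            length(coords) >= 1)
  na <- nrow(structure$xyz)
  for (f in seq_along(coords)) {
    coords[[f]] <- as.matrix(coords[[f]])
    if (nrow(coords[[f]]) != na || ncol(coords[[f]]) != 3)
      stop("frame ", f, " has ", nrow(coords[[f]]),
           " atoms; structure has ", na, " (topology mismatch)")
  }
  nf <- length(coords)
  if (!is.null(box)) {
    if (is.matrix(box)) {
      stopifnot(nrow(box) == nf, ncol(box) == 3)
    } else {
      box <- matrix(rep(check_box(box), each = nf), nf, 3)
    }
    if (any(box <= 0)) stop("box edges must be positive")
  }
  if (is.null(times)) {
    stride_ns <- stride_ns %||% 1
    times <- stride_ns * seq_len(nf)
  } else {
    stopifnot(length(times) == nf)
    if (nf > 1 && any(diff(times) <= 0))
      stop("frame times must be strictly increasing")
    stride_ns <- stride_ns %||% (if (nf > 1) stats::median(diff(times)) else 1)
  }
  out <- list(structure = structure, coords = coords, box = box,
              times = as.numeric(times), stride_ns = stride_ns)
  class(out) <- "TrajectoryEnsemble"
  out
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf(paste0("TrajectoryEnsemble: %d frames x %d atoms ",
                     "(%d residues), stride %.4g ns, %s\n"),
              n_frames(x), nrow(x$structure$xyz), n_residues(x$structure),
              x$stride_ns,
              if (is.null(x$box)) "non-periodic" else "periodic"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `TrajectoryEnsemble`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Subsample a trajectory by a stride
#'
#' Keeps every `stride`-th frame starting from the first. Striding by `s` then
#' by `t` equals striding once by `s * t`.
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param stride positive integer.
#' @return a `TrajectoryEnsemble` with `ceiling(n_frames / stride)` frames.
#' @export
stride_trajectory <- function(traj, stride) {
  stopifnot(stride >= 1, stride == round(stride))
  keep <- seq(1, n_frames(traj), by = stride)
  trajectory_ensemble(traj$structure, traj$coords[keep],
                      box = if (is.null(traj$box)) NULL else
                        traj$box[keep, , drop = FALSE],
                      times = traj$times[keep],
                      stride_ns = traj$stride_ns * stride)
}

#' Read a trajectory file
#'
#' Supported dialects: multi-model PDB (MODEL/ENDMDL records, per-model CRYST1
#' boxes honoured) and binary DCD (read through \pkg{bio3d}; unit-cell
#' information used when present). Frame times are synthesized as
#' `stride_ns * frame` when the file carries none.
#'
#' @param structure the `StructureModel` the frames belong to; atom counts
#'   must match.
#' @param path trajectory file path.
#' @param format `"pdb"` (multi-model) or `"dcd"`; default guesses from the
#'   extension.
#' @param stride keep every `stride`-th frame (default 1).
#' @param stride_ns time per retained frame in ns; when `NULL` and the file
#'   has no times, 1 ns is assumed.
#' @param total_time_ns alternative to `stride_ns`: the simulation time span
#'   the file covers; the per-frame stride is recomputed as
#'   `total_time_ns / n_frames` (e.g. 2000 frames exported over 2400 ns give
#'   1.2 ns/frame).
#' @param periodic set `FALSE` to accept files without box information.
#' @return a `TrajectoryEnsemble`.
#' @export
read_trajectory <- function(structure, path, format = c("auto", "pdb", "dcd"),
                            stride = 1, stride_ns = NULL, total_time_ns = NULL,
                            periodic = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "dcd") "dcd" else "pdb"
  }
  raw <- if (format == "dcd") read_traj_dcd(path) else read_traj_multipdb(path)
  na <- nrow(structure$xyz)
  for (f in seq_along(raw$coords))
    if (nrow(raw$coords[[f]]) != na)
      stop("topology mismatch: frame ", f, " has ", nrow(raw$coords[[f]]),
           " atoms, structure has ", na)
  if (is.null(raw$box) && periodic)
    stop("trajectory carries no box information; pass periodic = FALSE ",
         "for a non-periodic system")
  if (!is.null(total_time_ns))
    stride_ns <- total_time_ns / length(raw$coords)
  traj <- trajectory_ensemble(structure, raw$coords, box = raw$box,
                              stride_ns = stride_ns %||% 1)
  if (stride > 1) traj <- stride_trajectory(traj, stride) else traj
}

read_traj_multipdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_cryst <- startsWith(lines, "CRYST1")
  if (!any(is_atom)) stop("no ATOM records in ", path)
  # frame id per line: count of MODEL records seen so far (0 if none -> 1 frame)
  model_no <- cumsum(is_model)
  if (!any(is_model)) model_no <- rep(1L, length(lines))
  frames <- sort(unique(model_no[is_atom]))
  coords <- vector("list", length(frames))
  boxes <- NULL
  for (k in seq_along(frames)) {
    al <- lines[is_atom & model_no == frames[k]]
    xyz <- cbind(as.numeric(substr(al, 31, 38)),
                 as.numeric(substr(al, 39, 46)),
                 as.numeric(substr(al, 47, 54)))
    if (any(is.na(xyz)))
      stop("PDB coordinate parse error in model ", k, " of ", path)
    coords[[k]] <- xyz
    cl <- lines[is_cryst & model_no == frames[k]]
    if (length(cl) >= 1) {
      b <- c(as.numeric(substr(cl[1], 7, 15)),
             as.numeric(substr(cl[1], 16, 24)),
             as.numeric(substr(cl[1], 25, 33)))
      if (is.null(boxes)) boxes <- matrix(NA_real_, length(frames), 3)
      boxes[k, ] <- b
    }
  }
  # a single leading CRYST1 before the first MODEL applies to all frames
  if (is.null(boxes) && any(is_cryst)) {
    cl <- lines[is_cryst][1]
    b <- c(as.numeric(substr(cl, 7, 15)), as.numeric(substr(cl, 16, 24)),
           as.numeric(substr(cl, 25, 33)))
    boxes <- matrix(rep(b, each = length(frames)), length(frames), 3)
  }
  if (!is.null(boxes) && any(is.na(boxes))) {
    # per-model boxes present but missing for some frames: carry forward
    for (k in seq_len(nrow(boxes)))
      if (any(is.na(boxes[k, ]))) boxes[k, ] <- boxes[max(1, k - 1), ]
    if (any(is.na(boxes))) boxes <- NULL
  }
  list(coords = coords, box = boxes)
}

read_traj_dcd <- function(path) {
  dcd <- bio3d::read.dcd(path, cell = FALSE, verbose = FALSE)
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  nf <- nrow(dcd)
  coords <- lapply(seq_len(nf), function(f) matrix(dcd[f, ], ncol = 3, byrow = TRUE))
  box <- NULL
  if (!is.null(cell) && ncol(cell) >= 6)
    box <- cell[, c(1, 3, 6), drop = FALSE]  # a, b, c edges
  list(coords = coords, box = box)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; per-frame CRYST1 records carry the box.
#' This is the package's text trajectory dialect, readable back with
#' [read_trajectory()].
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param path output file path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  resno <- a$residue_index %% 10000
  atno <- a$atom_id %% 100000
  nm <- ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    if (!is.null(traj$box))
      writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                         traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    xyz <- traj$coords[[f]]
    writeLines(sprintf("ATOM  %5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       atno, substr(nm, 1, 4), substr(a$residue_name, 1, 3),
                       substr(a$chain_id, 1, 1), resno,
                       xyz[, 1], xyz[, 2], xyz[, 3],
                       substr(a$element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
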