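# Internal geometry helpers shared across modules.

#' Minimum-image displacement
#'
#' Wraps a displacement (or array of displacements) into the nearest periodic
#' image under an orthorhombic box.
#'
#' @param d numeric displacement(s) along one axis, in Angstrom.
#' @param box positive box edge length along that axis, in Angstrom.
#' @return displacement(s) in \code{[-box/2, box/2]}.
#' @keywords internal
min_image <- function(d, box) d - box * round(d / box)

# All-pairs squared distances between rows of xyz (n x 3), optionally under
# the minimum-image convention for an orthorhombic box (length-3 vector).
pairwise_sq_dists <- function(xyz, box = NULL) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  d2 <- matrix(0, nrow(xyz), nrow(xyz))
  for (k in 1:3) {
    dk <- outer(xyz[, k], xyz[, k], "-")
    if (!is.null(box)) dk <- min_image(dk, box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

# Squared distances between rows of a (n x 3) and rows of b (m x 3).
cross_sq_dists <- function(a, b, box = NULL) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) dk <- min_image(dk, box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

# Trapezoid-rule integral of y over grid x.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

check_box <- function(box) {
  if (is.null(box)) return(NULL)
  box <- as.numeric(box)
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(box) == 3, all(is.finite(box)), all(box > 0))
  box
}

`%||%` <- function(a, b) if (is.null(a)) b else a
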