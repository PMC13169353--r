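#' Write a labelled numeric matrix as delimited text
#'
#' Tab-separated values with `#`-prefixed header lines carrying the column
#' labels; values are printed with 12 significant digits so a read-back
#' ([read_matrix()]) reproduces the matrix to that precision.
#'
#' @param m numeric matrix.
#' @param path output path.
#' @param row_labels,col_labels label vectors matching the dimensions;
#'   defaults to existing dimnames or 1-based indices.
#' @param allow_nan permit NaN/NA entries (written as `nan`).
#' @export
write_matrix <- function(m, path, row_labels = NULL, col_labels = NULL,
                         allow_nan = FALSE) {
  m <- as.matrix(m)
  row_labels <- row_labels %||% rownames(m) %||% as.character(seq_len(nrow(m)))
  col_labels <- col_labels %||% colnames(m) %||% as.character(seq_len(ncol(m)))
  if (length(row_labels) != nrow(m) || length(col_labels) != ncol(m))
    stop("label lengths must match matrix dimensions")
  if (!allow_nan && any(!is.finite(m)))
    stop("matrix contains non-finite entries (set allow_nan = TRUE to permit)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# rows\t", nrow(m), "\tcols\t", ncol(m)), con)
  writeLines(paste0("# columns\t", paste(col_labels, collapse = "\t")), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    vals <- ifelse(is.finite(m[i, ]), sprintf("%.12g", m[i, ]), "nan")
    paste(c(row_labels[i], vals), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path file path.
#' @return numeric matrix with dimnames restored.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  colline <- hdr[startsWith(hdr, "# columns")]
  if (length(colline) != 1) stop("not a contactmodes matrix file: ", path)
  col_labels <- strsplit(sub("^# columns\t", "", colline), "\t")[[1]]
  parts <- strsplit(body, "\t", fixed = TRUE)
  row_labels <- vapply(parts, `[`, character(1), 1)
  vals <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1]))
    v[p[-1] == "nan"] <- NaN
    v
  }, numeric(length(col_labels))))
  if (length(col_labels) == 1) vals <- matrix(vals, ncol = 1)
  dimnames(vals) <- list(row_labels, col_labels)
  vals
}

#' Export a signed contact map as a 3-D cylinder edge list
#'
#' One record per nonzero residue pair (i < j) of a contact displacement map:
#' 1-based residue indices, the representative-atom coordinates of both
#' residues (alpha-carbon when present, else the residue geometric centre),
#' and the signed weight. Negative weights mark breaking of contacts, positive
#' weights formation of contacts, along the mapped mode.
#'
#' @param map signed symmetric residue x residue matrix (a
#'   `ContactDisplacementMap` or plain matrix).
#' @param structure the `StructureModel` providing coordinates; residue count
#'   must match the map dimension.
#' @param path output TSV path.
#' @return invisibly, the edge data.frame written.
#' @export
export_cylinder_edges <- function(map, structure, path) {
  m <- if (inherits(map, "ContactDisplacementMap")) map$matrix else as.matrix(map)
  nr <- n_residues(structure)
  if (nrow(m) != nr || ncol(m) != nr)
    stop("map dimension (", nrow(m), ") does not match residue count (", nr, ")")
  rep_xyz <- representative_coords(structure)
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  edges <- data.frame(res_i = idx[, 1], res_j = idx[, 2],
                      xi = rep_xyz[idx[, 1], 1], yi = rep_xyz[idx[, 1], 2],
                      zi = rep_xyz[idx[, 1], 3],
                      xj = rep_xyz[idx[, 2], 1], yj = rep_xyz[idx[, 2], 2],
                      zj = rep_xyz[idx[, 2], 3],
                      weight = m[idx])
  con <- file(path, "w")
  writeLines(paste0("# ", paste(names(edges), collapse = "\t")), con)
  if (nrow(edges) > 0)
    writeLines(do.call(sprintf, c(list(
      "%d\t%d\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g"),
      unname(edges))), con)
  close(con)
  invisible(edges)
}

#' Read a cylinder edge list written by [export_cylinder_edges()]
#' @param path file path.
#' @return data.frame of edges (possibly zero rows).
#' @export
read_cylinder_edges <- function(path) {
  cols <- c("res_i", "res_j", "xi", "yi", "zi", "xj", "yj", "zj", "weight")
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    df <- as.data.frame(matrix(numeric(0), 0, 9))
    names(df) <- cols
    return(df)
  }
  df <- utils::read.table(text = body, sep = "\t", col.names = cols)
  df$res_i <- as.integer(df$res_i)
  df$res_j <- as.integer(df$res_j)
  df
}

# Per-residue representative coordinates: CA when the residue has one, else
# the geometric centre of its atoms.
representative_coords <- function(structure) {
  nr <- n_residues(structure)
  out <- matrix(NA_real_, nr, 3)
  for (r in seq_len(nr)) {
    sel <- which(structure$residue_id == r)
    ca <- sel[structure$atoms$atom_name[sel] == "CA"]
    out[r, ] <- if (length(ca) >= 1) structure$xyz[ca[1], ] else
      colMeans(structure$xyz[sel, , drop = FALSE])
  }
  out
}
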