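#' Molecular structure model
#'
#' A `StructureModel` holds the static atom table of a system (atom ids,
#' names, elements, residue assignment, chains) together with one set of
#' reference coordinates in Angstrom. It is the topology against which all
#' trajectory frames are interpreted.
#'
#' @param atoms data.frame with columns `atom_id` (unique integers),
#'   `atom_name`, `element`, `residue_index` (1-based, non-decreasing within
#'   each chain), `residue_name`, `chain_id`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return object of class `StructureModel` with fields `atoms`, `xyz`, and a
#'   derived `residue_id` vector giving each atom's global (chain-concatenated)
#'   1-based residue index.
#' @examples
#' atoms <- data.frame(atom_id = 1:2, atom_name = c("CA", "CA"),
#'                     element = "C", residue_index = 1:2,
#'                     residue_name = "GLY", chain_id = "A")
#' s <- structure_model(atoms, matrix(rnorm(6), 2, 3))
#' n_residues(s)
#' @export
structure_model <- function(atoms, xyz) {
  req <- c("atom_id", "atom_name", "element", "residue_index",
           "residue_name", "chain_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atoms table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: zero atoms")
  if (anyDuplicated(atoms$atom_id))
    stop("atom_id values must be unique")
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3 || nrow(xyz) != nrow(atoms))
    stop("xyz must be a numeric atoms x 3 matrix")
  if (!all(is.finite(xyz)))
    stop("reference coordinates must all be finite")
  for (ch in unique(atoms$chain_id)) {
    ri <- atoms$residue_index[atoms$chain_id == ch]
    if (is.unsorted(ri))
      stop("residue_index must be non-decreasing within chain ", ch)
  }
  # global residue id: chains concatenated in order of first appearance,
  # so a dimer's second chain occupies indices n_res(A)+1 .. n_res(A)+n_res(B)
  key <- paste(atoms$chain_id, atoms$residue_index, sep = "|")
  residue_id <- as.integer(factor(key, levels = unique(key)))
  out <- list(atoms = atoms, xyz = xyz, residue_id = residue_id)
  class(out) <- "StructureModel"
  out
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), n_residues(x), length(unique(x$atoms$chain_id))))
  invisible(x)
}

#' Number of residues in a structure (chains concatenated)
#' @param structure a `StructureModel`.
#' @return integer residue count.
#' @export
n_residues <- function(structure) max(structure$residue_id)

#' Per-residue summary table of a structure
#'
#' @param structure a `StructureModel`.
#' @return data.frame with one row per global residue: `residue_id`,
#'   `residue_name`, `chain_id`, `residue_index` (within-chain).
#' @export
residue_table <- function(structure) {
  first <- !duplicated(structure$residue_id)
  data.frame(residue_id = structure$residue_id[first],
             residue_name = structure$atoms$residue_name[first],
             chain_id = structure$atoms$chain_id[first],
             residue_index = structure$atoms$residue_index[first])
}

guess_element <- function(atom_name) {
  # strip digits/primes, take leading letters; two-letter elements in common
  # biomolecular use are recognized, everything else falls back to the first
  # letter (H of HG21, C of CA, ...)
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- c("CL", "NA", "MG", "ZN", "FE", "BR", "MN", "CA2")
  ifelse(nm %in% two, nm, substr(nm, 1, 1))
}

#' Read a molecular structure file
#'
#' Reads a PDB (single model; for multi-model files the first model is used)
#' or GROMACS GRO file into a [structure_model()]. GRO coordinates (nm) are
#' converted to Angstrom; GRO files carry no chain identifiers, so all atoms
#' are assigned chain "A".
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; default guesses from the file extension.
#' @return a `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gro") "gro" else "pdb"
  }
  if (format == "pdb") read_structure_pdb(path) else read_structure_gro(path)
}

read_structure_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure: zero atoms in ", path)
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  atoms <- data.frame(atom_id = a$eleno,
                      atom_name = a$elety,
                      element = ifelse(is.na(a$elesy) | a$elesy == "",
                                       guess_element(a$elety), a$elesy),
                      residue_index = a$resno,
                      residue_name = a$resid,
                      chain_id = chain)
  structure_model(atoms, cbind(a$x, a$y, a$z))
}

read_structure_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("not a GRO file (too few lines): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n <= 0)
    stop("GRO format error at line 2 of ", path, ": bad atom count '",
         trimws(lines[2]), "'")
  if (length(lines) < 2 + n)
    stop("GRO format error: header declares ", n, " atoms but file has ",
         length(lines) - 3, " atom lines")
  al <- lines[3:(2 + n)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resnm <- trimws(substr(al, 6, 10))
  atnm  <- trimws(substr(al, 11, 15))
  atno  <- suppressWarnings(as.integer(substr(al, 16, 20)))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop("GRO format error at line ", 2 + bad[1], " of ", path)
  atoms <- data.frame(atom_id = atno,
                      atom_name = atnm,
                      element = guess_element(atnm),
                      residue_index = resno,
                      residue_name = resnm,
                      chain_id = "A")
  structure_model(atoms, cbind(x, y, z) * 10)  # nm -> Angstrom
}

#' Write a structure as a GRO file
#'
#' Inverse of [read_structure()] for the GRO dialect; coordinates are written
#' in nm with 3 decimals (the format's native precision).
#'
#' @param structure a `StructureModel`.
#' @param path output file path.
#' @param box optional length-3 box edge vector in Angstrom (written in nm);
#'   defaults to an axis-aligned bounding box plus 10 Angstrom.
#' @export
write_gro <- function(structure, path, box = NULL) {
  xyz <- structure$xyz / 10
  a <- structure$atoms
  if (is.null(box)) box <- apply(structure$xyz, 2, function(v) diff(range(v))) + 10
  box <- check_box(box) / 10
  lines <- c("written by contactmodes", sprintf("%5d", nrow(a)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$residue_index %% 100000, a$residue_name,
                     substr(a$atom_name, 1, 5), a$atom_id %% 100000,
                     xyz[, 1], xyz[, 2], xyz[, 3]),
             sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}
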