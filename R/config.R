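#' Analysis run configuration
#'
#' Bundles the tunable parameters of the contact pipeline and membrane
#' analytics with their standard defaults: any-atom contact cutoff 4.2
#' Angstrom, dynamic-contact frequency window (0.1, 0.9), 8 retained PCs,
#' hydrogen-bond cutoffs 3.5 Angstrom / 20 degrees, membrane normal along z.
#'
#' @param contact_cutoff_A any-atom residue contact cutoff, Angstrom.
#' @param u_low,u_high dynamic-contact mean-frequency window; pairs with mean
#'   contact strictly inside `(u_low, u_high)` are retained.
#' @param n_pcs number of principal components kept for discriminant analysis.
#' @param hbond_distance_A donor-to-acceptor heavy-atom distance cutoff.
#' @param hbond_angle_deg cutoff on the angle between the donor-to-hydrogen
#'   and donor-to-acceptor vectors.
#' @param membrane_normal_axis `"x"`, `"y"` or `"z"`.
#' @param random_seed integer seed recorded with the run.
#' @return validated list of class `RunConfig`.
#' @export
run_config <- function(contact_cutoff_A = 4.2, u_low = 0.1, u_high = 0.9,
                       n_pcs = 8, hbond_distance_A = 3.5, hbond_angle_deg = 20,
                       membrane_normal_axis = c("z", "x", "y"),
                       random_seed = 1L) {
  membrane_normal_axis <- match.arg(membrane_normal_axis)
  stopifnot(contact_cutoff_A > 0, n_pcs >= 1, hbond_distance_A > 0,
            hbond_angle_deg > 0, u_low >= 0, u_low < 1, u_high > 0,
            u_high <= 1)
  if (u_low >= u_high) stop("u_low must be < u_high")
  out <- list(contact_cutoff_A = contact_cutoff_A, u_low = u_low,
              u_high = u_high, n_pcs = as.integer(n_pcs),
              hbond_distance_A = hbond_distance_A,
              hbond_angle_deg = hbond_angle_deg,
              membrane_normal_axis = membrane_normal_axis,
              random_seed = as.integer(random_seed))
  class(out) <- "RunConfig"
  out
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the [run_config()]
#' defaults.
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Read a trajectory class-label manifest
#'
#' A manifest is delimited text with a header row; the first column holds
#' unique trajectory ids and the remaining columns name experimental
#' conditions (e.g. salt, redox, membrane) with one class label per cell.
#'
#' @param path TSV/CSV file path (separator auto-detected from the header).
#' @return data.frame with one row per trajectory, first column
#'   `trajectory_id`, one column per condition, all character.
#' @export
read_label_manifest <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE)
  if (ncol(df) < 2)
    stop("manifest needs a trajectory-id column plus >= 1 condition column")
  names(df)[1] <- "trajectory_id"
  if (anyDuplicated(df$trajectory_id))
    stop("duplicate trajectory id(s): ",
         paste(unique(df$trajectory_id[duplicated(df$trajectory_id)]),
               collapse = ", "))
  empty <- which(is.na(df) | trimws(as.matrix(df)) == "", arr.ind = TRUE)
  if (nrow(empty) > 0)
    stop("missing label for trajectory '", df$trajectory_id[empty[1, 1]],
         "', condition '", names(df)[empty[1, 2]], "'")
  df
}
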