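#' Build a molecular topology table
#'
#' A topology is a tibble with one row per atom, carrying identity
#' (`atom_id`, `name`, `element`), residue membership (`resid`, `resname`,
#' `chain`) and the per-atom parameters used by the energetics and surface
#' modules: partial charge (e), Lennard-Jones `sigma` (Angstrom) and
#' `epsilon` (kcal/mol), and the `radius` (Angstrom) used for
#' Poisson-Boltzmann dielectric boundaries and solvent-accessible surface
#' area.  Parameters may be `NA` when a stage that needs them is not used.
#'
#' @param atoms A data frame with at least columns `name`, `resid`,
#'   `resname`, `chain`.  Missing `atom_id` is filled with the row number,
#'   missing `element` is guessed from the first letter of `name`, missing
#'   parameter columns are filled with `NA`.
#' @return A tibble of class `md_topology`.
#' @export
#' @examples
#' md_topology(data.frame(name = "CA", resid = 1, resname = "ALA", chain = "A"))
md_topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) < 1) abort("topology must contain at least one atom")
  for (col in c("name", "resid", "resname", "chain")) {
    if (!col %in% names(atoms)) abort(paste0("topology is missing column '", col, "'"))
  }
  if (!"atom_id" %in% names(atoms)) atoms$atom_id <- seq_len(nrow(atoms))
  if (!"element" %in% names(atoms)) atoms$element <- toupper(substr(atoms$name, 1, 1))
  for (col in c("charge", "sigma", "epsilon", "radius")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  }
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$resid <- as.integer(atoms$resid)
  if (anyDuplicated(atoms$atom_id)) abort("atom identifiers must be unique")
  # residue indices must be non-decreasing within each chain
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r)) abort(paste0("residue indices not non-decreasing in chain ", ch))
  }
  ok <- function(x) all(is.na(x) | x >= 0)
  if (!ok(atoms$sigma) || !ok(atoms$epsilon) || !ok(atoms$radius)) {
    abort("sigma, epsilon and radius must be non-negative where given")
  }
  class(atoms) <- c("md_topology", class(atoms))
  atoms
}

#' @export
print.md_topology <- function(x, ...) {
  cat("<md_topology> ", nrow(x), " atoms, ",
      nrow(unique(x[c("chain", "resid")])), " residues, ",
      length(unique(x$chain)), " chain(s)\n", sep = "")
  NextMethod()
}

#' Select atoms from a topology
#'
#' Returns the ordered atom indices (row positions) matching all supplied
#' predicates; predicates left `NULL` do not constrain.
#'
#' @param topology An [md_topology] (or a trajectory, whose topology is used).
#' @param name,element,resid,resname,chain Vectors of admissible values.
#' @param heavy If `TRUE` keep only non-hydrogen atoms.
#' @return Integer vector of atom indices (1-based, duplicate free).
#' @export
select_atoms <- function(topology, name = NULL, element = NULL, resid = NULL,
                         resname = NULL, chain = NULL, heavy = FALSE) {
  top <- as_topology(topology)
  keep <- rep(TRUE, nrow(top))
  if (!is.null(name))    keep <- keep & top$name %in% name
  if (!is.null(element)) keep <- keep & top$element %in% element
  if (!is.null(resid))   keep <- keep & top$resid %in% resid
  if (!is.null(resname)) keep <- keep & top$resname %in% resname
  if (!is.null(chain))   keep <- keep & top$chain %in% chain
  if (heavy)             keep <- keep & top$element != "H"
  which(keep)
}

as_topology <- function(x) {
  if (inherits(x, "md_topology")) return(x)
  if (inherits(x, "md_trajectory")) return(x$topology)
  if (is.data.frame(x)) return(md_topology(x))
  abort("cannot interpret object as a topology")
}

# validate a selection: in-range, no duplicates
check_selection <- function(sel, n_atoms, what = "selection") {
  sel <- as.integer(sel)
  if (length(sel) == 0) abort(paste0(what, " is empty"))
  if (anyDuplicated(sel)) abort(paste0(what, " contains duplicate atom indices"))
  if (any(sel < 1 | sel > n_atoms)) abort(paste0(what, " has out-of-range atom indices"))
  sel
}

#' Read a per-atom parameter table
#'
#' The table is whitespace- or comma-delimited text with a header naming at
#' least `atom_id`, `charge`, `sigma`, `epsilon`, `radius`.
#'
#' @param path File to read.
#' @return A tibble with one row per atom.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter table not found: ", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("atom_id", "charge", "sigma", "epsilon", "radius")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("parameter table missing columns: ",
                                 paste(miss, collapse = ", ")))
  as_tibble(df)
}

#' Write a per-atom parameter table
#'
#' @param topology An [md_topology].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(topology, path) {
  top <- as_topology(topology)
  utils::write.table(top[c("atom_id", "charge", "sigma", "epsilon", "radius")],
                     path, row.names = FALSE, quote = FALSE, sep = " ")
  invisible(path)
}

#' Attach parameters from a table to a topology
#'
#' @param topology An [md_topology].
#' @param params A data frame with `atom_id` plus parameter columns, e.g.
#'   from [read_parameter_table()].
#' @return The topology with `charge`, `sigma`, `epsilon`, `radius` replaced.
#' @export
set_parameters <- function(topology, params) {
  top <- as_topology(topology)
  m <- match(top$atom_id, params$atom_id)
  if (anyNA(m)) abort("parameter table does not cover every atom_id in the topology")
  for (col in c("charge", "sigma", "epsilon", "radius")) {
    if (col %in% names(params)) top[[col]] <- as.numeric(params[[col]][m])
  }
  top
}
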