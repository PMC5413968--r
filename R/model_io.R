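# Atomic models are plain data frames (one row per atom) so that subsetting,
# merging and bookkeeping stay idiomatic.  PDB reading/writing is delegated
# to bio3d; the altloc column is respected throughout because multi-state
# ensemble models live and die by their conformer labels.

#' Construct a structure model
#'
#' An atom table with one row per atom.  Blank altloc (\code{""}) denotes a
#' single-conformer atom; conformer labels are single characters.
#'
#' @param atoms data frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}, \code{altloc}, \code{x},
#'   \code{y}, \code{z}, \code{occ}, \code{b}.  May have zero rows.
#' @return An object of class \code{structure_model} (a data frame).
#' @export
structure_model <- function(atoms = NULL) {
  cols <- c("chain", "resno", "resname", "atom", "element", "altloc",
            "x", "y", "z", "occ", "b")
  if (is.null(atoms) || nrow(atoms) == 0L) {
    atoms <- data.frame(chain = character(), resno = integer(),
                        resname = character(), atom = character(),
                        element = character(), altloc = character(),
                        x = numeric(), y = numeric(), z = numeric(),
                        occ = numeric(), b = numeric(),
                        stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(cols, names(atoms))
  if (length(missing_cols))
    stop("missing atom columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[cols]
  atoms$resno <- as.integer(atoms$resno)
  atoms$altloc[is.na(atoms$altloc)] <- ""
  for (cc in c("x", "y", "z", "occ", "b")) atoms[[cc]] <- as.numeric(atoms[[cc]])
  if (nrow(atoms)) {
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
      stop("non-finite coordinates")
    if (any(atoms$occ < 0 | atoms$occ > 1))
      stop("occupancies must lie in [0, 1]")
    if (any(atoms$b < 0))
      stop("B-factors must be >= 0")
    key <- atom_key(atoms)
    if (anyDuplicated(key))
      stop("duplicate atom key(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(atoms) <- NULL
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

# unique identifier of an atom record
atom_key <- function(atoms, with_altloc = TRUE) {
  if (with_altloc)
    paste(atoms$chain, atoms$resno, atoms$atom, atoms$altloc, sep = "|")
  else
    paste(atoms$chain, atoms$resno, atoms$atom, sep = "|")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, conformers: %s\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              paste(sort(unique(x$altloc)), collapse = " ")))
  if (nrow(x)) print.data.frame(head(x, 6L))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param model a \code{structure_model}.
#' @return n x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @export
coords <- function(model) {
  as.matrix(model[, c("x", "y", "z"), drop = FALSE])
}

#' Read an atomic model from a PDB file
#'
#' ATOM and HETATM records are read (via bio3d), preserving altloc labels,
#' occupancies and B-factors.  A file with no atom records yields an empty
#' model.
#'
#' @param path path to a PDB file.
#' @return A \code{\link{structure_model}}.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    return(structure_model())
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  structure_model(data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    resname = a$resid,
    atom = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     toupper(substr(gsub("[0-9'*]", "", a$elety), 1L, 1L)),
                     a$elesy),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occ = a$o, b = a$b,
    stringsAsFactors = FALSE))
}

#' Write an atomic model to a PDB file
#'
#' @param model a \code{\link{structure_model}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  xyz <- as.vector(t(coords(model)))
  bio3d::write.pdb(file = path,
                   xyz = xyz,
                   type = rep("ATOM", nrow(model)),
                   resno = model$resno,
                   resid = model$resname,
                   eleno = seq_len(nrow(model)),
                   elety = model$atom,
                   chain = model$chain,
                   alt = ifelse(model$altloc == "", NA, model$altloc),
                   o = model$occ,
                   b = model$b,
                   elesy = model$element)
  invisible(path)
}

#' Construct a dataset (map + model + resolution)
#'
#' @param id dataset identifier string.
#' @param map a \code{\link{density_map}}.
#' @param model a \code{\link{structure_model}}.
#' @param resolution nominal resolution d (Angstrom), > 0.
#' @param role \code{"ground"} (ground-state candidate) or
#'   \code{"changed"} (putative changed state to analyse).
#' @return An object of class \code{dd_dataset}.
#' @export
dd_dataset <- function(id, map, model, resolution, role = c("ground", "changed")) {
  role <- match.arg(role)
  stopifnot(inherits(map, "density_map"), inherits(model, "structure_model"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number (Angstrom)")
  structure(list(id = as.character(id), map = map, model = model,
                 resolution = as.numeric(resolution), role = role),
            class = "dd_dataset")
}

#' @export
print.dd_dataset <- function(x, ...) {
  cat(sprintf("dd_dataset '%s': %.2f A, role %s, %d atoms, grid %s\n",
              x$id, x$resolution, x$role, nrow(x$model),
              paste(dim(x$map$values), collapse = "x")))
  invisible(x)
}
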