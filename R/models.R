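#' Construct an atomic model
#'
#' An `atomic_model` is a set of weighted point atoms: the minimal
#' representation needed to blur a structure into a density map and dock it
#' rigidly. Coordinates are in Angstrom.
#'
#' @param model_id identifier, unique within a library (defaults of the file
#'   readers: the file name stem).
#' @param coords numeric n x 3 matrix of atom positions (Angstrom).
#' @param element character vector of element symbols (recycled).
#' @param weight positive per-atom weights (recycled); weight 1 means every
#'   atom contributes equally to the simulated density.
#' @return an object of class `atomic_model`.
#' @export
atomic_model <- function(model_id, coords, element = "C", weight = 1) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) < 1L)
    stop("'coords' must be an n x 3 matrix with at least one atom")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("atom positions must be finite")
  n <- nrow(coords)
  element <- rep_len(as.character(element), n)
  weight <- rep_len(as.numeric(weight), n)
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("atom weights must be positive and finite")
  if (!is.character(model_id) || length(model_id) != 1L || !nzchar(model_id))
    stop("'model_id' must be a non-empty string")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(model_id = model_id, coords = coords, element = element,
         weight = weight),
    class = "atomic_model"
  )
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> '%s': %d atoms\n", x$model_id, n_atoms(x)))
  ext <- apply(x$coords, 2, range)
  cat(sprintf("  extent   : %.1f x %.1f x %.1f A\n",
              diff(ext[, 1]), diff(ext[, 2]), diff(ext[, 3])))
  invisible(x)
}

#' Number of atoms in a model
#' @param model an [atomic_model()].
#' @return integer atom count.
#' @export
n_atoms <- function(model) {
  stopifnot(inherits(model, "atomic_model"))
  nrow(model$coords)
}

#' Centroid of a model
#' @param model an [atomic_model()].
#' @return numeric triple, the unweighted mean atom position (Angstrom).
#' @export
model_centroid <- function(model) {
  stopifnot(inherits(model, "atomic_model"))
  colMeans(model$coords)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses ATOM/HETATM records with bio3d. The model id defaults to the file
#' name stem. With `weight_mode = "mass"` each atom is weighted by its
#' element mass; the default weights every atom equally, which is how probe
#' structures enter the matching protocol.
#'
#' @param path a `.pdb`/`.ent` or `.cif` file.
#' @param model_id identifier; default: file name without extension.
#' @param weight_mode `"unit"` (default) or `"mass"`.
#' @return an [atomic_model()].
#' @export
read_model <- function(path, model_id = NULL,
                       weight_mode = c("unit", "mass")) {
  weight_mode <- match.arg(weight_mode)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(model_id)) model_id <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else
      suppressWarnings(bio3d::read.pdb(path)),
    error = function(e) stop(sprintf("cannot parse model '%s': %s",
                                     path, conditionMessage(e))))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop(sprintf("no atoms parsed from '%s'", path))
  coords <- cbind(at$x, at$y, at$z)
  keep <- stats::complete.cases(coords)
  if (!any(keep)) stop(sprintf("no atoms parsed from '%s'", path))
  coords <- coords[keep, , drop = FALSE]
  elem <- at$elesy[keep]
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- substr(trimws(at$elety[keep]), 1L, 1L)
  elem[is.na(elem) | elem == ""] <- "C"
  w <- if (weight_mode == "mass") element_mass(elem) else 1
  atomic_model(model_id, coords, element = elem, weight = w)
}

## Element symbol -> atomic mass, from bio3d's periodic-table dataset;
## unknown symbols fall back to carbon so a screen never dies on an exotic
## HETATM.
element_mass <- local({
  table <- NULL
  function(elem) {
    if (is.null(table)) {
      e <- new.env()
      utils::data("elements", package = "bio3d", envir = e)
      table <<- stats::setNames(e$elements$mass, e$elements$symb)
    }
    key <- paste0(toupper(substr(elem, 1, 1)),
                  tolower(substr(elem, 2, 2)))
    m <- unname(table[key])
    m[!is.finite(m) | m <= 0] <- 12.011
    m
  }
})

#' Write an atomic model as PDB
#'
#' Serializes atoms as CA ATOM records (one residue per atom), sufficient
#' for round-tripping synthetic models and decoy libraries.
#'
#' @param model an [atomic_model()].
#' @param path output `.pdb` path.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  n <- n_atoms(model)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(model$coords)),
    type = rep("ATOM", n),
    resno = seq_len(n), eleno = seq_len(n),
    elety = rep("CA", n), resid = rep("ALA", n),
    chain = rep("A", n), o = rep(1, n), b = rep(0, n),
    elesy = model$element)
  invisible(path)
}

## Rigid placement used throughout fitcore: rotate about the model centroid,
## then translate. Returns the transformed n x 3 coordinate matrix.
transform_coords <- function(model, rotation, translation = c(0, 0, 0)) {
  ctr <- model_centroid(model)
  sweep(model$coords, 2, ctr) %*% t(rotation) +
    matrix(ctr + translation, n_atoms(model), 3, byrow = TRUE)
}

## Mirror a model through its centroid (x -> -x in the centroid frame).
## Exposed to fit_model's mirror search; never applied silently.
mirror_model <- function(model) {
  ctr <- model_centroid(model)
  coords <- sweep(model$coords, 2, ctr)
  coords[, 1] <- -coords[, 1]
  atomic_model(model$model_id, sweep(coords, 2, ctr, "+"),
               element = model$element, weight = model$weight)
}
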