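# Atomic model container: a data.frame of atom sites plus covalent topology
# and an orthogonal bounding cell (P1, no symmetry).

#' Atomic model
#'
#' @param atoms data.frame with columns `atom` (name), `residue` (3-letter
#'   code), `resno`, `element`, `x`, `y`, `z` (Angstrom), `b` (isotropic
#'   B-factor, Angstrom^2), `occ` (occupancy), `charge` (fractional charge),
#'   and for hydrogens `parent` (row index of the bonded heavy atom),
#'   `h_class` (bond-type label) and `excluded` (left out of bond statistics,
#'   e.g. lysine side-chain amine hydrogens).
#' @param bonds two-column integer matrix of covalent bonds (row indices).
#' @param cell orthogonal box dimensions in Angstrom (length 3).
#' @param origin box corner in Angstrom (length 3).
#' @return object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, bonds = NULL, cell = NULL, origin = c(0, 0, 0)) {
  req <- c("atom", "residue", "resno", "element", "x", "y", "z", "b", "occ")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$parent)) atoms$parent <- NA_integer_
  if (is.null(atoms$h_class)) atoms$h_class <- NA_character_
  if (is.null(atoms$excluded)) atoms$excluded <- FALSE
  if (any(atoms$b < 0)) stop("B-factors must be >= 0")
  if (any(atoms$occ <= 0 | atoms$occ > 1)) stop("occupancies must be in (0, 1]")
  if (any(abs(atoms$charge) > 1)) stop("|partial charge| must be <= 1")
  if (!is.null(bonds) && length(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1 | bonds > nrow(atoms))) stop("bond indices out of range")
  } else bonds <- matrix(integer(0), ncol = 2)
  if (is.null(cell)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    cell <- apply(xyz, 2, max) - apply(xyz, 2, min) + 10
  }
  stopifnot(length(cell) == 3, all(cell > 0), length(origin) == 3)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds,
                 cell = as.numeric(cell), origin = as.numeric(origin)),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("atomic model: %d atoms (%d H), %d residues, cell %.1f x %.1f x %.1f A\n",
              nrow(a), sum(a$element == "H"), length(unique(a$resno)),
              x$cell[1], x$cell[2], x$cell[3]))
  invisible(x)
}

#' Coordinate matrix of a model
#' @param model an `atomic_model`.
#' @return n x 3 numeric matrix in Angstrom.
#' @export
coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

is_hydrogen <- function(atoms) atoms$element == "H"

#' Remove atoms matched by a selector
#'
#' Returns a copy of the model with the selected sites removed and bonds,
#' hydrogen parent links and indices remapped consistently. The canonical use
#' is building the hydrogen-omitted model for difference maps.
#'
#' @param model an `atomic_model`.
#' @param selector either the string `"hydrogen"`, or a logical vector of
#'   length n_atoms, or a predicate `function(atoms) -> logical`.
#' @return an `atomic_model`; may contain zero atoms.
#' @export
omit_atoms <- function(model, selector = "hydrogen") {
  a <- model$atoms
  sel <- if (is.character(selector) && identical(selector, "hydrogen")) {
    is_hydrogen(a)
  } else if (is.function(selector)) selector(a) else as.logical(selector)
  stopifnot(length(sel) == nrow(a))
  keep <- which(!sel)
  remap <- rep(NA_integer_, nrow(a))
  remap[keep] <- seq_along(keep)
  a2 <- a[keep, , drop = FALSE]
  a2$parent <- remap[a2$parent]
  b <- model$bonds
  if (nrow(b)) {
    ok <- !sel[b[, 1]] & !sel[b[, 2]]
    b <- cbind(remap[b[ok, 1]], remap[b[ok, 2]])
  }
  rownames(a2) <- NULL
  out <- model
  out$atoms <- a2
  out$bonds <- matrix(as.integer(b), ncol = 2)
  out
}

#' Assign partial charges to selected atoms
#'
#' @param model an `atomic_model`.
#' @param selection integer indices, logical vector, or predicate function.
#' @param q fractional charge in \[-1, 1\].
#' @return the modified model.
#' @export
set_partial_charges <- function(model, selection, q) {
  if (abs(q) > 1) stop("|q| must be <= 1")
  idx <- resolve_selection(model, selection)
  model$atoms$charge[idx] <- q
  model
}

resolve_selection <- function(model, selection) {
  a <- model$atoms
  if (is.function(selection)) which(selection(a))
  else if (is.logical(selection)) which(selection)
  else as.integer(selection)
}

#' Indices of carboxylate oxygen atoms (Asp OD1/OD2, Glu OE1/OE2)
#' @param model an `atomic_model`.
#' @return integer vector of row indices.
#' @export
carboxylate_oxygens <- function(model) {
  a <- model$atoms
  which((a$residue == "ASP" & a$atom %in% c("OD1", "OD2")) |
        (a$residue == "GLU" & a$atom %in% c("OE1", "OE2")))
}
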