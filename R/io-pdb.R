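# Atomic model I/O: a PDB-subset dialect through bio3d. The PDB format has
# no fractional-charge field, so partial charges travel in a sidecar JSON
# (written next to the PDB as <path>.charges.json).

#' Write a model to PDB (+ charge sidecar)
#'
#' Coordinates, element, occupancy and B-factor round-trip at PDB precision
#' (3 decimals on coordinates). Nonzero partial charges are written to
#' `<path>.charges.json` keyed by atom serial.
#'
#' @param model an `atomic_model`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$residue,
                   eleno = seq_len(nrow(a)), elety = a$atom,
                   chain = rep("A", nrow(a)), o = a$occ, b = a$b,
                   elesy = a$element)
  if (any(a$charge != 0)) {
    ch <- a$charge[a$charge != 0]
    names(ch) <- which(a$charge != 0)
    jsonlite::write_json(list(charges = as.list(ch)),
                         paste0(path, ".charges.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a model from PDB (+ charge sidecar)
#'
#' Reads element, name, residue, coordinates, occupancy and B-factor;
#' partial charges are restored from `<path>.charges.json` when present.
#' Hydrogen topology (parent links, bond classes) and covalent bonds are
#' re-derived from the residue templates by atom name; atoms of residues
#' without a template keep NA topology.
#'
#' @param path PDB file path.
#' @return an `atomic_model`.
#' @export
read_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms in ", path)
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) {
    elem[bad] <- vapply(at$elety[bad], infer_element, "")
    warning(sum(bad), " atoms had no element field; inferred from atom names")
  }
  atoms <- data.frame(atom = at$elety, residue = at$resid, resno = at$resno,
                      element = elem, x = at$x, y = at$y, z = at$z,
                      b = ifelse(is.na(at$b), 0, at$b),
                      occ = ifelse(is.na(at$o), 1, at$o), charge = 0)
  side <- paste0(path, ".charges.json")
  if (file.exists(side)) {
    ch <- jsonlite::fromJSON(side)$charges
    atoms$charge[as.integer(names(ch))] <- as.numeric(unlist(ch))
  }
  model <- atomic_model(atoms)
  infer_topology(model)
}

# PDB convention: the element is the first alphabetic character(s) of the
# atom name with remoteness indicators stripped; a leading digit (e.g.
# "1HB2") marks a hydrogen variant.
infer_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  if (nm == "") return("H")
  if (grepl("^H", nm) || grepl("^[0-9]", trimws(name))) return("H")
  substr(nm, 1, 1)
}

# Rebuild hydrogen parent links, bond classes and covalent bonds from the
# residue templates, matching atoms by residue + atom name.
infer_topology <- function(model) {
  tpl <- residue_templates()
  a <- model$atoms
  a$parent <- NA_integer_
  a$h_class <- NA_character_
  a$excluded <- FALSE
  bonds <- list()
  prev_c <- NA_integer_
  for (i in unique(a$resno)) {
    ridx <- which(a$resno == i)
    res <- a$residue[ridx[1]]
    t <- tpl[[res]]
    if (is.null(t)) { prev_c <- NA_integer_; next }
    nm <- a$atom[ridx]
    for (p in t$bonds) {
      i1 <- match(p[[1]], nm); i2 <- match(p[[2]], nm)
      if (!is.na(i1) && !is.na(i2))
        bonds[[length(bonds) + 1]] <- c(ridx[i1], ridx[i2])
    }
    ci <- match("C", nm); ni <- match("N", nm)
    if (!is.na(prev_c) && !is.na(ni))
      bonds[[length(bonds) + 1]] <- c(prev_c, ridx[ni])
    prev_c <- if (!is.na(ci)) ridx[ci] else NA_integer_
    cnt <- template_h_count(res)
    for (h in t$hydrogens) {
      hi <- match(h$name, nm)
      if (is.na(hi)) next
      pi <- match(h$parent, nm)
      a$parent[ridx[hi]] <- ridx[pi]
      cls <- classify_bond_type(res, h$parent, as.integer(cnt[[h$parent]]))
      a$h_class[ridx[hi]] <- cls$class
      a$excluded[ridx[hi]] <- cls$excluded
      bonds[[length(bonds) + 1]] <- c(ridx[pi], ridx[hi])
    }
    hi <- match("H", nm)
    if (!is.na(hi) && !is.na(ni)) {
      a$parent[ridx[hi]] <- ridx[ni]
      a$h_class[ridx[hi]] <- "N-H"
      bonds[[length(bonds) + 1]] <- c(ridx[ni], ridx[hi])
    }
  }
  atomic_model(a, do.call(rbind, bonds), cell = model$cell,
               origin = model$origin)
}
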