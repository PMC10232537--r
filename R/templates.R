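# Residue template registry: idealized heavy-atom geometry, hydrogen topology
# and bond-type classification for the standard amino acids used by the
# synthetic-data generator. Classification beyond residue-template lookup
# (e.g. arbitrary ligands) is out of scope.

.empot_templates <- new.env(parent = emptyenv())

residue_templates <- function() {
  if (is.null(.empot_templates$tpl)) {
    path <- system.file("extdata", "residue_templates.json", package = "empot")
    .empot_templates$tpl <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  .empot_templates$tpl$residues
}

#' Supported residue types
#' @return character vector of 3-letter residue codes.
#' @export
supported_residues <- function() names(residue_templates())

# Riding hydrogen-to-parent distances (Angstrom) by bond type. "nuclear"
# holds neutron-derived internuclear distances, "electron" the shorter
# X-ray-derived electron-cloud centroid distances.
RIDING_DISTANCES <- list(
  nuclear  = c("Calk-H" = 1.09, "Caro-H" = 1.08, "C-H2" = 1.09,
               "C-H3" = 1.09, "N-H" = 1.02, "O-H" = 0.98),
  electron = c("Calk-H" = 0.97, "Caro-H" = 0.93, "C-H2" = 0.97,
               "C-H3" = 0.97, "N-H" = 0.86, "O-H" = 0.84)
)

#' Bond-type classes
#'
#' The hydrogen bond-type vocabulary: `Calk-H` (single hydrogen on an sp3
#' carbon), `Caro-H` (aromatic ring carbon), `C-H2` (methylene), `C-H3`
#' (methyl), `N-H`, `O-H`, and the aggregate `C-H` (union of `Calk-H` and
#' `Caro-H`).
#' @return character vector of class labels.
#' @export
bond_type_classes <- function() c("C-H", "Calk-H", "Caro-H", "C-H2", "C-H3",
                                  "N-H", "O-H")

# Count of template hydrogens per parent atom within a residue (side chains
# and HA; the backbone amide hydrogen is handled separately).
template_h_count <- function(residue) {
  tpl <- residue_templates()[[residue]]
  if (is.null(tpl)) stop("unknown residue '", residue, "'")
  parents <- vapply(tpl$hydrogens, function(h) h$parent, "")
  table(parents)
}

#' Classify the hydrogen bond type of a parent heavy atom
#'
#' Classification is by parent element, aromatic-ring membership and the
#' number of riding hydrogens: aromatic carbons give `Caro-H`; sp3 carbons
#' give `Calk-H`/`C-H2`/`C-H3` for 1/2/3 hydrogens; nitrogens give `N-H`
#' (lysine side-chain NZ is flagged excluded, following the convention of
#' leaving solvent-facing amines out of the statistics); hydroxyl oxygens
#' give `O-H`.
#'
#' @param residue 3-letter residue code.
#' @param parent_name atom name of the parent heavy atom (e.g. "CB", "N").
#' @param n_h number of hydrogens riding on the parent; if NULL, looked up
#'   from the residue template (backbone N counts 1).
#' @return list with `class` (label) and `excluded` (logical).
#' @export
classify_bond_type <- function(residue, parent_name, n_h = NULL) {
  tpl <- residue_templates()[[residue]]
  if (is.null(tpl)) stop("unknown residue '", residue, "'")
  if (parent_name == "N") {
    return(list(class = "N-H", excluded = FALSE))
  }
  if (is.null(n_h)) {
    cnt <- template_h_count(residue)
    n_h <- if (parent_name %in% names(cnt)) as.integer(cnt[[parent_name]]) else 0L
  }
  if (n_h < 1) stop("atom ", parent_name, " of ", residue, " has no riding hydrogens")
  heavy <- vapply(tpl$heavy, function(a) a$name, "")
  elem <- vapply(tpl$heavy, function(a) a$element, "")[match(parent_name, heavy)]
  if (is.na(elem)) stop("atom ", parent_name, " not in template for ", residue)
  aro <- unlist(tpl$aromatic_carbons)
  if (elem == "C") {
    if (parent_name %in% aro) return(list(class = "Caro-H", excluded = FALSE))
    cls <- switch(n_h, "Calk-H", "C-H2", "C-H3")
    if (is.null(cls)) stop("carbon with ", n_h, " hydrogens not classifiable")
    return(list(class = cls, excluded = FALSE))
  }
  if (elem == "N") {
    excl <- residue == "LYS" && parent_name == "NZ"
    return(list(class = "N-H", excluded = excl))
  }
  if (elem == "O") return(list(class = "O-H", excluded = FALSE))
  stop("parent element ", elem, " not supported for hydrogen classification")
}
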