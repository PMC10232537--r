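# Electron scattering factors for neutral, ionized and partially charged atoms.
#
# Neutral atoms use the Peng et al. (1996) 5-Gaussian elastic electron
# scattering parameterization; ions are synthesized through the Mott-Bethe
# relation from International Tables (1992) X-ray form factors, which is the
# only route available for species missing from the electron table.

# Mott-Bethe prefactor: m0 e^2 / (8 pi eps0 h^2), in Angstrom when s is in
# 1/Angstrom and f_x in electrons.
MOTT_BETHE_K <- 0.0239337

.empot_tables <- new.env(parent = emptyenv())

scattering_tables <- function() {
  if (is.null(.empot_tables$tab)) {
    path <- system.file("extdata", "scattering_factors.json", package = "empot")
    tab <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    # normalize neutral X-ray rows so f_x(0) = Z exactly: the published fits
    # carry ~1e-3 residuals that would otherwise leak a spurious 1/s^2 term
    # into the Mott-Bethe conversion at very low s
    tab$xray_it92$species <- lapply(tab$xray_it92$species, function(sp) {
      if (sp$charge == 0) sp$a <- sp$a * (sp$Z - sp$c) / sum(sp$a)
      sp
    })
    .empot_tables$tab <- tab
  }
  .empot_tables$tab
}

#' Scattering species
#'
#' Construct a species (element + integer charge state) carrying the Gaussian
#' parameterizations needed to evaluate its electron scattering factor.
#' Neutral species carry the published 5-Gaussian electron coefficients and
#' the X-ray coefficients; charged species carry X-ray ionic coefficients and
#' are evaluated through the Mott-Bethe relation.
#'
#' @param element chemical element symbol ("H", "C", "N", "O", "S").
#' @param charge integer charge state; 0 for neutral, -1 for the oxygen anion.
#' @return an object of class `scattering_species`.
#' @export
scattering_species <- function(element, charge = 0L) {
  tab <- scattering_tables()
  charge <- as.integer(charge)
  key <- if (charge == 0L) element else
    paste0(element, abs(charge), if (charge < 0L) "-" else "+")
  el5g <- tab$electron_5g$species[[element]]
  xr <- tab$xray_it92$species[[key]]
  if (charge == 0L && is.null(el5g))
    stop("no electron scattering coefficients for element '", element, "'")
  if (charge != 0L && is.null(xr))
    stop("no X-ray ionic form factor for species '", key,
         "'; cannot synthesize its electron scattering factor")
  Z <- if (!is.null(el5g)) el5g$Z else xr$Z
  stopifnot(Z >= 1)
  structure(list(element = element, Z = as.integer(Z), charge = charge,
                 electron_gaussians = if (charge == 0L)
                   list(a = el5g$a, b = el5g$b) else NULL,
                 xray = xr),
            class = "scattering_species")
}

#' @export
print.scattering_species <- function(x, ...) {
  cat(sprintf("scattering species %s (Z=%d, charge=%+d)\n",
              x$element, x$Z, x$charge))
  invisible(x)
}

#' Evaluate a sum-of-Gaussians scattering factor
#'
#' \eqn{f(s) = \sum_i a_i \exp(-b_i s^2)}, the standard parameterized form of
#' tabulated electron scattering factors.
#'
#' @param species a `scattering_species` (must be neutral, i.e. carry
#'   electron-table Gaussians) or a list with elements `a` and `b`.
#' @param s spatial frequency \eqn{\sin\theta/\lambda} in 1/Angstrom
#'   (equivalently 1/(2d) for resolution d); vectorized.
#' @return scattering factor in Angstrom.
#' @export
evaluate_gaussian_ff <- function(species, s) {
  if (inherits(species, "scattering_species")) {
    g <- species$electron_gaussians
    if (is.null(g))
      stop("species ", species$element, " charge ", species$charge,
           " has no tabulated electron Gaussians; use electron_ff()")
  } else g <- species
  stopifnot(length(g$a) >= 1, all(g$b > 0))
  if (any(s < 0)) stop("spatial frequency s must be >= 0")
  colSums(g$a * exp(-outer(g$b, s^2)))
}

#' Tabulated X-ray form factor
#'
#' @param species a `scattering_species` carrying X-ray coefficients.
#' @param s spatial frequency in 1/Angstrom.
#' @return X-ray form factor in electrons.
#' @export
xray_ff <- function(species, s) {
  xr <- if (inherits(species, "scattering_species")) species$xray else species
  if (is.null(xr)) stop("no X-ray coefficients for this species")
  if (any(s < 0)) stop("spatial frequency s must be >= 0")
  colSums(xr$a * exp(-outer(xr$b, s^2))) + xr$c
}

#' Mott-Bethe electron scattering factor
#'
#' Converts an X-ray form factor to an electron scattering factor via
#' \eqn{f_e(s) = k (Z - f_x(s)) / s^2}, \eqn{k \approx 0.023934} Angstrom.
#' For a neutral species (\eqn{f_x(0) = Z}) the \eqn{s \to 0} limit is finite
#' and evaluated by the small-s expansion \eqn{k \sum_i a_i b_i}. For a net
#' charged species the factor diverges as \eqn{s \to 0} with the sign of the
#' net charge, and `s = 0` signals an error rather than returning a number.
#'
#' @param Z atomic number.
#' @param f_x X-ray form factor: either a function of s or a coefficient list
#'   with `a`, `b`, `c` (needed for the analytic s = 0 limit).
#' @param s spatial frequency in 1/Angstrom; vectorized.
#' @return electron scattering factor in Angstrom.
#' @export
mott_bethe_ff <- function(Z, f_x, s) {
  coefs <- NULL
  if (is.list(f_x) && !is.function(f_x)) {
    coefs <- f_x
    fxfun <- function(s) colSums(coefs$a * exp(-outer(coefs$b, s^2))) + coefs$c
  } else fxfun <- f_x
  if (any(s < 0)) stop("spatial frequency s must be >= 0")
  out <- numeric(length(s))
  zero <- s == 0
  if (any(zero)) {
    f0 <- fxfun(0)
    if (abs(Z - f0) > 1e-3)
      stop("Mott-Bethe factor diverges at s = 0 for a net-charged species ",
           "(Z - f_x(0) = ", format(Z - f0), ")")
    if (is.null(coefs))
      stop("s = 0 limit requires coefficient form of f_x (list with a, b, c)")
    out[zero] <- MOTT_BETHE_K * sum(coefs$a * coefs$b)
  }
  if (any(!zero)) {
    ss <- s[!zero]
    out[!zero] <- MOTT_BETHE_K * (Z - fxfun(ss)) / ss^2
  }
  out
}

#' Electron scattering factor of any supported species
#'
#' Dispatches on charge state: neutral species use the tabulated 5-Gaussian
#' electron parameterization; fully ionized species are synthesized via
#' Mott-Bethe from the tabulated ionic X-ray form factor; fractional charges
#' use the linear combination rule (see [partial_charge_ff()]). When the ion
#' matching the sign of the charge is not tabulated (e.g. an oxygen cation),
#' the curve is extrapolated linearly in charge through the tabulated
#' opposite ion: the charged-minus-neutral difference is dominated by the
#' net-charge Coulomb term, which is odd in q, so the charge-reflected
#' difference is the leading-order behaviour.
#'
#' @param element element symbol.
#' @param s spatial frequency in 1/Angstrom; vectorized.
#' @param charge charge state; may be fractional in \[-1, 1\].
#' @return scattering factor in Angstrom.
#' @export
electron_ff <- function(element, s, charge = 0) {
  if (abs(charge) > 1) stop("|charge| must be <= 1")
  neutral <- scattering_species(element)
  f_n <- evaluate_gaussian_ff(neutral, s)
  if (charge == 0) return(f_n)
  ion <- tryCatch(scattering_species(element, as.integer(sign(charge))),
                  error = function(e) NULL)
  if (!is.null(ion)) {
    if (abs(charge) == 1) return(mott_bethe_ff(ion$Z, ion$xray, s))
    return(partial_charge_ff(neutral, ion, charge, s))
  }
  opp <- scattering_species(element, -as.integer(sign(charge)))
  f_opp <- mott_bethe_ff(opp$Z, opp$xray, s)
  f_n - abs(charge) * (f_opp - f_n)
}

#' Scattering factor of a partially charged atom
#'
#' Linear combination of the neutral and fully ionized scattering factors:
#' \eqn{f_q(s) = (1 - |q|) f_{neutral}(s) + |q| f_{ion}(s)}.
#'
#' @param element neutral `scattering_species`.
#' @param ion fully ionized `scattering_species` of the same element.
#' @param q fractional charge in \[-1, 1\]; its sign must match the ion.
#' @param s spatial frequency in 1/Angstrom; vectorized.
#' @return scattering factor in Angstrom.
#' @export
partial_charge_ff <- function(element, ion, q, s) {
  if (abs(q) > 1) stop("|q| must be <= 1")
  if (element$element != ion$element)
    stop("element mismatch: ", element$element, " vs ", ion$element)
  if (q != 0 && sign(q) != sign(ion$charge))
    stop("sign of q (", q, ") does not match the ion charge (", ion$charge, ")")
  f_n <- evaluate_gaussian_ff(element, s)
  if (q == 0) return(f_n)
  f_i <- mott_bethe_ff(ion$Z, ion$xray, s)
  (1 - abs(q)) * f_n + abs(q) * f_i
}

#' Difference between a charged and the neutral scattering-factor curve
#'
#' Evaluates \eqn{f_{charged}(s(d)) - f_{neutral}(s(d))} over a grid of
#' resolutions with \eqn{s = 1/(2d)}. For anions the difference is large and
#' negative at low resolution and vanishes at high resolution, the mechanism
#' behind charge detection by resolution selection.
#'
#' @param neutral neutral `scattering_species`.
#' @param charged_f function of s returning the charged scattering factor.
#' @param d_grid resolutions in Angstrom, all > 0.
#' @return data.frame with columns `d`, `s`, `f_neutral`, `f_charged`, `df`.
#' @export
ff_difference_profile <- function(neutral, charged_f, d_grid) {
  if (any(d_grid <= 0)) stop("resolutions must be > 0")
  s <- 1 / (2 * d_grid)
  f_n <- evaluate_gaussian_ff(neutral, s)
  f_c <- charged_f(s)
  data.frame(d = d_grid, s = s, f_neutral = f_n, f_charged = f_c,
             df = f_c - f_n)
}

#' Scattering factor curve on a frequency or resolution grid
#'
#' Convenience export used by plotting and the command-line interface.
#'
#' @param element element symbol.
#' @param charge charge state in \[-1, 1\].
#' @param s frequency grid in 1/Angstrom, or NULL to derive from `d`.
#' @param d resolution grid in Angstrom (used when `s` is NULL).
#' @return data.frame with columns `d`, `s`, `f`.
#' @export
ff_curve <- function(element, charge = 0, s = NULL, d = NULL) {
  if (is.null(s)) {
    if (is.null(d)) d <- seq(20, 1, by = -0.1)
    s <- 1 / (2 * d)
  } else d <- ifelse(s > 0, 1 / (2 * s), Inf)
  data.frame(d = d, s = s, f = electron_ff(element, s, charge))
}
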