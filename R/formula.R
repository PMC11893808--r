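## Exact monoisotopic masses (Da) of the elements handled by the pipeline.
## Carbon is exactly 12 by definition of the unified atomic mass scale.
ELEMENT_MASS <- c(
  c = 12,
  h = 1.00782503,
  n = 14.00307401,
  o = 15.99491462,
  s = 31.97207069,
  p = 30.97376200
)

#' Physical constants used in ion arithmetic
#'
#' Mass of the proton (Da), the spacing between a monoisotopic peak and its
#' single \eqn{^{13}C} isotopologue (Da), and the natural \eqn{^{13}C/^{12}C}
#' abundance ratio per carbon atom.
#'
#' @keywords internal
PROTON_MASS <- 1.00727646
C13_DELTA <- 1.0033548
C13_ABUNDANCE <- 0.0107

ELEMENTS <- c("c", "h", "n", "o", "s", "p")

#' Neutral monoisotopic mass of molecular formulae
#'
#' @param formulas data frame with integer columns `c`, `h`, `n`, `o`, `s`,
#'   `p` (one row per formula).
#' @return numeric vector of neutral monoisotopic masses in Da.
#' @export
#' @examples
#' formula_mass(parse_formula("C6H10O5"))
formula_mass <- function(formulas) {
  stopifnot(all(ELEMENTS %in% names(formulas)))
  as.numeric(as.matrix(formulas[, ELEMENTS, drop = FALSE]) %*% ELEMENT_MASS[ELEMENTS])
}

#' Double-bond equivalents
#'
#' DBE = 1 + (2C - H + N + P) / 2. Chemically valid neutral CHNOSP formulae
#' have integer, non-negative DBE.
#'
#' @inheritParams formula_mass
#' @return numeric vector (may be half-integer for invalid compositions).
#' @export
formula_dbe <- function(formulas) {
  1 + (2 * formulas$c - formulas$h + formulas$n + formulas$p) / 2
}

#' Render formulae as Hill-notation strings with explicit counts
#'
#' Carbon first, hydrogen second, remaining elements alphabetically
#' (N, O, P, S). Every non-zero element carries an explicit count, e.g.
#' `C6H10O5`, `C10H15N1O5`.
#'
#' @inheritParams formula_mass
#' @return character vector.
#' @export
formula_string <- function(formulas) {
  hill <- c("c", "h", "n", "o", "p", "s")
  sym <- c(c = "C", h = "H", n = "N", o = "O", p = "P", s = "S")
  out <- character(nrow(formulas))
  for (el in hill) {
    cnt <- formulas[[el]]
    out <- paste0(out, ifelse(cnt > 0, paste0(sym[[el]], cnt), ""))
  }
  out
}

#' Parse Hill-notation formula strings
#'
#' Accepts explicit (`C6H10N1O5`) and implicit (`C6H10NO5`) unit counts.
#'
#' @param x character vector of formula strings.
#' @return data frame with integer columns `c`, `h`, `n`, `o`, `s`, `p`.
#' @export
parse_formula <- function(x) {
  out <- matrix(0L, nrow = length(x), ncol = length(ELEMENTS),
                dimnames = list(NULL, ELEMENTS))
  rx <- gregexpr("([CHNOSP])([0-9]*)", x)
  for (i in seq_along(x)) {
    m <- regmatches(x[i], rx[i])[[1]]
    if (!length(m) || paste0(m, collapse = "") != x[i]) {
      stop("cannot parse formula string: ", x[i])
    }
    el <- tolower(substr(m, 1, 1))
    n <- suppressWarnings(as.integer(substring(m, 2)))
    n[is.na(n)] <- 1L
    for (j in seq_along(el)) {
      out[i, el[j]] <- out[i, el[j]] + n[j]
    }
  }
  as.data.frame(out)
}

#' Element count constraints for formula enumeration
#'
#' The default box covers the assignment window used for dissolved organic
#' matter in negative-mode ultrahigh-resolution MS: C 0-100, H 0-200,
#' O 0-50, N 0-4, S 0-2, P 0-1, singly charged deprotonated ions.
#'
#' @param c,h,n,o,s,p integer length-2 vectors, `c(min, max)` per element.
#' @param mass_range neutral mass window (Da) considered during enumeration.
#' @return object of class `element_constraints`.
#' @export
element_constraints <- function(c = base::c(0L, 100L), h = base::c(0L, 200L),
                                n = base::c(0L, 4L), o = base::c(0L, 50L),
                                s = base::c(0L, 2L), p = base::c(0L, 1L),
                                mass_range = base::c(100, 1000)) {
  box <- list(c = c, h = h, n = n, o = o, s = s, p = p)
  for (el in names(box)) {
    b <- box[[el]]
    if (length(b) != 2L || any(b < 0) || b[1] > b[2]) {
      stop("invalid bounds for element ", toupper(el))
    }
  }
  if (length(mass_range) != 2L || mass_range[1] <= 0 || mass_range[1] >= mass_range[2]) {
    stop("invalid mass_range")
  }
  structure(c(box, list(mass_range = as.numeric(mass_range))),
            class = "element_constraints")
}

## Chemical validity shared by enumeration, pool sampling and assignment:
## integer DBE >= 0 and at least one C and one H (carbon-free or
## hydrogen-free compositions are not meaningful organic matter formulae).
## Optional H/C and O/C screens follow common DOM assignment practice.
valid_formula <- function(formulas, hc_range = NULL, oc_max = NULL) {
  dbe <- formula_dbe(formulas)
  ok <- dbe >= 0 & abs(dbe - round(dbe)) < 1e-9 &
    formulas$c >= 1L & formulas$h >= 1L
  if (!is.null(hc_range)) {
    hc <- formulas$h / formulas$c
    ok <- ok & hc >= hc_range[1] & hc <= hc_range[2]
  }
  if (!is.null(oc_max)) {
    ok <- ok & formulas$o / formulas$c <= oc_max
  }
  ok
}
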