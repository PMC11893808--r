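## Per-formula molecular descriptors and van Krevelen categories.

#' Compute molecular descriptors for CHNOSP formulae
#'
#' For each formula computes H/C, O/C, DBE, DBE-O, the modified aromaticity
#' index and the nominal oxidation state of carbon:
#' \deqn{AI_{mod} = \frac{1 + C - 0.5O - S - 0.5(H + N + P)}{C - 0.5O - S - N - P}}
#' \deqn{NOSC = 4 - \frac{4C + H - 3N - 2O - 2S}{C}}
#' AImod is clamped to 0 when its numerator is negative or its denominator
#' is not positive, and to 1 from above, so that the index always lies in
#' \[0, 1\].
#'
#' @param formulas data frame with integer columns `c`, `h`, `n`, `o`, `s`,
#'   `p`; every formula must contain carbon.
#' @return data frame with columns `hc`, `oc`, `dbe`, `dbe_o`, `aimod`,
#'   `nosc`, `mass`.
#' @export
#' @examples
#' compute_descriptors(parse_formula(c("C1H4", "C1O2H0N0S0P0")))
compute_descriptors <- function(formulas) {
  if (any(formulas$c < 1)) {
    stop("carbon-free formulae have no descriptors; exclude them upstream")
  }
  C <- formulas$c; H <- formulas$h; N <- formulas$n
  O <- formulas$o; S <- formulas$s; P <- formulas$p
  num <- 1 + C - 0.5 * O - S - 0.5 * (H + N + P)
  den <- C - 0.5 * O - S - N - P
  aimod <- ifelse(num < 0 | den <= 0, 0, num / den)
  aimod <- pmin(aimod, 1)
  data.frame(
    hc = H / C,
    oc = O / C,
    dbe = formula_dbe(formulas),
    dbe_o = formula_dbe(formulas) - O,
    aimod = aimod,
    nosc = 4 - (4 * C + H - 3 * N - 2 * O - 2 * S) / C,
    mass = formula_mass(formulas)
  )
}

#' Exclusive elemental classes
#'
#' CHO, CHON, CHOS or CHOP. Formulae carrying several heteroatom types are
#' assigned by the precedence P > S > N so that the four classes partition
#' the data (the rarest heteroatom wins).
#'
#' @inheritParams compute_descriptors
#' @return character vector.
#' @export
classify_elemental <- function(formulas) {
  ifelse(formulas$p >= 1, "CHOP",
         ifelse(formulas$s >= 1, "CHOS",
                ifelse(formulas$n >= 1, "CHON", "CHO")))
}

#' Default molecular-category windows
#'
#' Ordered predicate windows on AImod and H/C; the first matching window
#' wins. Defaults follow the widely used van Krevelen convention:
#' condensed aromatics at AImod >= 0.67, aromatics at 0.5 <= AImod < 0.67,
#' highly unsaturated at AImod < 0.5 and H/C <= 1.5, unsaturated aliphatics
#' at 1.5 < H/C < 2.0, saturated at H/C >= 2.0. The CRAM
#' (carboxyl-rich alicyclic molecules) flag uses DBE-ratio windows
#' DBE/C 0.30-0.68, DBE/H 0.20-0.95, DBE/O 0.77-1.75; the oxy-aromatic
#' phytochemical flag is a configurable ratio box (O/C 0.1-0.85,
#' AImod >= 0.5, mass <= 800 Da by default).
#'
#' @return list with components `categories` (ordered list of bounds),
#'   `cram` and `phytochemical`.
#' @export
category_windows <- function() {
  list(
    categories = list(
      condensed_aromatic   = list(aimod_min = 0.67),
      aromatic             = list(aimod_min = 0.5, aimod_max = 0.67),
      highly_unsaturated   = list(aimod_max = 0.5, hc_max = 1.5),
      unsaturated_aliphatic = list(hc_min = 1.5, hc_max = 2.0, hc_min_open = TRUE,
                                   hc_max_open = TRUE),
      saturated            = list(hc_min = 2.0)
    ),
    cram = list(dbe_c = c(0.30, 0.68), dbe_h = c(0.20, 0.95),
                dbe_o = c(0.77, 1.75)),
    phytochemical = list(oc = c(0.1, 0.85), aimod_min = 0.5, mass_max = 800)
  )
}

#' Assign every formula to one molecular category plus flags
#'
#' @param descriptors result of [compute_descriptors()].
#' @param formulas the matching formula table (element counts).
#' @param windows window configuration, see [category_windows()].
#' @return data frame with `elemental_class`, `category` and logical flags
#'   `cram`, `phytochemical`, `aliphatic_with_nitrogen`.
#' @export
classify_category <- function(descriptors, formulas,
                              windows = category_windows()) {
  n <- nrow(descriptors)
  category <- rep(NA_character_, n)
  for (nm in names(windows$categories)) {
    w <- windows$categories[[nm]]
    hit <- rep(TRUE, n)
    if (!is.null(w$aimod_min)) hit <- hit & descriptors$aimod >= w$aimod_min
    if (!is.null(w$aimod_max)) hit <- hit & descriptors$aimod < w$aimod_max
    if (!is.null(w$hc_min)) {
      hit <- hit & if (isTRUE(w$hc_min_open)) descriptors$hc > w$hc_min
        else descriptors$hc >= w$hc_min
    }
    if (!is.null(w$hc_max)) {
      hit <- hit & if (isTRUE(w$hc_max_open)) descriptors$hc < w$hc_max
        else descriptors$hc <= w$hc_max
    }
    category[is.na(category) & hit] <- nm
  }
  if (anyNA(category)) {
    stop("category windows do not cover all formulae (",
         sum(is.na(category)), " uncovered); check the window configuration")
  }
  cw <- windows$cram
  with_o <- formulas$o >= 1
  cram <- with_o &
    descriptors$dbe / formulas$c >= cw$dbe_c[1] &
    descriptors$dbe / formulas$c <= cw$dbe_c[2] &
    descriptors$dbe / formulas$h >= cw$dbe_h[1] &
    descriptors$dbe / formulas$h <= cw$dbe_h[2] &
    ifelse(with_o, descriptors$dbe / formulas$o >= cw$dbe_o[1] &
             descriptors$dbe / formulas$o <= cw$dbe_o[2], FALSE)
  pw <- windows$phytochemical
  phyto <- descriptors$oc >= pw$oc[1] & descriptors$oc <= pw$oc[2] &
    descriptors$aimod >= pw$aimod_min & descriptors$mass <= pw$mass_max
  data.frame(
    elemental_class = classify_elemental(formulas),
    category = category,
    cram = cram,
    phytochemical = phyto,
    aliphatic_with_nitrogen =
      category %in% c("unsaturated_aliphatic", "saturated") & formulas$n >= 1
  )
}

#' Intensity-weighted descriptor summary of a formula subset in one sample
#'
#' Weights are the normalized intensities of the subset in the given
#' sample, re-normalized over the subset. Also reports unweighted
#' elemental-class and category composition shares (percent).
#'
#' @param mat an `fticr_matrix` (or bare formulae x samples matrix).
#' @param subset character vector of formula strings (must be non-empty in
#'   the sample).
#' @param sample sample id (column name).
#' @param windows category window configuration.
#' @return list with `n`, weighted means (`mass_wa`, `hc_wa`, `oc_wa`,
#'   `aimod_wa`, `nosc_wa`, `dbe_o_wa`), weighted `mass_sd`, and percentage
#'   tables `elemental_pct`, `category_pct`, `cram_pct`,
#'   `phytochemical_pct`, `aliphatic_n_pct`.
#' @export
weighted_summary <- function(mat, subset, sample,
                             windows = category_windows()) {
  m <- if (inherits(mat, "fticr_matrix")) mat$intensity else mat
  subset <- intersect(subset, rownames(m))
  if (!length(subset)) stop("empty formula subset")
  w <- m[subset, sample]
  if (sum(w) <= 0) stop("subset has zero intensity in sample ", sample)
  w <- w / sum(w)
  f <- parse_formula(subset)
  d <- compute_descriptors(f)
  cat <- classify_category(d, f, windows)
  wa <- function(x) sum(w * x)
  pct <- function(x) 100 * as.vector(table(factor(x)) / length(x))
  elem <- factor(cat$elemental_class, levels = c("CHO", "CHON", "CHOS", "CHOP"))
  catf <- factor(cat$category, levels = names(windows$categories))
  list(
    n = length(subset),
    mass_wa = wa(d$mass),
    mass_sd = sqrt(max(0, wa(d$mass^2) - wa(d$mass)^2)),
    hc_wa = wa(d$hc), oc_wa = wa(d$oc),
    aimod_wa = wa(d$aimod), nosc_wa = wa(d$nosc), dbe_o_wa = wa(d$dbe_o),
    elemental_pct = 100 * prop.table(table(elem)),
    category_pct = 100 * prop.table(table(catf)),
    cram_pct = 100 * mean(cat$cram),
    phytochemical_pct = 100 * mean(cat$phytochemical),
    aliphatic_n_pct = 100 * mean(cat$aliphatic_with_nitrogen)
  )
}
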