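## Compositional comparison of habitats: Bray-Curtis dissimilarity,
## non-metric multidimensional scaling and habitat-signal extraction.

#' Bray-Curtis dissimilarity between samples
#'
#' @param mat an `fticr_matrix` or a bare formulae x samples matrix with
#'   normalized columns.
#' @return symmetric sample x sample dissimilarity matrix with zero
#'   diagonal, values in \[0, 1\].
#' @export
bray_curtis <- function(mat) {
  m <- if (inherits(mat, "fticr_matrix")) mat$intensity else mat
  if (ncol(m) < 2) stop("Bray-Curtis needs at least 2 samples")
  if (any(colSums(m) <= 0)) stop("all-zero sample column")
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Two-dimensional NMDS of molecular composition
#'
#' Best-of-restarts non-metric multidimensional scaling of the Bray-Curtis
#' dissimilarities (Kruskal stress, monotone regression), via
#' [vegan::metaMDS()] without transformation of the normalized intensities.
#' Formula loadings are the intensity-weighted averages of the sample
#' coordinates (species scores); both sample coordinates and loadings are
#' rescaled per axis so the sample scores span \[-1, 1\], which puts the
#' habitat-signal threshold on a common scale.
#'
#' @param mat an `fticr_matrix` or formulae x samples matrix.
#' @param k number of dimensions (default 2).
#' @param seed integer seed; identical seeds give identical coordinates.
#' @param n_restarts random restarts (default 50).
#' @return object of class `dom_nmds`: `points` (samples x k), `loadings`
#'   (formulae x k), `stress`, `seed`, `n_restarts`, plus the `samples`
#'   table when available.
#' @export
nmds <- function(mat, k = 2, seed = 42L, n_restarts = 50L) {
  m <- if (inherits(mat, "fticr_matrix")) mat$intensity else mat
  comm <- t(m)
  set.seed(seed)
  fit <- vegan::metaMDS(comm, distance = "bray", k = k, try = n_restarts,
                        trymax = n_restarts, trace = 0,
                        autotransform = FALSE, wascores = TRUE,
                        expand = FALSE)
  pts <- fit$points
  pts <- sweep(pts, 2, colMeans(pts))
  scl <- apply(abs(pts), 2, max)
  scl[scl == 0] <- 1
  pts <- sweep(pts, 2, scl, "/")
  load <- sweep(sweep(fit$species, 2, colMeans(fit$points)), 2, scl, "/")
  structure(list(points = pts, loadings = load, stress = fit$stress,
                 seed = seed, n_restarts = n_restarts,
                 samples = if (inherits(mat, "fticr_matrix")) mat$samples,
                 fit = fit),
            class = "dom_nmds")
}

#' @export
print.dom_nmds <- function(x, ...) {
  cat("<dom_nmds> ", nrow(x$points), " samples, stress ",
      signif(x$stress, 4), "\n", sep = "")
  invisible(x)
}

#' Habitat-characteristic formulae from NMDS1 loadings
#'
#' Returns the formula sets loading at or below `-threshold` and at or
#' above `+threshold` on the first axis. When habitat assignments are
#' available, each side is named after the habitat whose sample centroid
#' falls on it.
#'
#' @param result a `dom_nmds`.
#' @param threshold positive loading cutoff (default 0.45 on the rescaled
#'   axis).
#' @param habitats optional character vector of habitat codes per sample
#'   (defaults to the `samples` table carried by the result).
#' @return named list of two character vectors of formula strings.
#' @export
habitat_signal <- function(result, threshold = 0.45, habitats = NULL) {
  stopifnot(inherits(result, "dom_nmds"), threshold > 0)
  l1 <- result$loadings[, 1]
  if (diff(range(l1, na.rm = TRUE)) < .Machine$double.eps) {
    stop("degenerate first axis: all loadings equal")
  }
  neg <- rownames(result$loadings)[!is.na(l1) & l1 <= -threshold]
  pos <- rownames(result$loadings)[!is.na(l1) & l1 >= threshold]
  sides <- list(negative = neg, positive = pos)
  if (is.null(habitats) && !is.null(result$samples)) {
    habitats <- result$samples$habitat
  }
  if (!is.null(habitats)) {
    cent <- tapply(result$points[, 1], habitats, mean)
    if (length(cent) == 2) {
      names(sides) <- c(names(cent)[which.min(cent)],
                        names(cent)[which.max(cent)])
    }
  }
  sides
}
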