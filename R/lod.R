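#' Two-point LOD score
#'
#' `Z(theta) = log10 L(theta) - log10 L(0.5)`: the classical two-point LOD
#' score comparing linkage at recombination fraction `theta` against free
#' recombination.  `Z(0.5)` is identically 0; `Z >= 3` is the conventional
#' significance threshold.
#'
#' @inheritParams two_locus_likelihood
#' @return the LOD score (log10 units); `-Inf` if the data are impossible at
#'   `theta` but possible at 0.5.
#' @export
lod <- function(ped, gt, model, theta) {
  l05 <- peel_loglik10(ped, gt, model, 0.5)
  if (!is.finite(l05))
    stop_lx("lx_impossible_data",
            "data have zero likelihood under the model (even at theta = 0.5)")
  peel_loglik10(ped, gt, model, theta) - l05
}

new_lod_curve <- function(marker_name, grid, values, z_max, theta_max,
                          refined, family_ids = NULL) {
  structure(list(marker_name = marker_name,
                 theta_grid = as.numeric(grid),
                 lod_values = as.numeric(values),
                 z_max = as.numeric(z_max),
                 theta_max = as.numeric(theta_max),
                 refined = isTRUE(refined),
                 family_ids = family_ids),
            class = "lod_curve")
}

# golden-section search for the maximiser of f on [lo, hi]; ties and the
# final midpoint resolve toward smaller theta via the >= comparison.
golden_section_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  xm <- (a + b) / 2
  list(theta = xm, z = f(xm))
}

#' Fit a LOD curve and estimate the recombination fraction
#'
#' Evaluates the two-point LOD score on a grid of recombination fractions
#' and (by default) refines the maximum by golden-section search bracketed
#' around the best grid point, reporting `z_max` and `theta_max`.  This is
#' the package's central fitting function; the returned object has
#' [print()], [summary()], [coef()] and [plot()] methods.
#'
#' @inheritParams two_locus_likelihood
#' @param grid ascending vector of recombination fractions in `[0, 0.5]`;
#'   the default is the conventional reporting grid.
#' @param refine if `TRUE` (default), `theta_max` is refined off-grid by
#'   golden-section search (tolerance 1e-4 in `theta`); if `FALSE`, the grid
#'   argmax is reported, reproducing grid-only tabulations exactly.  Ties
#'   break toward smaller `theta`.
#' @return object of class `lod_curve` with elements `marker_name`,
#'   `theta_grid`, `lod_values`, `z_max`, `theta_max`.
#' @examples
#' \dontrun{
#' cv <- lod_curve(ped, gt, disease_model())
#' coef(cv)   # c(z_max = ..., theta_max = ...)
#' plot(cv)
#' }
#' @export
lod_curve <- function(ped, gt, model, grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                      refine = TRUE) {
  stopifnot(all(grid >= 0), all(grid <= 0.5), !is.unsorted(grid, strictly = TRUE))
  l05 <- peel_loglik10(ped, gt, model, 0.5)
  if (!is.finite(l05))
    stop_lx("lx_impossible_data",
            "data have zero likelihood under the model (even at theta = 0.5)")
  zfun <- function(th) peel_loglik10(ped, gt, model, th) - l05
  z <- vapply(grid, zfun, numeric(1))
  i <- which.max(z)                       # first maximum: smaller theta wins ties
  z_max <- z[i]; theta_max <- grid[i]
  if (refine && length(grid) > 1L) {
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    ref <- golden_section_max(zfun, lo, hi, tol = 1e-4)
    if (ref$z > z_max) { z_max <- ref$z; theta_max <- ref$theta }
  }
  new_lod_curve(gt$marker$name, grid, z, z_max, theta_max, refine,
                family_ids = ped$family_id)
}

#' Build a LOD curve from precomputed grid values
#'
#' For working with published LOD tables: takes the grid and the printed
#' `Z(theta)` values and reports the grid argmax (no off-grid refinement is
#' possible without the underlying likelihood).  Ties break toward smaller
#' `theta`.
#'
#' @param marker_name marker name.
#' @param grid ascending vector of recombination fractions.
#' @param values LOD scores at the grid points.
#' @return a `lod_curve` object (with `refined = FALSE`).
#' @export
lod_curve_from_values <- function(marker_name, grid, values) {
  stopifnot(length(grid) == length(values),
            !is.unsorted(grid, strictly = TRUE))
  i <- which.max(values)
  new_lod_curve(marker_name, grid, values, values[i], grid[i], FALSE)
}

#' Combine LOD curves across independent families
#'
#' Families are independent, so their log-likelihoods -- and hence their LOD
#' scores -- add pointwise over the shared `theta` grid.  `z_max` and
#' `theta_max` are recomputed from the summed curve (grid argmax, ties
#' toward smaller `theta`).
#'
#' @param ... `lod_curve` objects (or a single list of them) on identical
#'   grids.
#' @return a combined `lod_curve`.
#' @export
combine_families <- function(...) {
  curves <- list(...)
  if (length(curves) == 1L && !inherits(curves[[1]], "lod_curve"))
    curves <- curves[[1]]
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "lod_curve")))
  grid <- curves[[1]]$theta_grid
  for (cv in curves[-1])
    if (length(cv$theta_grid) != length(grid) ||
        any(abs(cv$theta_grid - grid) > 1e-12))
      stop_lx("lx_mismatched_grid",
              "LOD curves must share an identical theta grid to be combined")
  z <- Reduce(`+`, lapply(curves, `[[`, "lod_values"))
  i <- which.max(z)
  new_lod_curve(paste(unique(vapply(curves, `[[`, character(1), "marker_name")),
                      collapse = "+"),
                grid, z, z[i], grid[i], FALSE,
                family_ids = unlist(lapply(curves, `[[`, "family_ids")))
}

#' @export
print.lod_curve <- function(x, digits = 2, ...) {
  cat(sprintf("Two-point LOD curve for %s\n", x$marker_name))
  tab <- rbind(theta = x$theta_grid, Z = round(x$lod_values, digits))
  colnames(tab) <- rep("", ncol(tab))
  print(tab)
  cat(sprintf("Z_max = %.*f at theta = %.*f%s\n", digits, x$z_max,
              if (x$refined) 4 else digits, x$theta_max,
              if (x$refined) " (golden-section refined)" else " (grid argmax)"))
  invisible(x)
}

#' @export
summary.lod_curve <- function(object, ...) {
  cat(sprintf("Marker %s: Z_max = %.2f at theta_max = %.4f\n",
              object$marker_name, object$z_max, object$theta_max))
  sig <- if (object$z_max >= 3) "significant (Z >= 3)"
         else if (object$z_max <= -2) "excluded (Z <= -2)" else "inconclusive"
  cat(sprintf("Linkage evidence: %s\n", sig))
  invisible(object)
}

#' @export
coef.lod_curve <- function(object, ...) {
  c(z_max = object$z_max, theta_max = object$theta_max)
}

#' @export
plot.lod_curve <- function(x, ...) {
  graphics::plot(x$theta_grid, x$lod_values, type = "b", pch = 16,
                 xlab = expression(theta), ylab = "LOD score Z",
                 main = sprintf("Two-point LOD: %s", x$marker_name), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::points(x$theta_max, x$z_max, col = 2, pch = 8)
  invisible(x)
}
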