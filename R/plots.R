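#' @include AllClasses.R AllGenerics.R
NULL

#' Contour map of a free-energy landscape
#'
#' Filled-image rendering of deltaF over the grid with contour lines.
#' Empty bins are shown at the display cap (max occupied deltaF + RT); path
#' bins, when a \linkS4class{ReactionPath} is supplied, are overdrawn.
#'
#' @param grid a \linkS4class{LandscapeGrid} with deltaF filled.
#' @param path optional \linkS4class{ReactionPath} to overlay.
#' @param ... passed to \code{image}.
#' @return invisibly, the plotted deltaF matrix (capped).
#' @export
plotLandscape <- function(grid, path = NULL, ...) {
  stopifnot(is(grid, "LandscapeGrid"))
  if (!is.finite(grid@rt)) stop("apply freeEnergy() before plotting")
  z <- grid@deltaF
  cap <- max(z[grid@counts > 0]) + grid@rt
  z[is.na(z)] <- cap
  graphics::image(grid@midpoints[[1L]], grid@midpoints[[2L]], z,
    col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
    xlab = "axis 1 (Angstrom)", ylab = "axis 2 (Angstrom)", ...
  )
  graphics::contour(grid@midpoints[[1L]], grid@midpoints[[2L]], z,
                    add = TRUE, col = "grey30", nlevels = 8)
  if (!is.null(path)) {
    graphics::lines(
      grid@midpoints[[1L]][path@binSequence[, 1L]],
      grid@midpoints[[2L]][path@binSequence[, 2L]],
      col = "red", lwd = 2
    )
  }
  invisible(z)
}

#' Native-vs-total contact plane
#'
#' Scatter of native contacts against total contacts per frame (the
#' Pande-Rokhsar plane), coloured by classification when one is given;
#' native, molten-globule and unfolded populations separate into clusters.
#'
#' @param series a \linkS4class{ContactSeries}.
#' @param classes optional factor from \code{\link{classifyMoltenGlobule}}.
#' @param ... passed to \code{plot}.
#' @export
plotContactPlane <- function(series, classes = NULL, ...) {
  stopifnot(is(series, "ContactSeries"))
  col <- if (is.null(classes)) "grey40" else {
    c(native = "#1b7837", molten_globule = "#f1a340",
      unfolded = "#762a83")[as.character(classes)]
  }
  graphics::plot(series@total, series@q,
    col = col, pch = 16, cex = 0.6,
    xlab = "total contacts", ylab = "native contacts", ...
  )
  invisible(NULL)
}

#' Free-energy profile along the reaction coordinate
#'
#' @param path a \linkS4class{ReactionPath}.
#' @param ... passed to \code{plot}.
#' @export
plotProfile <- function(path, ...) {
  stopifnot(is(path, "ReactionPath"))
  graphics::plot(path@arcLength, path@profile,
    type = "l", lwd = 2,
    xlab = "arc length (Angstrom)", ylab = "deltaF (kcal/mol)", ...
  )
  graphics::abline(h = max(path@profile) - path@rt, lty = 2, col = "grey50")
  invisible(NULL)
}
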