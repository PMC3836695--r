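# Parametric synthetic cleft masks with analytic ground truth, used to
# validate the morphometric indices on boundaries of known geometry.

#' Synthetic cleft-shaped label mask
#'
#' Rasterizes an epithelial slab carrying a single cleft of known geometry
#' into an integer label mask (1 = epithelium, 0 = matrix), together with
#' the analytic values of the three morphometric indices implied by the
#' generating parameters. \code{"V"} produces straight walls converging at
#' a sharp apex; \code{"U"} blunts the apex with a circular cap (walls
#' still flare to the mouth — a boundary-curvature method that grows
#' straight-line fits from the deepest point cannot traverse parallel-wall
#' channels, and real cleft profiles flare). A horizontal apex offset
#' introduces a known tilt. The slab's own corners are rounded: square
#' convex corners subtend sharper angles than gentle cleft bottoms, which
#' no real tissue boundary exhibits. Optional raster noise jitters the
#' wall positions by +-\code{noise} pixels.
#'
#' @param width,height Mask dimensions in pixels.
#' @param depth Cleft depth in pixels (apex below the slab surface).
#' @param mouthHalfWidth Half-width of the cleft mouth in pixels.
#' @param apexOffset Horizontal offset of the apex from the mouth centre
#'   (pixels); nonzero values tilt the cleft.
#' @param shape \code{"V"} or \code{"U"}.
#' @param tipRadius Radius of the blunt tip cap for \code{"U"}.
#' @param surfaceY Row of the slab surface (epithelium occupies
#'   \code{y >= surfaceY} inside the margins).
#' @param margin Matrix margin kept around the slab.
#' @param noise Uniform wall jitter amplitude in pixels (0 = exact).
#' @param seed Seed for the jitter.
#' @return Integer mask matrix \code{[x, y]} with attribute \code{truth}: a
#'   list with the generating \code{center}, \code{extrema}, \code{depth},
#'   \code{spanning}, \code{tilt}.
#' @export
syntheticCleftMask <- function(width = 120L, height = 90L, depth = 30,
                               mouthHalfWidth = 12, apexOffset = 0,
                               shape = c("V", "U"), tipRadius = 4,
                               surfaceY = 25L, margin = 8L, noise = 0,
                               seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(depth > 0, mouthHalfWidth > 0)
  cx <- width / 2
  e1 <- c(cx - mouthHalfWidth, surfaceY)
  e2 <- c(cx + mouthHalfWidth, surfaceY)
  apex <- c(cx + apexOffset, surfaceY + depth)
  if (apex[2] > height - margin - 2) stop("cleft deeper than the slab")

  mask <- matrix(0L, width, height)
  mask[(margin + 1):(width - margin), surfaceY:(height - margin)] <- 1L

  # round the slab's own corners (radius 14)
  rc <- 14
  corners <- list(c(margin + 1, surfaceY, 1, 1),
                  c(width - margin, surfaceY, -1, 1),
                  c(margin + 1, height - margin, 1, -1),
                  c(width - margin, height - margin, -1, -1))
  for (cr in corners) {
    ccx <- cr[1] + cr[3] * rc; ccy <- cr[2] + cr[4] * rc
    for (y in seq.int(cr[2], ccy)) {
      for (x in seq.int(cr[1], ccx)) {
        if ((x - ccx)^2 + (y - ccy)^2 > rc^2) mask[x, y] <- 0L
      }
    }
  }

  if (noise > 0) set.seed(seed)
  jit <- function(n) if (noise > 0) runif(n, -noise, noise) else numeric(n)

  rb <- if (shape == "U") min(tipRadius, mouthHalfWidth / 2) else 0
  capCy <- apex[2] - rb
  # carve up to one row above the analytic apex so the deepest epithelial
  # boundary pixel sits at the apex itself
  for (y in surfaceY:(ceiling(apex[2]) - 1L)) {
    t <- (y - surfaceY) / depth          # 0 at mouth, 1 at apex
    lo <- e1[1] + t * (apex[1] - e1[1])
    hi <- e2[1] + t * (apex[1] - e2[1])
    if (rb > 0 && y >= capCy - rb) {
      half <- sqrt(max(0, rb^2 - (y - capCy)^2))
      lo <- min(lo, apex[1] - half)
      hi <- max(hi, apex[1] + half)
    }
    lo <- lo + jit(1); hi <- hi + jit(1)
    xr <- seq.int(max(1, ceiling(lo)), min(width, floor(hi)))
    if (length(xr) && hi >= lo) mask[xr, y] <- 0L
  }

  mid <- (e1 + e2) / 2
  v <- mid - apex
  u1 <- e1 - apex; u2 <- e2 - apex
  spanning <- acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))) * 180 / pi
  seg <- e2 - e1
  th <- acos(pmin(1, pmax(-1,
    sum(seg * v) / sqrt(sum(seg^2) * sum(v^2))))) * 180 / pi
  truth <- list(center = apex, extrema = rbind(e1, e2),
                depth = sqrt(sum(v^2)), spanning = spanning,
                tilt = min(th, 180 - th))
  attr(mask, "truth") <- truth
  mask
}

#' Rotate a label mask by 90 degrees
#'
#' Utility for the rotation-equivariance checks: rotates the mask a quarter
#' turn counter-clockwise in lattice coordinates.
#'
#' @param mask Integer matrix.
#' @return Rotated matrix.
#' @export
rotateMask90 <- function(mask) {
  t(mask)[ncol(mask):1, , drop = FALSE]
}
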