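# Cleft morphometrics: boundary tracing, cleft-centre location by the
# 8-distance neighbour angle, extrema by incremental line-fit MSE, and the
# three indices (depth, spanning angle, tilt angle) with the discard/failed
# filters and unit conversions.

#' Unit conversions
#'
#' Spatial and temporal calibration of the model: micrometres per pixel
#' (default 1.06, from matching the simulated base-case depth to the
#' ex-vivo mean) and seconds per Monte-Carlo step (default 48, so 1500 MCS
#' correspond to a 20-hour growth period).
#'
#' @param umPerPx Micrometres per pixel.
#' @param secondsPerMcs Seconds per MCS.
#' @return Named list of class \code{unitConversions}.
#' @export
#' @examples
#' mcsToHours(1500)  # 20 h
unitConversions <- function(umPerPx = 1.06, secondsPerMcs = 48) {
  stopifnot(umPerPx > 0, secondsPerMcs > 0)
  structure(list(umPerPx = umPerPx, secondsPerMcs = secondsPerMcs),
            class = c("unitConversions", "list"))
}

#' @rdname unitConversions
#' @param mcs Monte-Carlo steps.
#' @param conv A \code{unitConversions}.
#' @export
mcsToHours <- function(mcs, conv = unitConversions()) {
  mcs * conv$secondsPerMcs / 3600
}

#' @rdname unitConversions
#' @param px Pixels.
#' @export
pxToUm <- function(px, conv = unitConversions()) px * conv$umPerPx

# coerce input to a binary epithelium mask [x, y]: GlandSim -> non-matrix
# owners; integer label mask -> non-zero labels
epithelialMask <- function(x) {
  if (is(x, "GlandSim")) {
    own <- ownerMatrix(x)
    ct <- cpm_cells(x@ptr)
    epithIds <- ct$id[ct$type != CELL_TYPES[["MATRIX"]]]
    mask <- matrix(0L, nrow(own), ncol(own))
    mask[own %in% epithIds] <- 1L
    mask
  } else if (is.matrix(x)) {
    mask <- matrix(0L, nrow(x), ncol(x))
    mask[x != 0] <- 1L
    mask
  } else stop("expected a GlandSim or an integer label mask (0 = matrix)")
}

#' Trace the epithelium-matrix boundary
#'
#' Returns the ordered closed contour of epithelial sites adjacent to the
#' matrix, counter-clockwise (in lattice coordinates with y increasing
#' downward). Input may be a [GlandSim-class] (all non-matrix cells form
#' the epithelium) or an integer label-mask image (0 = matrix), so the same
#' morphometrics can be applied to segmented microscopy.
#'
#' @param x A \code{GlandSim} or integer matrix label mask.
#' @return Matrix with columns \code{x}, \code{y} (1-based site
#'   coordinates) and attribute \code{closed = TRUE}.
#' @export
traceBoundary <- function(x) {
  mask <- epithelialMask(x)
  if (!any(mask == 1L)) stop("no epithelial sites in input (0 components)")
  lab <- EBImage::bwlabel(mask)
  ncomp <- max(lab)
  if (ncomp != 1)
    stop("expected one epithelial component, found ", ncomp)
  oc <- EBImage::ocontour(lab)[[1]] + 1L   # 0-based -> lattice coordinates
  colnames(oc) <- c("x", "y")
  # normalise orientation: positive shoelace area = counter-clockwise
  n <- nrow(oc)
  nxt <- c(2:n, 1)
  signedArea <- sum(oc[, 1] * oc[nxt, 2] - oc[nxt, 1] * oc[, 2]) / 2
  if (signedArea < 0) oc <- oc[n:1, , drop = FALSE]
  attr(oc, "closed") <- TRUE
  oc
}

wrapIdx <- function(i, n) ((i - 1L) %% n) + 1L

#' Locate the cleft centre on a boundary trace
#'
#' For each boundary point, computes the angle subtended at it by its
#' 8-distance neighbours along the trace on either side; the cleft centre —
#' the deepest point of the cleft — has the lowest such angle. Points whose
#' angle is not below \code{maxAngle} are not cleft-like (a straight
#' boundary segment subtends 180 degrees), so a trace with no angle below
#' the threshold reports no cleft.
#'
#' @param trace Boundary trace from [traceBoundary()].
#' @param offset Neighbour distance along the trace in index positions.
#' @param maxAngle Largest angle (degrees) still considered cleft-like.
#' @param candidates Optional integer vector restricting the candidate
#'   indices (used for multi-cleft extraction).
#' @return Index of the minimizing point (ties broken by smallest index),
#'   with the angle in attribute \code{angle}; \code{NA} if no candidate
#'   angle falls below \code{maxAngle}.
#' @export
findCleftCenter <- function(trace, offset = 8L, maxAngle = 150,
                            candidates = NULL) {
  n <- nrow(trace)
  closed <- isTRUE(attr(trace, "closed"))
  if (n <= 2L * offset) stop("trace too short for the configured offset")
  idx <- seq_len(n)
  if (!closed) idx <- idx[idx > offset & idx <= n - offset]
  if (!is.null(candidates)) idx <- intersect(idx, candidates)
  if (!length(idx)) return(NA_integer_)
  angAll <- traceAngles(trace, offset)
  ang <- angAll[idx]
  best <- which(ang < maxAngle)
  if (!length(best)) return(NA_integer_)
  k <- idx[best[which.min(ang[best])]]
  # the discrete angle minimum can sit a point or two up one wall when
  # the cleft is tilted; among near-minimal neighbours, prefer the point
  # of greatest prominence (perpendicular distance to the chord joining
  # its offset neighbours) — the deepest point of the cleft
  plateau <- intersect(idx[abs(ang - angAll[k]) <= 5],
                       wrapIdx(k + (-4:4), nrow(trace)))
  if (length(plateau) > 1) {
    n <- nrow(trace)
    prom <- vapply(plateau, function(i) {
      a <- trace[wrapIdx(i - offset, n), ]
      b <- trace[wrapIdx(i + offset, n), ]
      ch <- b - a
      if (all(ch == 0)) return(0)
      nrm <- c(-ch[2], ch[1]) / sqrt(sum(ch^2))
      abs(sum((trace[i, ] - a) * nrm))
    }, 0)
    k <- plateau[which.max(prom)]
  }
  structure(k, angle = angAll[k])
}

traceAngles <- function(trace, offset = 8L) {
  n <- nrow(trace)
  i <- seq_len(n)
  a <- trace[wrapIdx(i - offset, n), , drop = FALSE]
  b <- trace[wrapIdx(i + offset, n), , drop = FALSE]
  v1 <- a - trace; v2 <- b - trace
  d <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Find the cleft extrema by incremental line-fit MSE
#'
#' Starting at the cleft centre, points are progressively included along
#' each side of the boundary; a total-least-squares line is refit after
#' each inclusion and the mean squared perpendicular residual computed.
#' The extremum on each side is the last included index before the MSE
#' first exceeds the threshold; if a side exhausts its available span the
#' extremum is the span end (flagged in the \code{exhausted} attribute).
#'
#' Because the window mean reacts sluggishly once a long straight wall
#' has been included, the raw stop index runs a few points past the cleft
#' mouth onto the bud surface. On noiseless boundaries (analytic masks)
#' \code{refineMouth = TRUE} corrects this by moving the extremum to the
#' sharp bend near the window's far end. On rough simulated or segmented
#' boundaries the raw stop is the calibrated behaviour and the default.
#'
#' @param trace Boundary trace.
#' @param center Centre index from [findCleftCenter()].
#' @param mseThreshold MSE threshold in squared pixels.
#' @param maxSpan Largest number of points explored per side (defaults to
#'   a quarter of the trace).
#' @param refineMouth Apply the mouth-overshoot correction (recommended
#'   for noiseless analytic boundaries; see Details).
#' @return Integer vector \code{c(left, right)} of trace indices, attribute
#'   \code{exhausted} a logical pair.
#' @export
findExtrema <- function(trace, center, mseThreshold = 2,
                        maxSpan = NULL, refineMouth = FALSE) {
  n <- nrow(trace)
  closed <- isTRUE(attr(trace, "closed"))
  if (is.null(maxSpan)) maxSpan <- max(2L, floor(n / 4))
  out <- integer(2)
  exhausted <- logical(2)
  for (side in 1:2) {
    dir <- if (side == 1) -1L else 1L
    k <- 1L
    repeat {
      kNext <- k + 1L
      if (kNext > maxSpan) { exhausted[side] <- TRUE; break }
      iNext <- center + dir * kNext
      if (!closed && (iNext < 1L || iNext > n)) { exhausted[side] <- TRUE; break }
      pts <- trace[wrapIdx(center + dir * (0:kNext), n), , drop = FALSE]
      if (lineFitMse(pts) > mseThreshold) break
      k <- kNext
    }
    # optional mouth-overshoot correction for noiseless boundaries: the
    # window mean reacts sluggishly once a long straight wall has been
    # included, so the raw stop index overshoots the cleft mouth onto the
    # flat surface by a few points; if the window bends sharply near its
    # far end (max deviation from the centre-to-end chord in the outer
    # part of the window), the extremum is moved to that bend
    if (refineMouth && k >= 8L) {
      win <- trace[wrapIdx(center + dir * (0:k), n), , drop = FALSE]
      chord <- win[k + 1L, ] - win[1L, ]
      nrm <- c(-chord[2], chord[1]) / sqrt(sum(chord^2))
      dev <- abs(as.matrix(sweep(win, 2, win[1L, ])) %*% nrm)
      j <- which.max(dev)
      # the bend must stand clear of the wall's own roughness (mid-wall
      # MSE, away from both the apex curvature and the bend itself)
      mid <- win[max(2L, round(0.25 * k)):ceiling(0.6 * (k + 1L)), ,
                 drop = FALSE]
      bar <- max(1.5, 4 * sqrt(lineFitMse(mid)))
      if (dev[j] > bar && j - 1L >= 0.5 * k && j <= k) k <- j - 1L
    }
    out[side] <- wrapIdx(center + dir * k, n)
  }
  structure(c(left = out[1], right = out[2]), exhausted = exhausted)
}

# perpendicular residuals of each point to the total-least-squares line
lineFitResiduals <- function(pts) {
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  cv <- crossprod(d) / nrow(pts)
  ev <- eigen(cv, symmetric = TRUE)
  normal <- ev$vectors[, 2]
  as.numeric(d %*% normal)
}

# mean squared perpendicular residual of the total-least-squares line
lineFitMse <- function(pts) {
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  cv <- crossprod(d) / nrow(pts)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  max(min(ev), 0)
}

#' Cleft measurement from centre and extrema
#'
#' Computes the three indices: depth — the distance from the cleft centre
#' to the midpoint of the segment joining the two extrema; spanning angle —
#' the angle formed at the centre by the segments to each extremum; tilt
#' angle — the smaller of the complementary angles between the extrema
#' segment and the centre-to-midpoint segment (a measure of the cleft's
#' perpendicularity to the bud surface).
#'
#' @param center Numeric \code{c(x, y)}.
#' @param extrema 2x2 matrix, one extremum per row.
#' @param conv Unit conversions for the micrometre field.
#' @return One-row data frame: centre and extrema coordinates,
#'   \code{depth_px}, \code{depth_um}, \code{spanning_deg}, \code{tilt_deg},
#'   \code{status} (\code{"valid"} or \code{"invalid"} for degenerate
#'   geometry; run [applyFilters()] for the discard/failed rules).
#' @export
measureCleft <- function(center, extrema, conv = unitConversions()) {
  e1 <- as.numeric(extrema[1, ]); e2 <- as.numeric(extrema[2, ])
  ctr <- as.numeric(center)
  mid <- (e1 + e2) / 2
  v <- mid - ctr
  depth <- sqrt(sum(v^2))
  u1 <- e1 - ctr; u2 <- e2 - ctr
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  seg <- e2 - e1; ns <- sqrt(sum(seg^2))
  degenerate <- n1 == 0 || n2 == 0 || ns == 0 || depth == 0
  if (degenerate) {
    spanning <- NA_real_; tilt <- NA_real_
  } else {
    spanning <- acos(pmin(1, pmax(-1, sum(u1 * u2) / (n1 * n2)))) * 180 / pi
    th <- acos(pmin(1, pmax(-1, sum(seg * v) / (ns * depth)))) * 180 / pi
    tilt <- min(th, 180 - th)
  }
  data.frame(cx = ctr[1], cy = ctr[2], e1x = e1[1], e1y = e1[2],
             e2x = e2[1], e2y = e2[2],
             depth_px = depth, depth_um = pxToUm(depth, conv),
             spanning_deg = spanning, tilt_deg = tilt,
             status = if (degenerate) "invalid" else "valid",
             stringsAsFactors = FALSE)
}

#' Discard / failed-cleft filters
#'
#' Applies the measurement filters in precedence order: clefts measuring
#' less than 5 pixels in depth are discarded as shallow; clefts exceeding
#' 160 degrees in spanning angle are discarded as wide; clefts with a tilt
#' angle below 45 degrees are labelled failed; all others are valid.
#'
#' @param m Measurement row(s) from [measureCleft()].
#' @param minDepthPx,maxSpanningDeg,minTiltDeg Filter thresholds.
#' @return \code{m} with \code{status} set to one of \code{"valid"},
#'   \code{"discarded_shallow"}, \code{"discarded_wide"},
#'   \code{"failed_tilt"} (rows already \code{"invalid"} are untouched).
#' @export
applyFilters <- function(m, minDepthPx = 5, maxSpanningDeg = 160,
                         minTiltDeg = 45) {
  status <- m$status
  ok <- status != "invalid"
  status[ok & m$depth_px < minDepthPx] <- "discarded_shallow"
  rest <- ok & m$depth_px >= minDepthPx
  status[rest & m$spanning_deg > maxSpanningDeg] <- "discarded_wide"
  rest <- rest & m$spanning_deg <= maxSpanningDeg
  status[rest & m$tilt_deg < minTiltDeg] <- "failed_tilt"
  status[rest & m$tilt_deg >= minTiltDeg] <- "valid"
  m$status <- status
  m
}

#' Fill micrometre / hour fields of a measurement
#'
#' @param m Measurement rows.
#' @param conv A [unitConversions()].
#' @return \code{m} with \code{depth_um} recomputed (and \code{time_h} if a
#'   \code{mcs} column is present).
#' @export
convertUnits <- function(m, conv = unitConversions()) {
  m$depth_um <- pxToUm(m$depth_px, conv)
  if (!is.null(m$mcs)) m$time_h <- mcsToHours(m$mcs, conv)
  m
}

#' Measure clefts on a simulation state or label mask
#'
#' Runs the full pipeline: boundary trace, cleft-centre location, extrema
#' search, the three indices, and the discard/failed filters. For
#' multi-cleft states, each detected cleft's span is masked out of the
#' candidate set and detection repeats, up to \code{nClefts}.
#'
#' @param x A [GlandSim-class] or integer label mask (0 = matrix).
#' @param nClefts Number of clefts to extract (defaults to the number of
#'   cleft descriptors for a simulation, else 1).
#' @param offset,maxAngle See [findCleftCenter()].
#' @param mseThreshold,refineMouth See [findExtrema()].
#' @param conv Unit conversions.
#' @return Data frame with one row per detected cleft (zero rows when no
#'   cleft-like boundary point exists).
#' @export
measureClefts <- function(x, nClefts = NULL, offset = 8L, maxAngle = 150,
                          mseThreshold = 2, refineMouth = FALSE,
                          conv = unitConversions()) {
  if (is.null(nClefts))
    nClefts <- if (is(x, "GlandSim") && length(x@clefts)) length(x@clefts) else 1L
  trace <- traceBoundary(x)
  n <- nrow(trace)
  candidates <- seq_len(n)
  if (is(x, "GlandSim")) {
    # anchored (slab) geometries: boundary segments running along the
    # frozen frame are tissue edge, not epithelium-matrix interface; a
    # candidate centre must have its whole angle window on the free
    # boundary so frame corners are never mistaken for cleft centres
    dm <- latticeDim(x)
    frameAdj <- trace[, 1] <= 2 | trace[, 1] >= dm[["width"]] - 1 |
                trace[, 2] <= 2 | trace[, 2] >= dm[["height"]] - 1
    if (any(frameAdj)) {
      bad <- which(frameAdj)
      windows <- unique(as.vector(outer(bad, -offset:offset, "+")))
      candidates <- setdiff(candidates, wrapIdx(windows, n))
    }
  }
  out <- list()
  for (k in seq_len(nClefts)) {
    ctr <- findCleftCenter(trace, offset = offset, maxAngle = maxAngle,
                           candidates = candidates)
    if (is.na(ctr)) break
    ext <- findExtrema(trace, ctr, mseThreshold = mseThreshold,
                       refineMouth = refineMouth)
    m <- measureCleft(trace[ctr, ], trace[ext, , drop = FALSE], conv = conv)
    m <- applyFilters(m)
    m$cleft <- k
    out[[k]] <- m
    # mask the detected span (extrema inclusive) from further candidates
    span <- spanIndices(ext[["left"]], ext[["right"]], n)
    candidates <- setdiff(candidates, span)
    if (length(candidates) <= 2L * offset) break
  }
  if (!length(out)) {
    empty <- measureCleft(c(NA, NA), matrix(NA_real_, 2, 2), conv)[0, ]
    empty$cleft <- integer(0)
    return(empty)
  }
  do.call(rbind, out)
}

# indices along the (closed) trace from left to right the short way through
# the cleft centre
spanIndices <- function(left, right, n) {
  if (left <= right) left:right else c(left:n, 1:right)
}
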