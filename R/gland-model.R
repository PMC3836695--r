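# Gland geometry: single-cleft and three-cleft organ configurations, cell
# typing, FPP link topology with depth-dependent target distances, and the
# named parameter presets.

#' Geometry and engine configuration for the gland models
#'
#' Defaults reproduce the study conditions: a homogeneous grid of 6x6-pixel
#' square cells, a six-cell-deep cleft totalling 36 pixels, one-cell-thick
#' outer columnar (OCC) layer, a marginal increase in the IPC target
#' perimeter over the square-perimeter baseline of 24, quadratic constraint
#' strengths lambda_area = 2 and lambda_perimeter = 2, and T = 10.
#'
#' @param cellSide Cell side length in pixels.
#' @param cleftWallCells Cells per cleft wall; \code{cleftWallCells *
#'   cellSide} must equal \code{cleftDepthTarget}.
#' @param cleftDepthTarget Total designed cleft depth in pixels.
#' @param epithRows,epithCols Epithelium size in cells.
#' @param latticeWidth,latticeHeight Lattice size in pixels (includes the
#'   frozen one-site frame).
#' @param anchor \code{"slab"} (default): local-patch geometry — the
#'   epithelium spans the lattice width and rests on the bottom frame with
#'   matrix above, as in the single-cleft model; \code{"island"}: the
#'   epithelium floats inside the matrix, as in the organ-level model.
#' @param nClefts 1 (single-cleft model) or 3 (organ model).
#' @param occPerimTarget,ipcPerimTarget,cleftPerimTarget Target perimeters
#'   in unit-edge counts. The OCC value is the square baseline; IPCs get a
#'   marginal increase so they take on more irregular shapes.
#' @param lambdaArea,lambdaPerim Constraint strengths.
#' @param cleftVerticalTarget Target centroid distance (pixels) of the
#'   vertical links down each cleft wall. Slightly above the cell side so
#'   the wall stack stays extended against compression by the surrounding
#'   tissue; a calibration constant of the base case.
#' @param temperature Boltzmann temperature T.
#' @param contactOrder Contact-energy neighbourhood order (1 to 4).
#' @param contactBaseline Named list of baseline contact energies for pairs
#'   not governed by the parameter set: \code{occOcc}, \code{ipcIpc},
#'   \code{occIpc}, \code{occMatrix}, \code{ipcMatrix}, \code{cleftEpith},
#'   \code{mitoticEpith}, \code{mitoticMatrix}, \code{matrixMatrix}. The
#'   defaults keep the required ordering: a lower penalty between OCCs than
#'   the epithelial baseline of 5, a higher penalty between IPCs, and an
#'   IPC-matrix penalty well above the OCC-matrix penalty.
#' @param rule Width-depth rule, see [widthDepthRule()].
#' @return A named list of class \code{glandConfig}.
#' @export
glandConfig <- function(cellSide = 6L, cleftWallCells = 6L,
                        cleftDepthTarget = 36L,
                        epithRows = 9L, epithCols = 14L,
                        latticeWidth = 86L, latticeHeight = 96L,
                        anchor = c("slab", "island"),
                        nClefts = 1L,
                        occPerimTarget = 24, ipcPerimTarget = 28,
                        cleftPerimTarget = 28,
                        lambdaArea = 2, lambdaPerim = 2,
                        temperature = 10, contactOrder = 4L,
                        cleftVerticalTarget = 7.2,
                        contactBaseline = list(
                          occOcc = 4, ipcIpc = 6, occIpc = 5,
                          occMatrix = 8, ipcMatrix = 20,
                          cleftEpith = 5, mitoticEpith = 5,
                          mitoticMatrix = 8, matrixMatrix = 0),
                        rule = widthDepthRule()) {
  anchor <- match.arg(anchor)
  cfg <- list(cellSide = as.integer(cellSide),
              anchor = anchor,
              cleftWallCells = as.integer(cleftWallCells),
              cleftDepthTarget = as.integer(cleftDepthTarget),
              epithRows = as.integer(epithRows),
              epithCols = as.integer(epithCols),
              latticeWidth = as.integer(latticeWidth),
              latticeHeight = as.integer(latticeHeight),
              nClefts = as.integer(nClefts),
              occPerimTarget = occPerimTarget,
              ipcPerimTarget = ipcPerimTarget,
              cleftPerimTarget = cleftPerimTarget,
              lambdaArea = lambdaArea, lambdaPerim = lambdaPerim,
              cleftVerticalTarget = cleftVerticalTarget,
              temperature = temperature,
              contactOrder = as.integer(contactOrder),
              contactBaseline = contactBaseline, rule = rule)
  if (cfg$cleftWallCells * cfg$cellSide != cfg$cleftDepthTarget)
    stop("cleftWallCells * cellSide must equal cleftDepthTarget")
  if (!cfg$nClefts %in% c(1L, 3L)) stop("nClefts must be 1 or 3")
  if (cfg$ipcPerimTarget <= cfg$occPerimTarget)
    stop("IPC target perimeter must exceed the OCC target perimeter")
  class(cfg) <- c("glandConfig", "list")
  cfg
}

#' Organ-level configuration (three clefts)
#'
#' A square bud of 16x16 cells with three clefts at (near-)equal arc spacing
#' along the boundary, otherwise identical engine settings to the
#' single-cleft configuration.
#'
#' @param ... Overrides passed to [glandConfig()].
#' @return A \code{glandConfig} with \code{nClefts = 3}.
#' @export
organConfig <- function(...) {
  glandConfig(epithRows = 16L, epithCols = 16L, anchor = "island",
              latticeWidth = 140L, latticeHeight = 140L, nClefts = 3L, ...)
}

#' The cleft width-depth rule W(D)
#'
#' Lateral target distances across the cleft follow the empirical relation
#' \eqn{W(D) = 402 / (D + 11) - 5} (pixels), measured from segmented
#' progressing clefts: width is inversely related to depth, so pairs deeper
#' within the cleft are pulled to smaller separations. Targets are clamped
#' at a floor so they never become degenerate.
#'
#' @param numerator,offset,subtrahend Constants of the relation.
#' @param floor Lower clamp for the target distance in pixels.
#' @return A named list of class \code{widthDepthRule}.
#' @export
#' @examples
#' widthDepthTarget(0)   # 402/11 - 5 = 31.5 px
#' widthDepthTarget(36)  # 402/47 - 5 ~ 3.55 px
widthDepthRule <- function(numerator = 402, offset = 11, subtrahend = 5,
                           floor = 2) {
  stopifnot(numerator > 0, offset > 0, floor >= 0)
  structure(list(numerator = numerator, offset = offset,
                 subtrahend = subtrahend, floor = floor),
            class = c("widthDepthRule", "list"))
}

#' @rdname widthDepthRule
#' @param D Cleft depth(s) in pixels.
#' @param rule A \code{widthDepthRule}.
#' @export
widthDepthTarget <- function(D, rule = widthDepthRule()) {
  pmax(rule$numerator / (D + rule$offset) - rule$subtrahend, rule$floor)
}

#' Named parameter sets
#'
#' \code{presetParams} packages the study's named conditions:
#' \describe{
#'   \item{base}{mitosis rate 1\% per 100 MCS split evenly between OCCs and
#'     IPCs; FPP lambda 10 in OCCs and cleft cells; cell-cell contact energy
#'     10 between cleft-wall cells (5 for all other cells); cleft
#'     cell-matrix contact energy 3.}
#'   \item{rock_kd}{ROCK-I knockdown mimic: lateral cleft FPP lambda lowered
#'     from 10 to 1 and mitosis rate lowered from 1\% to 0.5\%.}
#'   \item{blebbistatin}{contractility inhibition mimic: lateral cleft FPP
#'     lambda 1, proliferation unchanged.}
#'   \item{no_fpp}{all FPP links removed.}
#' }
#'
#' @param name One of \code{"base"}, \code{"rock_kd"}, \code{"blebbistatin"},
#'   \code{"no_fpp"}.
#' @param ... Overrides of individual fields (e.g. \code{ccCleft = 20}).
#' @return Named list of class \code{parameterSet} with fields
#'   \code{mitosisRate} (\% per 100 MCS), \code{occMitosisFraction} (\%),
#'   \code{fppLambdaCleft} (lateral cleft links), \code{fppLambdaCleftVertical},
#'   \code{fppLambdaOcc}, \code{ccCleft}, \code{cmCleft}, \code{noLinks}.
#' @export
#' @examples
#' presetParams("base")$ccCleft       # 10
#' presetParams("rock_kd")$fppLambdaCleft  # 1
presetParams <- function(name = c("base", "rock_kd", "blebbistatin", "no_fpp"),
                         ...) {
  name <- match.arg(name)
  p <- list(name = "base", mitosisRate = 1, occMitosisFraction = 50,
            fppLambdaCleft = 10, fppLambdaCleftVertical = 10,
            fppLambdaOcc = 10, ccCleft = 10, cmCleft = 3, noLinks = FALSE)
  p <- switch(name,
    base = p,
    rock_kd = modifyList(p, list(name = "rock_kd", fppLambdaCleft = 1,
                                 mitosisRate = 0.5)),
    blebbistatin = modifyList(p, list(name = "blebbistatin",
                                      fppLambdaCleft = 1)),
    no_fpp = modifyList(p, list(name = "no_fpp", noLinks = TRUE)))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    p <- modifyList(p, dots)
  }
  stopifnot(p$mitosisRate >= 0, p$occMitosisFraction >= 0,
            p$occMitosisFraction <= 100, p$fppLambdaCleft >= 0,
            p$ccCleft >= 0, p$cmCleft >= 0)
  class(p) <- c("parameterSet", "list")
  p
}

#' Contact-energy table for a configuration and parameter set
#'
#' Builds the symmetric 5x5 J table over \{OCC, IPC, CLEFT, MITOTIC,
#' MATRIX\}. Cleft-wall cell-cell (CC) and cleft-matrix (CM) energies come
#' from the parameter set and are assigned at the onset of simulation; all
#' remaining pairs take the configured baselines.
#'
#' @param config A [glandConfig()].
#' @param params A [presetParams()] parameter set.
#' @return 5x5 symmetric numeric matrix with type dimnames.
#' @export
contactTable <- function(config = glandConfig(), params = presetParams("base")) {
  b <- config$contactBaseline
  J <- matrix(0, 5, 5, dimnames = list(names(CELL_TYPES), names(CELL_TYPES)))
  J["OCC", "OCC"] <- b$occOcc
  J["IPC", "IPC"] <- b$ipcIpc
  J["OCC", "IPC"] <- J["IPC", "OCC"] <- b$occIpc
  J["OCC", "MATRIX"] <- J["MATRIX", "OCC"] <- b$occMatrix
  J["IPC", "MATRIX"] <- J["MATRIX", "IPC"] <- b$ipcMatrix
  J["CLEFT", "CLEFT"] <- params$ccCleft
  J["CLEFT", "MATRIX"] <- J["MATRIX", "CLEFT"] <- params$cmCleft
  J["CLEFT", "OCC"] <- J["OCC", "CLEFT"] <- b$cleftEpith
  J["CLEFT", "IPC"] <- J["IPC", "CLEFT"] <- b$cleftEpith
  for (t in c("OCC", "IPC", "CLEFT", "MITOTIC"))
    J["MITOTIC", t] <- J[t, "MITOTIC"] <- b$mitoticEpith
  J["MITOTIC", "MATRIX"] <- J["MATRIX", "MITOTIC"] <- b$mitoticMatrix
  J["MATRIX", "MATRIX"] <- b$matrixMatrix
  J
}

# ---- builders ---------------------------------------------------------------

# cleft site descriptor used internally: for each cleft, the wall cell ids
# rank by rank (top of the cleft first), the entry edge, and the pixel
# window used to measure matrix-finger penetration
newCleftDescriptor <- function(edge, wallA, wallB, window, surfaceDepthMax) {
  list(edge = edge, wallA = wallA, wallB = wallB, window = window,
       lateralIdx = integer(), depthMax = surfaceDepthMax)
}

#' Build the single-cleft gland model
#'
#' Constructs the initial lattice: a rectangular epithelium of 6x6-pixel
#' cells inside a single matrix compartment; boundary cells typed OCC (one
#' cell thick along the epithelium-matrix interface), interior cells IPC;
#' two facing columns of \code{cleftWallCells} cells typed CLEFT at the
#' horizontal centre of the top boundary; and an initiated indentation — a
#' 2-px-wide, one-cell-side-deep matrix finger between the topmost cleft
#' pair. FPP links are assigned with [assignFppLinks()] unless the parameter
#' set removes them.
#'
#' @param config A [glandConfig()].
#' @param params A [presetParams()] parameter set.
#' @param seed Integer seed for the simulation's generator.
#' @return A [GlandSim-class].
#' @export
buildSingleCleft <- function(config = glandConfig(),
                             params = presetParams("base"), seed = 1L) {
  stopifnot(inherits(config, "glandConfig"))
  cw <- floor(config$epithCols / 2)  # cleft walls at cell columns cw, cw+1
  buildGland(config, params, seed,
             clefts = list(list(edge = "top", at = cw)))
}

#' Build the organ-level model (three clefts)
#'
#' A single bud carrying three clefts at (near-)equal arc spacing along the
#' OCC boundary — one at the top centre, one on each lateral face — each
#' with its own link set and measurement window, run under the same
#' parameters as the single-cleft model.
#'
#' @inheritParams buildSingleCleft
#' @return A [GlandSim-class].
#' @export
buildOrganModel <- function(config = organConfig(),
                            params = presetParams("base"), seed = 1L) {
  stopifnot(inherits(config, "glandConfig"))
  if (config$nClefts != 3L) stop("the organ model requires nClefts = 3")
  rows <- config$epithRows; cols <- config$epithCols
  # arc positions: top centre, then perimeter/3 along each direction.
  # for the default 16x16 bud this lands the lateral clefts at cell rows
  # 13-14 (1-based), making the three pairwise boundary arcs 21/21/22
  # cell-sides against the ideal 64/3.
  perim <- 2 * (rows + cols)
  topAt <- floor(cols / 2)                          # walls at topAt, topAt+1
  arc <- perim / 3
  sideAt <- round(arc - (cols - topAt - 1))         # rows down the lateral face
  if (sideAt < 2 || sideAt + 1L > rows)
    stop("bud too small to space three clefts along the boundary")
  if (2L * config$cleftWallCells + 2L > cols)
    stop("bud too small: opposing lateral clefts would collide")
  if (arc < 3)
    stop("bud too small: cleft arc spacing under three cell-sides")
  buildGland(config, params, seed,
             clefts = list(list(edge = "top", at = topAt),
                           list(edge = "right", at = sideAt),
                           list(edge = "left", at = sideAt)))
}

# shared builder: `clefts` is a list of list(edge, at) where `at` is the
# 0-based index of the first wall line (cells `at` and `at+1` become walls)
buildGland <- function(config, params, seed, clefts) {
  s <- config$cellSide
  rows <- config$epithRows; cols <- config$epithCols
  W <- config$latticeWidth; H <- config$latticeHeight
  ew <- cols * s; eh <- rows * s
  if (identical(config$anchor, "slab")) {
    # local-patch geometry: the epithelium spans the full width and rests
    # on the bottom frame, matrix above only — the tissue is anchored, so
    # cleft progression is not fought by whole-bud rounding and drift
    if (W != ew + 2L)
      stop("slab geometry requires latticeWidth = epithelium width + 2")
    x0 <- 2L
    y0 <- H - eh
  } else {
    x0 <- floor((W - ew) / 2) + 1L
    y0 <- floor((H - eh) / 2) + 1L
  }
  if (x0 < 2L || y0 < 3L || x0 + ew > W || y0 + eh > H)
    stop("lattice too small for the configured epithelium")

  owner <- matrix(1L, W, H)            # cell 1 is the matrix compartment
  nEpith <- rows * cols
  cellId <- function(r, c) as.integer(2L + (r - 1) * cols + (c - 1))  # r, c 1-based
  type <- integer(nEpith + 1L)
  type[1] <- CELL_TYPES[["MATRIX"]]
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      id <- cellId(r, c)
      xs <- x0 + (c - 1L) * s; ys <- y0 + (r - 1L) * s
      owner[xs:(xs + s - 1L), ys:(ys + s - 1L)] <- id
      boundary <- r == 1L || r == rows || c == 1L || c == cols
      type[id] <- if (boundary) CELL_TYPES[["OCC"]] else CELL_TYPES[["IPC"]]
    }
  }

  # cleft walls and initiated notches
  wall <- config$cleftWallCells
  descriptors <- list()
  for (cl in clefts) {
    at <- cl$at
    if (cl$edge == "top") {
      wallA <- vapply(seq_len(wall), function(k) cellId(k, at), 0L)
      wallB <- vapply(seq_len(wall), function(k) cellId(k, at + 1L), 0L)
      fx <- x0 + at * s - 1L                     # interface between the walls
      owner[fx:(fx + 1L), y0:(y0 + s - 1L)] <- 1L
      win <- c(x0 + (at - 1L) * s, x0 + (at + 1L) * s - 1L, y0, y0 + eh - 1L)
      desc <- newCleftDescriptor("top", wallA, wallB, win, eh)
    } else if (cl$edge == "right") {
      wallA <- vapply(seq_len(wall), function(k) cellId(at, cols - k + 1L), 0L)
      wallB <- vapply(seq_len(wall), function(k) cellId(at + 1L, cols - k + 1L), 0L)
      fy <- y0 + at * s - 1L
      owner[(x0 + ew - s):(x0 + ew - 1L), fy:(fy + 1L)] <- 1L
      win <- c(x0, x0 + ew - 1L, y0 + (at - 1L) * s, y0 + (at + 1L) * s - 1L)
      desc <- newCleftDescriptor("right", wallA, wallB, win, ew)
    } else if (cl$edge == "left") {
      wallA <- vapply(seq_len(wall), function(k) cellId(at, k), 0L)
      wallB <- vapply(seq_len(wall), function(k) cellId(at + 1L, k), 0L)
      fy <- y0 + at * s - 1L
      owner[x0:(x0 + s - 1L), fy:(fy + 1L)] <- 1L
      win <- c(x0, x0 + ew - 1L, y0 + (at - 1L) * s, y0 + (at + 1L) * s - 1L)
      desc <- newCleftDescriptor("left", wallA, wallB, win, ew)
    } else stop("unsupported cleft edge: ", cl$edge)
    # opposing walls carry distinct internal codes so the CC parameter
    # governs only the wall-wall interface (the adhesion lost as the cleft
    # opens), not cohesion within a wall
    type[wallA] <- CELL_TYPES[["CLEFT"]]
    type[wallB] <- 6L
    descriptors[[length(descriptors) + 1L]] <- desc
  }

  targetPerim <- rep(config$occPerimTarget, nEpith + 1L)
  targetPerim[type == CELL_TYPES[["IPC"]]] <- config$ipcPerimTarget
  targetPerim[type %in% c(CELL_TYPES[["CLEFT"]], 6L)] <- config$cleftPerimTarget
  cells <- data.frame(
    type = type,
    targetArea = rep(s * s, nEpith + 1L),
    lambdaArea = rep(config$lambdaArea, nEpith + 1L),
    targetPerim = targetPerim,
    lambdaPerim = rep(config$lambdaPerim, nEpith + 1L),
    constrained = type != CELL_TYPES[["MATRIX"]])

  J <- expandContactTable(contactTable(config, params))
  # CC acts across the cleft channel; cohesion within each wall stays at
  # the epithelial baseline
  J[3, 3] <- J[6, 6] <- config$contactBaseline$cleftEpith
  J[3, 6] <- J[6, 3] <- params$ccCleft
  sim <- newLattice(owner, cells, J,
                    contactOrder = config$contactOrder,
                    temperature = config$temperature, seed = seed)
  sim@config <- config
  sim@params <- params
  sim@clefts <- descriptors
  if (!isTRUE(params$noLinks)) sim <- assignFppLinks(sim)
  sim
}

#' Assign FPP links for a built gland model
#'
#' Creates the focal-point-plasticity topology: lateral links between each
#' adjacent OCC pair along the epithelial boundary (target = one cell side,
#' lambda = \code{fppLambdaOcc}); vertical links down each cleft wall
#' between successive cleft cells (target = one cell side); and lateral
#' links across the cleft joining opposing wall cells at equal rank, with
#' target length W(D_k) from the width-depth rule at the rank's nominal
#' depth D_k = (k - 1) cell sides — decreasing with depth, so pairs deep in
#' the cleft are held closer. All cleft links use the parameter set's
#' lambdas. Replaces any existing links.
#'
#' @param sim A built [GlandSim-class].
#' @param params Parameter set; defaults to the one stored in \code{sim}.
#' @param rule Width-depth rule; defaults to the configuration's.
#' @return The simulation with links installed, invisibly.
#' @export
assignFppLinks <- function(sim, params = sim@params, rule = sim@config$rule) {
  config <- sim@config
  s <- config$cellSide
  ct <- cellTable(sim)
  meta <- list()

  # lateral OCC links along the boundary adjacency order
  rows <- config$epithRows; cols <- config$epithCols
  cellId <- function(r, c) as.integer(2L + (r - 1) * cols + (c - 1))
  ring <- c(vapply(1:cols, function(c) cellId(1L, c), 0L),
            vapply(2:rows, function(r) cellId(r, cols), 0L),
            vapply((cols - 1L):1L, function(c) cellId(rows, c), 0L),
            vapply((rows - 1L):2L, function(r) cellId(r, 1L), 0L))
  # chain members: boundary OCCs plus the mouth (rank-1) cleft cells, so the
  # cleft mouth stays tethered to the bud surface instead of drifting out
  mouth <- unlist(lapply(sim@clefts, function(d) c(d$wallA[1], d$wallB[1])))
  isOcc <- ct$type[ring] == "OCC" | ring %in% mouth
  n <- length(ring)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if ((ring[i] %in% mouth) && (ring[j] %in% mouth)) next
    if (isOcc[i] && isOcc[j])
      meta[[length(meta) + 1L]] <- data.frame(
        a = ring[i], b = ring[j], lambda = params$fppLambdaOcc, L = s,
        orientation = "lateral_occ", cleft = NA_integer_, rank = NA_integer_,
        stringsAsFactors = FALSE)
  }

  # cleft links
  clefts <- sim@clefts
  for (ci in seq_along(clefts)) {
    d <- clefts[[ci]]
    wall <- length(d$wallA)
    if (length(d$wallB) != wall || wall < 2L)
      stop("unmatched cleft wall pair in cleft ", ci)
    vertL <- config$cleftVerticalTarget %||% s
    for (k in seq_len(wall - 1L)) {
      for (w in list(d$wallA, d$wallB)) {
        meta[[length(meta) + 1L]] <- data.frame(
          a = w[k], b = w[k + 1L], lambda = params$fppLambdaCleftVertical,
          L = vertL, orientation = "vertical_cleft", cleft = ci, rank = k,
          stringsAsFactors = FALSE)
      }
    }
    lateralStart <- length(meta)
    Lk <- cleftRankTargets(s, wall, s, rule)  # initiated notch one side deep
    for (k in seq_len(wall)) {
      meta[[length(meta) + 1L]] <- data.frame(
        a = d$wallA[k], b = d$wallB[k], lambda = params$fppLambdaCleft,
        L = Lk[k], orientation = "lateral_cleft",
        cleft = ci, rank = k, stringsAsFactors = FALSE)
    }
    clefts[[ci]]$lateralIdx <- (lateralStart + 1L):length(meta)
  }

  meta <- do.call(rbind, meta)
  cpm_set_links(sim@ptr, meta$a, meta$b, meta$lambda, meta$L)
  sim@linkMeta <- meta
  sim@clefts <- clefts
  invisible(sim)
}

#' Measured matrix-finger depth of each cleft
#'
#' Fast geometric depth used by the dynamic target updates: the deepest run
#' of matrix-owned sites entering the cleft's measurement window from the
#' bud surface, in pixels. (Final reported measurements use the full
#' boundary-trace morphometrics instead; see [measureClefts()].)
#'
#' @param sim A built [GlandSim-class].
#' @return Numeric vector, one depth per cleft.
#' @export
cleftFingerDepth <- function(sim) {
  vapply(sim@clefts, function(d) {
    from <- match(d$edge, c("top", "bottom", "left", "right"))
    from <- c(1L, 2L, 3L, 4L)[from]
    cpm_finger_depth(sim@ptr, d$window[1], d$window[2], d$window[3],
                     d$window[4], from)
  }, 0)
}

#' Dynamically update lateral cleft link targets
#'
#' Recomputes each lateral cleft link's target from the current measured
#' cleft depth D via the width-depth rule: rank k (top of the cleft first,
#' n ranks in all) is taken to sit at depth
#' \eqn{d_k = \max((k-1)s,\; D - (n-k)s)} — its nominal position in the
#' wall stack, or deeper once the advancing cleft bottom has passed it —
#' and its target becomes W(d_k). Ranks the matrix finger has not yet
#' reached are held at cell contact (one cell side): the separating force
#' mimics fibronectin assembled between wall cells that have already
#' parted, so a rank is only pried open once the front reaches it. Engaged
#' ranks' targets never increase while the depth is non-decreasing (W is
#' decreasing, d_k non-decreasing in D); a rank's target steps up from the
#' closed width to the wedge profile exactly once, when the front first
#' reaches it. Attach as an MCS hook via [cleftTargetHook()].
#'
#' @param sim A built [GlandSim-class].
#' @param rule Width-depth rule; defaults to the configuration's.
#' @return The simulation, invisibly.
#' @export
updateCleftTargets <- function(sim, rule = sim@config$rule) {
  if (nrow(sim@linkMeta) == 0) return(invisible(sim))
  s <- sim@config$cellSide
  depths <- cleftFingerDepth(sim)
  meta <- sim@linkMeta
  for (ci in seq_along(sim@clefts)) {
    idx <- sim@clefts[[ci]]$lateralIdx
    if (!length(idx)) next
    L <- cleftRankTargets(depths[ci], length(idx), s, rule)
    cpm_set_link_targets(sim@ptr, idx, L)
    meta$L[idx] <- L
  }
  # slot update works because callers use the returned object or the hook
  # path, which re-reads targets from the engine via linkTable()
  sim@linkMeta <- meta
  invisible(sim)
}

# lateral target profile for n ranks when the cleft front is at depth D:
# rank k sits at d_k = max((k-1)s, D-(n-k)s); ranks beyond the front
# (one cell side ahead of D) are held at cell contact. The separating
# force mimics fibronectin assembled only between wall cells that have
# already parted.
cleftRankTargets <- function(D, n, s, rule = widthDepthRule()) {
  k <- seq_len(n)
  dk <- pmax((k - 1) * s, D - (n - k) * s)
  L <- widthDepthTarget(dk, rule)
  engaged <- (k - 1) * s <= D + s
  L[!engaged] <- pmin(L[!engaged], s)
  L
}

#' @rdname updateCleftTargets
#' @param every Cadence in MCS (default every 10 MCS).
#' @export
cleftTargetHook <- function(every = 10L) {
  list(every = as.integer(every),
       fn = function(sim, mcs) updateCleftTargets(sim))
}

#' Two-cell calibration experiment
#'
#' The reduced simulation used to choose workable FPP strengths: two
#' 6x6-pixel cells subjected to area and perimeter constraints, joined by a
#' single FPP link with target distance D, at cell-cell contact energy
#' \code{cc} and cell-matrix contact energy CM. Each (D, CM, lambda) triple
#' is run for \code{mcs} steps and scored for separation (no shared contact
#' edge) and final centroid distance.
#'
#' @param DGrid,cmGrid,lambdaGrid Value grids for the sweep.
#' @param mcs Steps per run.
#' @param cc Constant cell-cell contact energy.
#' @param replicates Replicates per triple.
#' @param seed Master seed.
#' @return Data frame (D, CM, lambda, rep, separated, finalDistance) of
#'   class \code{twoCellCalibration}.
#' @export
twoCellCalibration <- function(DGrid, cmGrid, lambdaGrid, mcs = 1000,
                               cc = 10, replicates = 1L, seed = 1L) {
  stopifnot(length(DGrid) > 0, length(cmGrid) > 0, length(lambdaGrid) > 0)
  grid <- expand.grid(D = DGrid, CM = cmGrid, lambda = lambdaGrid,
                      rep = seq_len(replicates))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sim <- buildTwoCell(D = g$D, cm = g$CM, lambda = g$lambda, cc = cc,
                        seed = deriveSeed(seed, i))
    runMCS(sim, mcs)
    own <- ownerMatrix(sim)
    ct <- cellTable(sim)
    sep <- !sharesEdge(own, 2L, 3L)
    dist <- sqrt((ct$cx[2] - ct$cx[3])^2 + (ct$cy[2] - ct$cy[3])^2)
    data.frame(D = g$D, CM = g$CM, lambda = g$lambda, rep = g$rep,
               separated = sep, finalDistance = dist)
  })
  out <- do.call(rbind, out)
  class(out) <- c("twoCellCalibration", "data.frame")
  out
}

buildTwoCell <- function(D, cm, lambda, cc = 10, seed = 1L,
                         width = 80L, height = 40L) {
  owner <- matrix(1L, width, height)
  x0 <- floor(width / 2) - 6L; y0 <- floor(height / 2) - 3L
  owner[x0:(x0 + 5L), y0:(y0 + 5L)] <- 2L
  owner[(x0 + 6L):(x0 + 11L), y0:(y0 + 5L)] <- 3L
  type <- c(CELL_TYPES[["MATRIX"]], CELL_TYPES[["CLEFT"]], CELL_TYPES[["CLEFT"]])
  J <- contactTable(params = presetParams("base", ccCleft = cc, cmCleft = cm))
  cells <- data.frame(type = type, targetArea = 36, lambdaArea = 2,
                      targetPerim = 24, lambdaPerim = 1,
                      constrained = type != CELL_TYPES[["MATRIX"]])
  sim <- newLattice(owner, cells, J, seed = seed)
  if (lambda > 0) {
    cpm_set_links(sim@ptr, 2L, 3L, lambda, D)
    sim@linkMeta <- data.frame(a = 2L, b = 3L, lambda = lambda, L = D,
                               orientation = "lateral_cleft",
                               cleft = NA_integer_, rank = NA_integer_,
                               stringsAsFactors = FALSE)
  }
  sim
}

sharesEdge <- function(owner, a, b) {
  W <- nrow(owner); H <- ncol(owner)
  h <- (owner[-W, ] == a & owner[-1, ] == b) | (owner[-W, ] == b & owner[-1, ] == a)
  v <- (owner[, -H] == a & owner[, -1] == b) | (owner[, -H] == b & owner[, -1] == a)
  any(h) || any(v)
}

#' Fit the separation frontier of the two-cell calibration
#'
#' For each (D, CM) pair, finds the smallest lambda achieving
#' majority-of-replicates separation, then fits a linear surface
#' \code{lambdaStar ~ D * CM} to the frontier.
#'
#' @param calib Result of [twoCellCalibration()].
#' @return List with \code{frontier} (data frame D, CM, lambdaStar) and
#'   \code{fit} (an \code{lm}), or frontier only if too few points to fit.
#' @export
separationFrontier <- function(calib) {
  agg <- aggregate(separated ~ D + CM + lambda, data = calib, FUN = mean)
  combos <- unique(agg[, c("D", "CM")])
  frontier <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- agg[agg$D == combos$D[i] & agg$CM == combos$CM[i], ]
    sub <- sub[order(sub$lambda), ]
    hit <- which(sub$separated > 0.5)
    data.frame(D = combos$D[i], CM = combos$CM[i],
               lambdaStar = if (length(hit)) sub$lambda[min(hit)] else NA_real_)
  }))
  ok <- !is.na(frontier$lambdaStar)
  fit <- if (sum(ok) >= 4) lm(lambdaStar ~ D * CM, data = frontier[ok, ]) else NULL
  list(frontier = frontier, fit = fit)
}

# derive a child seed (< 2^31) from a master seed and index path
deriveSeed <- function(master, ...) {
  x <- as.double(master) %% 2147483647
  for (v in c(...)) {
    x <- (x * 75 + as.double(v) * 7919 + 1) %% 2147483647
  }
  as.integer(x) + 1L
}
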