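# Mitosis: selection of mitotic cells at the configured rate and OCC/IPC
# split, growth to double size, and division every cycle.

#' Mitosis schedule
#'
#' Cells selected for mitosis are flagged MITOTIC, their target area is
#' doubled so the area constraint grows them over the following cycle, and
#' they divide at the next cycle boundary once they have reached twice
#' their original size (otherwise division is deferred one cycle).
#'
#' @param rate Mitosis rate MR in \% of epithelial cells per cycle.
#' @param occFraction Percentage of mitotic cells drawn from the OCC
#'   population (the study uses 25, 50 or 75; any value in \[0, 100\] is
#'   legal).
#' @param cycleLength Cycle length in MCS (default 100).
#' @param mode \code{"deterministic"}: select round-half-up(MR x
#'   N_epith / 100) cells each cycle; \code{"bernoulli"}: each epithelial
#'   cell is selected independently with probability MR/100 (the OCC/IPC
#'   split is then emergent, not imposed).
#' @param includeCleft Whether cleft-wall cells may divide. Excluded by
#'   default so the FPP pairing across the cleft stays well-defined.
#' @param growthSlack Extra target area (pixels^2) added on top of the
#'   doubled target while a cell grows. In a crowded tissue a cell
#'   equilibrates a few pixels below its target area, so instructing
#'   exactly 2A would leave growth perpetually just short of the division
#'   threshold; the slack offsets that crowding deficit. Division still
#'   requires the cell to actually reach twice its original size.
#' @return Named list of class \code{mitosisSchedule}.
#' @export
mitosisSchedule <- function(rate = 1, occFraction = 50, cycleLength = 100L,
                            mode = c("deterministic", "bernoulli"),
                            includeCleft = FALSE, growthSlack = 8) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, occFraction >= 0, occFraction <= 100, cycleLength >= 1,
            growthSlack >= 0)
  structure(list(rate = rate, occFraction = occFraction,
                 cycleLength = as.integer(cycleLength), mode = mode,
                 includeCleft = includeCleft, growthSlack = growthSlack),
            class = c("mitosisSchedule", "list"))
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Select cells entering mitosis
#'
#' Draws the cycle's mitotic cells from the epithelial (OCC + IPC)
#' population: round-half-up(MR x N_epith / 100) cells in total,
#' partitioned so that round-half-up(occFraction x k / 100) come from the
#' OCC compartment and the rest from IPC. Selected cells are flagged
#' MITOTIC and their target area is doubled (target perimeter raised to
#' match a doubled cell). If a compartment has fewer cells than requested,
#' all available are taken with a warning.
#'
#' @param sim A [GlandSim-class]; modified in place.
#' @param schedule A [mitosisSchedule()].
#' @return Integer vector of selected cell ids (possibly empty), invisibly
#'   annotated in \code{sim@store$pending}.
#' @export
selectMitotic <- function(sim, schedule = mitosisSchedule()) {
  ct <- cellTable(sim)
  pool <- ct$type %in% c("OCC", "IPC")
  if (schedule$includeCleft) pool <- pool | ct$type == "CLEFT"
  pool <- pool & ct$area > 0
  nEpith <- sum(pool)
  if (nEpith == 0 || schedule$rate == 0) return(invisible(integer()))

  occIds <- ct$id[pool & ct$type == "OCC"]
  ipcIds <- ct$id[pool & ct$type != "OCC"]

  if (schedule$mode == "bernoulli") {
    u <- simRunif(sim, nEpith)
    sel <- ct$id[pool][u < schedule$rate / 100]
  } else {
    k <- roundHalfUp(schedule$rate * nEpith / 100)
    if (k == 0) return(invisible(integer()))
    kOcc <- roundHalfUp(schedule$occFraction * k / 100)
    kIpc <- k - kOcc
    if (kOcc > length(occIds)) {
      warning("requested ", kOcc, " OCC mitoses but only ", length(occIds),
              " OCC cells available; taking all")
      kOcc <- length(occIds)
    }
    if (kIpc > length(ipcIds)) {
      warning("requested ", kIpc, " IPC mitoses but only ", length(ipcIds),
              " IPC cells available; taking all")
      kIpc <- length(ipcIds)
    }
    # sample without replacement through the simulation's generator
    pickOcc <- occIds[order(simRunif(sim, length(occIds)))][seq_len(kOcc)]
    pickIpc <- ipcIds[order(simRunif(sim, length(ipcIds)))][seq_len(kIpc)]
    sel <- c(pickOcc, pickIpc)
  }

  for (id in sel) {
    row <- ct[ct$id == id, ]
    flagMitotic(sim, id, row, schedule$growthSlack)
  }
  rec <- data.frame(id = sel,
                    origType = ct$type[match(sel, ct$id)],
                    origTargetArea = ct$targetArea[match(sel, ct$id)],
                    origTargetPerim = ct$targetPerim[match(sel, ct$id)],
                    stringsAsFactors = FALSE)
  sim@store$pending <- rbind(sim@store$pending, rec)
  sim@store$epithCensus <- c(sim@store$epithCensus, nEpith)
  invisible(sel)
}

flagMitotic <- function(sim, id, row, growthSlack = 8) {
  # doubled target area plus the crowding slack; target perimeter of a 1x2
  # block of the cell's original footprint (2 * (s + 2s) for square side s)
  s <- sqrt(row$targetArea)
  cpm_set_cell(sim@ptr, id, CELL_TYPES[["MITOTIC"]],
               2 * row$targetArea + growthSlack, 6 * s)
  invisible(sim)
}

#' Divide a cell
#'
#' Splits the cell's sites into two 4-connected halves of equal area (+-1
#' site; minor fragments created by the median split are reassigned to the
#' sibling) along a division axis through the centroid. Daughters are
#' re-typed by location — OCC if touching the matrix, IPC otherwise — and
#' inherit the parent's original targets. If the parent carried lateral OCC
#' links, the boundary-touching daughter inherits them.
#'
#' @param sim A [GlandSim-class]; modified in place.
#' @param id Cell id; its area must be at least twice its original size.
#' @param theta Division-axis orientation in radians; drawn uniformly from
#'   the simulation's generator when \code{NULL}.
#' @param origTargetArea,origTargetPerim Targets restored to both
#'   daughters; default to half the current target area and the OCC/IPC
#'   configured perimeters.
#' @return Named integer vector \code{c(parent, daughter)}.
#' @export
divideCell <- function(sim, id, theta = NULL,
                       origTargetArea = NULL, origTargetPerim = NULL) {
  if (is.null(theta)) theta <- simRunif(sim, 1) * pi
  ct0 <- cellTable(sim)
  row0 <- ct0[ct0$id == id, ]
  res <- cpm_divide(sim@ptr, as.integer(id), theta)
  parent <- res$parent; daughter <- res$daughter

  A <- origTargetArea %||% (row0$targetArea / 2)
  cfg <- sim@config
  perOcc <- cfg$occPerimTarget %||% (4 * sqrt(A))
  perIpc <- cfg$ipcPerimTarget %||% (4 * sqrt(A) + 4)
  touches <- c(cpm_touches_matrix(sim@ptr, parent),
               cpm_touches_matrix(sim@ptr, daughter))
  for (i in 1:2) {
    who <- c(parent, daughter)[i]
    newType <- if (touches[i]) CELL_TYPES[["OCC"]] else CELL_TYPES[["IPC"]]
    newPerim <- if (touches[i]) perOcc else perIpc
    cpm_set_cell(sim@ptr, who, newType, A, newPerim)
  }

  # lateral OCC link inheritance: the boundary-touching daughter keeps them
  meta <- sim@linkMeta
  if (nrow(meta)) {
    hasLink <- meta$orientation == "lateral_occ" &
      (meta$a == parent | meta$b == parent)
    if (any(hasLink) && !touches[1] && touches[2]) {
      meta$a[hasLink & meta$a == parent] <- daughter
      meta$b[hasLink & meta$b == parent] <- daughter
      cpm_set_links(sim@ptr, meta$a, meta$b, meta$lambda, meta$L)
      sim@linkMeta <- meta
    }
  }

  # track bookkeeping: close the parent's track, open daughters'
  gen <- sim@store$trackGen
  key <- as.character(parent)
  gen[key] <- (if (is.na(gen[key])) 0L else gen[key]) + 1L
  gen[as.character(daughter)] <- 0L
  sim@store$trackGen <- gen

  c(parent = parent, daughter = daughter)
}

#' Mitosis hook
#'
#' Returns a [runMCS()] hook implementing the growth-and-divide cycle: at
#' each cycle boundary, cells flagged in the previous cycle divide if they
#' have grown to at least twice their original size (deferred otherwise,
#' and logged), then the new cycle's mitotic cells are selected with
#' [selectMitotic()]. Division events accumulate in
#' \code{sim@store$divisions} (MCS, parent, daughter, compartment).
#'
#' @param schedule A [mitosisSchedule()].
#' @return A hook for [runMCS()].
#' @export
mitosisHook <- function(schedule = mitosisSchedule()) {
  list(every = schedule$cycleLength, fn = function(sim, mcs) {
    pending <- sim@store$pending
    if (!is.null(pending) && nrow(pending)) {
      ct <- cellTable(sim)
      keep <- logical(nrow(pending))
      for (i in seq_len(nrow(pending))) {
        id <- pending$id[i]
        area <- ct$area[match(id, ct$id)]
        if (is.na(area) || area == 0) next          # cell vanished; drop
        if (area >= 2 * pending$origTargetArea[i]) {
          pd <- divideCell(sim, id,
                           origTargetArea = pending$origTargetArea[i])
          ctAfter <- cellTable(sim)
          sim@store$divisions <- rbind(
            sim@store$divisions,
            data.frame(mcs = mcs, parent = pd[["parent"]],
                       daughter = pd[["daughter"]],
                       parentType = ctAfter$type[pd[["parent"]]],
                       daughterType = ctAfter$type[pd[["daughter"]]],
                       origType = pending$origType[i],
                       stringsAsFactors = FALSE))
        } else {
          keep[i] <- TRUE                            # growth incomplete: defer
        }
      }
      deferred <- pending[keep, , drop = FALSE]
      sim@store$deferrals <- (sim@store$deferrals %||% 0L) + sum(keep)
      sim@store$pending <- if (nrow(deferred)) deferred else NULL
    }
    selectMitotic(sim, schedule)
    invisible(NULL)
  })
}

#' Realized mitosis rate from the division log
#'
#' Recounts completed division events against the epithelial census at each
#' selection, giving the realized percentage per cycle for comparison with
#' the configured rate.
#'
#' @param sim A [GlandSim-class] after a run with [mitosisHook()].
#' @return List with \code{divisions}, \code{cycles}, \code{meanEpithelium},
#'   \code{realizedRate} (\% per cycle).
#' @export
realizedMitosisRate <- function(sim) {
  div <- sim@store$divisions
  census <- sim@store$epithCensus
  nDiv <- if (is.null(div)) 0L else nrow(div)
  cycles <- length(census)
  if (cycles == 0) return(list(divisions = nDiv, cycles = 0L,
                               meanEpithelium = NA_real_,
                               realizedRate = NA_real_))
  # cells selected in the final cycle have had no boundary at which to
  # divide yet; their census entry is not an assessable opportunity
  if (!is.null(sim@store$pending) && cycles > 1L) census <- census[-cycles]
  list(divisions = nDiv, cycles = cycles,
       meanEpithelium = mean(census),
       realizedRate = 100 * nDiv / sum(census))
}
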