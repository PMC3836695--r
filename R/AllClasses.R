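#' GlandSim: a Cellular Potts lattice simulation
#'
#' The central simulation object. The lattice state (owner grid, per-cell
#' bookkeeping, focal-point-plasticity links, Monte-Carlo counters and the
#' random-number generator) lives in compiled code behind the \code{ptr}
#' slot and is modified in place by [runMCS()] and the hooks; the R-side
#' slots carry the construction metadata (configuration, parameter set, link
#' annotations, cleft descriptors) and an environment for logs gathered
#' during a run (division events, tracks, energy log).
#'
#' Because the engine state is a reference, copies of a \code{GlandSim}
#' share it: treat the object like a connection, not a value.
#'
#' @slot ptr External pointer to the engine state.
#' @slot config Geometry/engine configuration, see [glandConfig()].
#' @slot params Named parameter set, see [presetParams()].
#' @slot linkMeta Data frame annotating every FPP link (endpoints, lambda,
#'   target length, orientation, cleft index, rank).
#' @slot clefts List of cleft descriptors (measurement window, entry edge,
#'   lateral link indices per rank) used by [updateCleftTargets()].
#' @slot conv Unit conversions, see [unitConversions()].
#' @slot store Environment holding run logs (divisions, tracks, pending
#'   mitoses, energy log).
#'
setOldClass(c("glandConfig", "list"))
setOldClass(c("parameterSet", "list"))
setOldClass(c("widthDepthRule", "list"))
setOldClass(c("unitConversions", "list"))
setOldClass(c("mitosisSchedule", "list"))

#' @export
setClass("GlandSim",
  representation(
    ptr = "externalptr",
    config = "list",
    params = "list",
    linkMeta = "data.frame",
    clefts = "list",
    conv = "list",
    store = "environment"
  )
)

setValidity("GlandSim", function(object) {
  a <- cpm_audit(object@ptr)
  msgs <- character()
  if (a$totalArea != a$latticeSites)
    msgs <- c(msgs, "owned area does not tile the lattice")
  if (a$maxAreaError > 1e-9 || a$maxPerimError > 1e-9 || a$maxCentroidError > 1e-9)
    msgs <- c(msgs, "cached bookkeeping disagrees with the owner grid")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GlandSim-class Print a compact summary of the simulation state.
#' @param object A \code{GlandSim}.
#' @export
setMethod("show", "GlandSim", function(object) {
  info <- cpm_info(object@ptr)
  ct <- cellTable(object)
  census <- table(factor(ct$type, levels = names(CELL_TYPES)))
  cat(sprintf("GlandSim: %d x %d lattice, step %d MCS, T = %g\n",
              info$width, info$height, as.integer(info$step), info$temperature))
  cat("  cells:", paste(sprintf("%s=%d", names(census), as.integer(census)),
                        collapse = ", "), "\n")
  cat(sprintf("  links: %d   clefts: %d   contact neighbourhood order: %d\n",
              info$nLinks, length(object@clefts), info$contactOrder))
  e <- energyTerms(object)
  cat(sprintf("  energy: total %.1f (contact %.1f, area %.1f, perimeter %.1f, fpp %.1f)\n",
              e[["total"]], e[["contact"]], e[["area"]], e[["perimeter"]], e[["fpp"]]))
  invisible(NULL)
})
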