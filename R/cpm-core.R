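# Engine wrappers: constructing lattice states, energy terms, Metropolis
# dynamics and the MCS loop with hooks.

#' Construct a lattice simulation from an owner grid and a cell table
#'
#' Low-level constructor used by the gland builders and the snapshot reader;
#' useful directly for small test lattices. Every lattice site must be owned
#' by a cell listed in \code{cells}; cached areas, perimeters and centroids
#' are recounted from the grid on construction.
#'
#' @param owner Integer matrix of cell ids (\code{owner[x, y]}; x horizontal,
#'   y vertical, increasing downward). Ids are row numbers of \code{cells}.
#' @param cells Data frame with one row per cell: \code{type} (label or
#'   code), \code{targetArea}, \code{lambdaArea}, \code{targetPerim},
#'   \code{lambdaPerim}, and optionally \code{constrained} (defaults to
#'   \code{TRUE} for every type except MATRIX).
#' @param J 5x5 symmetric contact-energy table over the cell types (see
#'   [cellTypes()] for row/column order), or a named list accepted by
#'   [contactTable()].
#' @param contactOrder Neighbourhood order for the contact energy, 1 to 4
#'   (4, 8, 12 or 20 neighbours). Copy attempts always use the first-order
#'   neighbourhood.
#' @param temperature Boltzmann temperature T of the Metropolis acceptance
#'   function.
#' @param seed Integer seed for the simulation's own generator; all
#'   stochasticity of a run flows through it.
#' @param conv Unit conversions, see [unitConversions()].
#' @return A [GlandSim-class] object.
#' @export
newLattice <- function(owner, cells, J, contactOrder = 2L, temperature = 10,
                       seed = 1L, conv = unitConversions()) {
  stopifnot(is.matrix(owner))
  type <- typeCode(cells$type)
  constrained <- cells$constrained %||% (type != CELL_TYPES[["MATRIX"]])
  J <- expandContactTable(as.matrix(J))
  ptr <- cpm_create(owner, type,
                    as.numeric(cells$targetArea), as.numeric(cells$lambdaArea),
                    as.numeric(cells$targetPerim), as.numeric(cells$lambdaPerim),
                    as.logical(constrained), as.matrix(J),
                    as.integer(contactOrder), temperature, as.numeric(seed))
  store <- new.env(parent = emptyenv())
  store$J <- J
  store$divisions <- NULL
  store$tracks <- list()
  store$trackGen <- integer()
  store$pending <- NULL
  store$energyLog <- NULL
  new("GlandSim", ptr = ptr, config = list(), params = list(),
      linkMeta = emptyLinkMeta(), clefts = list(), conv = conv, store = store)
}

# lift a user-facing 5x5 contact table over {OCC, IPC, CLEFT, MITOTIC,
# MATRIX} to the engine's 6x6 table: the sixth code (second cleft wall)
# mirrors CLEFT everywhere, so a one-type cleft behaves exactly as before
expandContactTable <- function(J) {
  if (nrow(J) == 6 && ncol(J) == 6) return(J)
  stopifnot(nrow(J) == 5, ncol(J) == 5)
  J6 <- matrix(0, 6, 6)
  J6[1:5, 1:5] <- J
  J6[6, 1:5] <- J[3, ]
  J6[1:5, 6] <- J[, 3]
  J6[6, 6] <- J[3, 3]
  dimnames(J6) <- list(c(names(CELL_TYPES), "CLEFT"),
                       c(names(CELL_TYPES), "CLEFT"))
  J6
}

emptyLinkMeta <- function() {
  data.frame(a = integer(), b = integer(), lambda = numeric(), L = numeric(),
             orientation = character(), cleft = integer(), rank = integer(),
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
ownerMatrix <- function(sim) cpm_owner(sim@ptr)

#' Accessors for a GlandSim
#'
#' \code{ownerMatrix} returns the integer owner grid; \code{cellTable} the
#' per-cell bookkeeping (type, area, targets, constraint strengths, centroid);
#' \code{linkTable} the current FPP links with their annotations;
#' \code{latticeDim} the grid dimensions; \code{currentStep} the MCS counter;
#' \code{acceptanceRate} the fraction of accepted copy attempts so far.
#'
#' @param sim A [GlandSim-class].
#' @name accessors
#' @export
cellTable <- function(sim) {
  cl <- cpm_cells(sim@ptr)
  data.frame(id = cl$id, type = typeLabel(cl$type), area = cl$area,
             targetArea = cl$targetArea, lambdaArea = cl$lambdaArea,
             perimeter = cl$perimeter, targetPerim = cl$targetPerim,
             lambdaPerim = cl$lambdaPerim, cx = cl$cx, cy = cl$cy,
             constrained = cl$constrained, stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
linkTable <- function(sim) {
  lk <- cpm_links(sim@ptr)
  n <- length(lk$a)
  meta <- sim@linkMeta
  if (nrow(meta) == n) {
    out <- meta
    out$lambda <- lk$lambda
    out$L <- lk$L
    out
  } else {
    data.frame(a = lk$a, b = lk$b, lambda = lk$lambda, L = lk$L,
               orientation = rep(NA_character_, n), cleft = rep(NA_integer_, n),
               rank = rep(NA_integer_, n), stringsAsFactors = FALSE)
  }
}

#' @rdname accessors
#' @export
latticeDim <- function(sim) {
  info <- cpm_info(sim@ptr)
  c(width = info$width, height = info$height)
}

#' @rdname accessors
#' @export
currentStep <- function(sim) as.integer(cpm_info(sim@ptr)$step)

#' @rdname accessors
#' @export
acceptanceRate <- function(sim) {
  info <- cpm_info(sim@ptr)
  if (info$attempts == 0) return(NA_real_)
  info$accepts / info$attempts
}

#' Hamiltonian energy terms
#'
#' \code{energyTerms} evaluates the four terms of the model Hamiltonian —
#' contact energy over neighbouring heterocell site pairs, the quadratic
#' area and perimeter constraints, and the focal-point-plasticity (FPP)
#' spring term over linked cell centroids — and their sum.
#' \code{totalEnergy} and \code{contactEnergy} are shorthands;
#' \code{areaEnergy} and \code{perimeterEnergy} return the per-cell
#' contributions \eqn{\lambda (a - A)^2} and \eqn{\lambda (p - P)^2}
#' (zero for the unconstrained matrix compartment); \code{fppEnergy}
#' returns the per-link contributions \eqn{\lambda (l - L)^2} where l is
#' the Euclidean centroid distance.
#'
#' @param sim A [GlandSim-class].
#' @return \code{energyTerms}: named numeric vector with elements
#'   \code{contact}, \code{area}, \code{perimeter}, \code{fpp}, \code{total}.
#' @export
energyTerms <- function(sim) {
  e <- cpm_energy(sim@ptr)
  c(contact = e$contact, area = e$area, perimeter = e$perimeter,
    fpp = e$fpp, total = e$total)
}

#' @rdname energyTerms
#' @export
totalEnergy <- function(sim) energyTerms(sim)[["total"]]

#' @rdname energyTerms
#' @export
contactEnergy <- function(sim) energyTerms(sim)[["contact"]]

#' @rdname energyTerms
#' @export
areaEnergy <- function(sim) {
  ct <- cellTable(sim)
  ifelse(ct$constrained, ct$lambdaArea * (ct$area - ct$targetArea)^2, 0)
}

#' @rdname energyTerms
#' @export
perimeterEnergy <- function(sim) {
  ct <- cellTable(sim)
  ifelse(ct$constrained, ct$lambdaPerim * (ct$perimeter - ct$targetPerim)^2, 0)
}

#' @rdname energyTerms
#' @export
fppEnergy <- function(sim) {
  lk <- linkTable(sim)
  if (nrow(lk) == 0) return(numeric(0))
  ct <- cellTable(sim)
  l <- sqrt((ct$cx[lk$a] - ct$cx[lk$b])^2 + (ct$cy[lk$a] - ct$cy[lk$b])^2)
  lk$lambda * (l - lk$L)^2
}

#' Incremental energy change of one copy attempt
#'
#' Exact change in [totalEnergy()] if the owner of \code{target} were
#' overwritten by the owner of \code{source}, computed locally from the
#' touched contact pairs, the two cells' area/perimeter deltas and the
#' affected link lengths. The two sites must have different owners.
#'
#' @param sim A [GlandSim-class].
#' @param source,target Sites as \code{c(x, y)} (1-based).
#' @return The energy change as a single number.
#' @export
deltaEnergy <- function(sim, source, target) {
  cpm_delta_energy(sim@ptr, as.integer(source[1]), as.integer(source[2]),
                   as.integer(target[1]), as.integer(target[2]))
}

#' Force-apply a single site copy (bookkeeping included)
#'
#' Applies the copy \code{source -> target} unconditionally, updating the
#' cached areas, perimeters and centroid sums incrementally. Intended for
#' validating [deltaEnergy()] against a full recomputation.
#'
#' @inheritParams deltaEnergy
#' @return The simulation, invisibly.
#' @export
applyCopy <- function(sim, source, target) {
  cpm_apply_copy(sim@ptr, as.integer(source[1]), as.integer(source[2]),
                 as.integer(target[1]), as.integer(target[2]))
  invisible(sim)
}

#' Metropolis acceptance trials at a fixed energy change
#'
#' Draws \code{n} accept/reject decisions for a hypothetical copy attempt
#' with energy change \code{dH} at the simulation temperature, consuming the
#' simulation's generator: acceptance probability is 1 for \code{dH < 0} and
#' \eqn{e^{-\Delta H / T}} otherwise (ties \code{dH = 0} are accepted).
#'
#' @param sim A [GlandSim-class].
#' @param dH Energy change.
#' @param n Number of trials.
#' @return Number of accepted trials.
#' @export
metropolisTrials <- function(sim, dH, n) {
  cpm_accept_trials(sim@ptr, dH, as.integer(n))
}

#' Uniform draws from the simulation's generator
#'
#' All randomness of a run (copy attempts, mitotic selection, division axes)
#' flows through this single generator, so a run is reproducible from the
#' initial state and seed alone.
#'
#' @param sim A [GlandSim-class].
#' @param n Number of draws.
#' @return Numeric vector of uniforms in \[0, 1).
#' @export
simRunif <- function(sim, n) cpm_runif(sim@ptr, as.integer(n))

#' Run Monte-Carlo steps
#'
#' Performs \code{nSteps} Monte-Carlo steps (MCS), each consisting of exactly
#' width x height copy attempts: a random site and a random first-order
#' neighbour are drawn; if the neighbour has a different owner (and is not
#' part of the frozen one-site boundary frame) the neighbour's owner is
#' overwritten by the site's owner with probability
#' \eqn{\min(1, e^{-\Delta H / T})}. Rejected same-owner draws still consume
#' an attempt. Hooks fire between steps at their configured cadence.
#'
#' @param sim A [GlandSim-class]; modified in place.
#' @param nSteps Number of MCS to run (>= 0).
#' @param hooks Named list of hooks, each \code{list(every = <MCS cadence>,
#'   fn = function(sim, mcs) ...)}. A hook error aborts the run with the MCS
#'   index in the message.
#' @return The simulation, invisibly.
#' @export
runMCS <- function(sim, nSteps, hooks = list()) {
  nSteps <- as.integer(nSteps)
  stopifnot(nSteps >= 0)
  if (nSteps == 0L) return(invisible(sim))
  for (h in hooks) {
    if (!is.function(h$fn) || !is.numeric(h$every) || h$every < 1)
      stop("each hook must be list(every = <positive integer>, fn = <function>)")
  }
  cur <- currentStep(sim)
  end <- cur + nSteps
  while (cur < end) {
    nxt <- end
    for (h in hooks) {
      due <- (cur %/% h$every + 1L) * as.integer(h$every)
      if (due < nxt) nxt <- due
    }
    cpm_run(sim@ptr, nxt - cur)
    cur <- nxt
    for (i in seq_along(hooks)) {
      h <- hooks[[i]]
      if (cur %% h$every == 0L) {
        nm <- names(hooks)[i] %||% as.character(i)
        tryCatch(h$fn(sim, cur), error = function(e) {
          stop(sprintf("hook '%s' failed at MCS %d: %s", nm, cur,
                       conditionMessage(e)), call. = FALSE)
        })
      }
    }
  }
  invisible(sim)
}

#' Audit cached bookkeeping against the owner grid
#'
#' Recounts every cell's area, perimeter and centroid from the owner grid
#' and reports the largest discrepancy from the incrementally maintained
#' values, plus the total owned area (which must tile the lattice exactly).
#'
#' @param sim A [GlandSim-class].
#' @return Named list with \code{maxAreaError}, \code{maxPerimError},
#'   \code{maxCentroidError}, \code{totalArea}, \code{latticeSites}.
#' @export
auditState <- function(sim) cpm_audit(sim@ptr)

#' Connected-component count per cell
#'
#' Cells should remain 4-connected at the working temperature; this monitor
#' reports the number of connected components per cell so the chosen T can
#' be verified not to fragment cells.
#'
#' @param sim A [GlandSim-class].
#' @return Integer vector, one component count per cell.
#' @export
fragmentCounts <- function(sim) cpm_fragments(sim@ptr)

#' Energy-log hook
#'
#' Returns a hook recording per-MCS total and per-term energies and the
#' cumulative acceptance rate into \code{sim@store$energyLog}.
#'
#' @param every Cadence in MCS.
#' @return A hook suitable for [runMCS()].
#' @export
energyLogHook <- function(every = 10L) {
  list(every = as.integer(every), fn = function(sim, mcs) {
    e <- energyTerms(sim)
    row <- data.frame(mcs = mcs, total = e[["total"]], contact = e[["contact"]],
                      area = e[["area"]], perimeter = e[["perimeter"]],
                      fpp = e[["fpp"]], acceptanceRate = acceptanceRate(sim))
    sim@store$energyLog <- rbind(sim@store$energyLog, row)
  })
}
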