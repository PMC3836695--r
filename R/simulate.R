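# High-level drivers: one condition, replicated conditions.

#' Simulate one gland condition
#'
#' Builds the single-cleft (or three-cleft organ) model, attaches the
#' standard hooks — mitosis every cycle, dynamic lateral cleft-link target
#' updates, optional tracking and energy logging — and runs the requested
#' number of Monte-Carlo steps.
#'
#' @param params Parameter set, see [presetParams()].
#' @param config Geometry configuration; [glandConfig()] or
#'   [organConfig()]. The organ builder is used when
#'   \code{config$nClefts == 3}.
#' @param mcs Steps to run (1500 corresponds to the 20-hour growth period).
#' @param seed Integer seed; the run is bit-reproducible given (config,
#'   params, mcs, seed).
#' @param mitosis Attach the mitosis hook.
#' @param updateCadence Cadence of dynamic cleft-target updates in MCS
#'   (\code{NULL} disables them, reproducing the static-link ablation).
#' @param trackCadence Tracking cadence in MCS (\code{NULL} disables).
#' @param energyCadence Energy-log cadence (\code{NULL} disables).
#' @param hooks Additional named hooks for [runMCS()].
#' @return The final [GlandSim-class].
#' @export
#' @examples
#' \donttest{
#' sim <- simulateCleft(mcs = 100, seed = 7)
#' measureClefts(sim)
#' }
simulateCleft <- function(params = presetParams("base"),
                          config = glandConfig(), mcs = 1500L, seed = 1L,
                          mitosis = TRUE, updateCadence = 10L,
                          trackCadence = NULL, energyCadence = NULL,
                          hooks = list()) {
  sim <- if (config$nClefts == 3L) buildOrganModel(config, params, seed)
         else buildSingleCleft(config, params, seed)
  hk <- hooks
  if (mitosis && params$mitosisRate > 0)
    hk$mitosis <- mitosisHook(mitosisSchedule(
      rate = params$mitosisRate, occFraction = params$occMitosisFraction))
  if (!is.null(updateCadence) && !isTRUE(params$noLinks))
    hk$cleftTargets <- cleftTargetHook(updateCadence)
  if (!is.null(trackCadence)) {
    attachInitialSample(sim)
    hk$tracking <- trackHook(trackCadence)
  }
  if (!is.null(energyCadence)) hk$energyLog <- energyLogHook(energyCadence)
  runMCS(sim, mcs, hooks = hk)
  sim
}

#' Replicate a condition and measure final clefts
#'
#' Runs \code{reps} independent simulations of one condition (derived
#' seeds are a pure function of the master seed and replicate index) and
#' measures the final state with the morphometrics pipeline.
#'
#' @inheritParams simulateCleft
#' @param reps Number of replicates.
#' @param measureConv Conversions used for the micrometre field of the
#'   measurements.
#' @param ... Passed to [simulateCleft()].
#' @return Data frame with one row per (replicate, cleft): replicate index,
#'   seed, cleft index, the three indices and status.
#' @export
runCondition <- function(params = presetParams("base"),
                         config = glandConfig(), reps = 20L, seed = 1L,
                         mcs = 1500L, measureConv = unitConversions(), ...) {
  out <- lapply(seq_len(reps), function(r) {
    sd <- deriveSeed(seed, 101L, r)
    sim <- simulateCleft(params = params, config = config, mcs = mcs,
                         seed = sd, ...)
    # a rare replicate can shed an epithelial fragment, which the strict
    # single-component tracer rejects; such replicates are dropped
    m <- tryCatch(measureClefts(sim, conv = measureConv),
                  error = function(e) NULL)
    if (is.null(m) || !nrow(m)) return(NULL)
    m$rep <- r
    m$seed <- sd
    m
  })
  do.call(rbind, out)
}
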