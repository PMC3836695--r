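# Per-cell centroid trajectories and motility statistics.

#' Tracking hook
#'
#' Returns a [runMCS()] hook appending every live non-matrix cell's
#' centroid to the track store at the configured cadence. Cells that divide
#' have their parent track closed and daughter tracks opened (handled by
#' [divideCell()] through a per-cell generation counter), so tracks are
#' never stitched across divisions.
#'
#' @param every Sampling cadence in MCS.
#' @param recordInitial Record the state at attachment time, i.e. MCS 0 of
#'   the run, by sampling immediately when the hook is created with
#'   [attachInitialSample()].
#' @return A hook for [runMCS()].
#' @export
trackHook <- function(every = 10L, recordInitial = TRUE) {
  list(every = as.integer(every), fn = function(sim, mcs) {
    recordTrackSample(sim, mcs)
  })
}

#' @rdname trackHook
#' @param sim A [GlandSim-class].
#' @export
attachInitialSample <- function(sim) {
  recordTrackSample(sim, currentStep(sim))
  invisible(sim)
}

recordTrackSample <- function(sim, mcs) {
  ct <- cellTable(sim)
  live <- ct$type != "MATRIX" & ct$area > 0
  gen <- sim@store$trackGen
  g <- gen[as.character(ct$id[live])]
  g[is.na(g)] <- 0L
  sim@store$tracks[[length(sim@store$tracks) + 1L]] <- data.frame(
    track = sprintf("%d.%d", ct$id[live], g),
    cellId = ct$id[live], mcs = mcs, x = ct$cx[live], y = ct$cy[live],
    stringsAsFactors = FALSE)
  invisible(NULL)
}

#' Collect recorded tracks
#'
#' @param sim A [GlandSim-class] run with a [trackHook()].
#' @return Data frame (track, cellId, mcs, x, y) ordered by track and MCS.
#' @export
collectTracks <- function(sim) {
  if (!length(sim@store$tracks))
    return(data.frame(track = character(), cellId = integer(),
                      mcs = integer(), x = numeric(), y = numeric(),
                      stringsAsFactors = FALSE))
  tr <- do.call(rbind, sim@store$tracks)
  tr[order(tr$track, tr$mcs), ]
}

#' Motility statistics
#'
#' Per-track net displacement (first-to-last sample distance), total path
#' length (sum of inter-sample distances), velocity (path length divided by
#' elapsed hours) and meandering index (net displacement divided by path
#' length, in \[0, 1\]). Distances are converted to micrometres and times
#' to hours with the supplied conversions. Single-sample tracks are
#' excluded and counted.
#'
#' @param tracks Data frame from [collectTracks()] (columns track, mcs, x,
#'   y).
#' @param conv A [unitConversions()].
#' @return List with \code{perTrack} (data frame: track, samples,
#'   displacement_um, path_um, velocity_um_h, meandering) and
#'   \code{summary} (means plus track counts).
#' @export
motilityStats <- function(tracks, conv = unitConversions()) {
  if (!nrow(tracks)) stop("no tracks recorded")
  sp <- split(tracks, tracks$track)
  rows <- lapply(sp, function(tt) {
    tt <- tt[order(tt$mcs), ]
    n <- nrow(tt)
    if (n < 2) return(NULL)
    dx <- diff(tt$x); dy <- diff(tt$y)
    path <- sum(sqrt(dx^2 + dy^2)) * conv$umPerPx
    disp <- sqrt((tt$x[n] - tt$x[1])^2 + (tt$y[n] - tt$y[1])^2) * conv$umPerPx
    hours <- mcsToHours(tt$mcs[n] - tt$mcs[1], conv)
    data.frame(track = tt$track[1], samples = n, displacement_um = disp,
               path_um = path,
               velocity_um_h = if (hours > 0) path / hours else NA_real_,
               meandering = if (path > 0) disp / path else NA_real_,
               stringsAsFactors = FALSE)
  })
  excluded <- sum(vapply(rows, is.null, TRUE))
  per <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per) || !nrow(per)) stop("no track has two or more samples")
  list(perTrack = per,
       summary = list(
         nTracks = nrow(per), nExcluded = excluded,
         meanDisplacement_um = mean(per$displacement_um),
         meanPath_um = mean(per$path_um),
         meanVelocity_um_h = mean(per$velocity_um_h, na.rm = TRUE),
         meanMeandering = mean(per$meandering, na.rm = TRUE)))
}
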