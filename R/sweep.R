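# Parameter sweep, cleft-class assignment and SVM feature-removal
# importance.

#' Sweep grid over the four varied parameters
#'
#' Default levels follow the hypothesis-driven individual analyses: four
#' mitosis rates, six contractility (FPP lambda) values, five cleft
#' cell-cell contact energies and five cleft-matrix contact energies —
#' 600 combinations in all.
#'
#' @param mr Mitosis-rate levels (\% per 100 MCS).
#' @param fpp Lateral cleft FPP lambda levels.
#' @param cc Cleft-wall cell-cell contact-energy levels.
#' @param cm Cleft-matrix contact-energy levels.
#' @param replicates Replicates per combination.
#' @return List of class \code{sweepGrid}.
#' @export
sweepGrid <- function(mr = c(0.5, 1, 2, 3), fpp = c(1, 5, 10, 15, 20, 30),
                      cc = c(1, 5, 10, 15, 20), cm = 1:5,
                      replicates = 40L) {
  structure(list(mr = mr, fpp = fpp, cc = cc, cm = cm,
                 replicates = as.integer(replicates)),
            class = c("sweepGrid", "list"))
}

#' Cleft depth classes
#'
#' Classifies a final cleft depth into the four classes derived from the
#' ex-vivo depth distribution (minimum, first and third quartiles): failed
#' (< 17.8 um), non-progressive (17.8 to 30.5 um), progressive (30.5 to
#' 40.7 um) and super-progressive (> 40.7 um). Boundaries follow the
#' lower-closed reading of the stated ranges: 17.8 is non-progressive,
#' 30.5 is progressive, and the progressive interval is closed above, so
#' 40.7 is progressive.
#'
#' @param depthUm Depth(s) in micrometres (finite, >= 0).
#' @param bounds The three class boundaries.
#' @return Factor with levels \code{failed}, \code{non_progressive},
#'   \code{progressive}, \code{super_progressive}.
#' @export
#' @examples
#' classifyDepth(c(10, 35, 45))
classifyDepth <- function(depthUm, bounds = c(17.8, 30.5, 40.7)) {
  stopifnot(all(is.finite(depthUm)), all(depthUm >= 0))
  lv <- cleftClassLevels()
  out <- ifelse(depthUm < bounds[1], lv[1],
         ifelse(depthUm < bounds[2], lv[2],
         ifelse(depthUm <= bounds[3], lv[3], lv[4])))
  factor(out, levels = lv)
}

#' @rdname classifyDepth
#' @export
cleftClassLevels <- function() {
  c("failed", "non_progressive", "progressive", "super_progressive")
}

#' Overall class of one parameter combination
#'
#' A combination is assigned the majority class over its replicate
#' outcomes; in the case of a tie among the most frequent classes, the
#' median replicate depth is classified instead.
#'
#' @param depthsUm Replicate final depths (um) for one combination.
#' @param bounds Class boundaries.
#' @return Single-level factor, the combination's class.
#' @export
assignComboClass <- function(depthsUm, bounds = c(17.8, 30.5, 40.7)) {
  stopifnot(length(depthsUm) >= 1)
  cls <- classifyDepth(depthsUm, bounds)
  tab <- table(cls)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) factor(top, levels = cleftClassLevels())
  else classifyDepth(median(depthsUm), bounds)
}

#' Run the parameter sweep
#'
#' For every (combination, replicate) builds the single-cleft model with
#' the combination's overrides, runs \code{mcs} steps, and measures the
#' final cleft depth. Seeds are a pure function of (master seed,
#' combination, replicate), so the sweep is resumable and bit-reproducible
#' cell by cell; a failed simulation is recorded in its row, not fatal.
#'
#' @param grid A [sweepGrid()].
#' @param config Geometry configuration.
#' @param baseParams Parameter set supplying all non-swept fields.
#' @param mcs Steps per run.
#' @param seed Master seed.
#' @param umPerPx Micrometres per pixel applied to the measured depth
#'   before classification. The class boundaries were derived in a regime
#'   where model pixels and micrometres were used interchangeably, so the
#'   default is 1.
#' @param executor A \code{lapply}-like function over row indices (swap in
#'   \code{parallel::mclapply} for a multiprocess sweep).
#' @return Data frame of class \code{sweepOutcomes}: mr, fpp, cc, cm, rep,
#'   seed, depth_um, class, error.
#' @export
runSweep <- function(grid = sweepGrid(), config = glandConfig(),
                     baseParams = presetParams("base"), mcs = 1500L,
                     seed = 1L, umPerPx = 1, executor = lapply) {
  combos <- expand.grid(mr = grid$mr, fpp = grid$fpp, cc = grid$cc,
                        cm = grid$cm, KEEP.OUT.ATTRS = FALSE)
  tasks <- expand.grid(combo = seq_len(nrow(combos)),
                       rep = seq_len(grid$replicates), KEEP.OUT.ATTRS = FALSE)
  conv <- unitConversions(umPerPx = umPerPx)
  rows <- executor(seq_len(nrow(tasks)), function(i) {
    ci <- tasks$combo[i]; r <- tasks$rep[i]
    cb <- combos[ci, ]
    sd <- deriveSeed(seed, ci, r)
    p <- modifyList(baseParams,
                    list(mitosisRate = cb$mr, fppLambdaCleft = cb$fpp,
                         ccCleft = cb$cc, cmCleft = cb$cm))
    res <- tryCatch({
      sim <- simulateCleft(params = p, config = config, mcs = mcs, seed = sd)
      m <- measureClefts(sim, conv = conv)
      d <- if (nrow(m)) m$depth_um[1] else 0
      list(depth = d, err = NA_character_)
    }, error = function(e) list(depth = NA_real_,
                                err = conditionMessage(e)))
    data.frame(mr = cb$mr, fpp = cb$fpp, cc = cb$cc, cm = cb$cm, rep = r,
               seed = sd, depth_um = res$depth,
               error = res$err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$depth_um)
  out$class <- factor(NA, levels = cleftClassLevels())
  out$class[ok] <- classifyDepth(out$depth_um[ok])
  class(out) <- c("sweepOutcomes", "data.frame")
  out
}

#' Per-combination classes from sweep outcomes
#'
#' @param outcomes A \code{sweepOutcomes} data frame from [runSweep()].
#' @return Data frame with one row per combination: mr, fpp, cc, cm,
#'   replicate count and the majority/median class.
#' @export
comboClasses <- function(outcomes) {
  ok <- !is.na(outcomes$depth_um)
  sp <- split(outcomes[ok, ], interaction(outcomes$mr, outcomes$fpp,
                                          outcomes$cc, outcomes$cm,
                                          drop = TRUE)[ok])
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(mr = g$mr[1], fpp = g$fpp[1], cc = g$cc[1], cm = g$cm[1],
               n = nrow(g),
               class = assignComboClass(g$depth_um),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

featureSubsets <- function(features = c("mr", "fpp", "cc", "cm")) {
  subsets <- list()
  for (k in rev(seq_along(features)))
    subsets <- c(subsets, combn(features, k, simplify = FALSE))
  subsets
}

#' SVM feature-removal importance
#'
#' Ranks the four parameters by how much a radial-basis-kernel SVM's
#' cross-validated accuracy drops when the parameter is removed: balanced
#' samples of \code{nPerClass} combinations per class are drawn, and for
#' each of the 15 non-empty feature subsets a 10-fold cross-validation is
#' performed on standardized features, reporting mean and standard
#' deviation of training and testing accuracy and the drop in testing
#' accuracy against the full set. A larger drop means a more important
#' feature.
#'
#' @param combos Data frame from [comboClasses()] (columns mr, fpp, cc, cm,
#'   class).
#' @param nPerClass Combinations drawn per class; classes with fewer are
#'   sampled with replacement (flagged in the result's
#'   \code{sampledWithReplacement} attribute).
#' @param folds Cross-validation folds.
#' @param cost SVM cost parameter.
#' @param gamma RBF kernel width; default 1 / n_features on the
#'   standardized features.
#' @param seed Sampling/fold seed.
#' @return Data frame with one row per subset: features, nFeatures,
#'   trainAcc, trainSd, testAcc, testSd, drop (percentage points vs the
#'   full set).
#' @export
featureImportance <- function(combos, nPerClass = 50L, folds = 10L,
                              cost = 1, gamma = NULL, seed = 1L) {
  stopifnot(all(c("mr", "fpp", "cc", "cm", "class") %in% names(combos)))
  cls <- factor(combos$class, levels = cleftClassLevels())
  present <- levels(droplevels(cls))
  if (length(present) < 2L)
    stop("degenerate sample: fewer than two classes present")
  set.seed(seed)
  withRepl <- character()
  idx <- unlist(lapply(present, function(lv) {
    pool <- which(cls == lv)
    if (length(pool) >= nPerClass) sample(pool, nPerClass)
    else { withRepl <<- c(withRepl, lv)
           sample(pool, nPerClass, replace = TRUE) }
  }))
  dat <- combos[idx, c("mr", "fpp", "cc", "cm")]
  y <- droplevels(cls[idx])
  X <- scale(as.matrix(dat))
  fold <- sample(rep_len(seq_len(folds), nrow(X)))

  subsets <- featureSubsets()
  res <- lapply(subsets, function(fs) {
    Xi <- X[, fs, drop = FALSE]
    g <- gamma %||% (1 / ncol(Xi))
    accTr <- accTe <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- e1071::svm(Xi[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = cost, gamma = g, scale = FALSE)
      accTr[f] <- mean(predict(fit, Xi[tr, , drop = FALSE]) == y[tr])
      accTe[f] <- mean(predict(fit, Xi[!tr, , drop = FALSE]) == y[!tr])
    }
    data.frame(features = paste(toupper(fs), collapse = "+"),
               nFeatures = length(fs),
               trainAcc = 100 * mean(accTr), trainSd = 100 * sd(accTr),
               testAcc = 100 * mean(accTe), testSd = 100 * sd(accTe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$drop <- out$testAcc[1] - out$testAcc
  attr(out, "sampledWithReplacement") <- withRepl
  out
}

#' Parameter-value distributions within the progressive class
#'
#' Value counts of each swept parameter restricted to progressive-class
#' combinations; parameters essential to progression concentrate around a
#' peak with low variance.
#'
#' @param combos Data frame from [comboClasses()].
#' @return List with per-parameter \code{counts} tables, \code{peak}
#'   values and \code{variance}s, plus \code{n} progressive combinations.
#' @export
progressiveValueDistribution <- function(combos) {
  prog <- combos[combos$class == "progressive", ]
  if (!nrow(prog)) stop("progressive class is empty")
  pars <- c("mr", "fpp", "cc", "cm")
  counts <- lapply(pars, function(p) table(prog[[p]]))
  names(counts) <- pars
  list(n = nrow(prog), counts = counts,
       peak = vapply(counts, function(tb)
         as.numeric(names(tb)[which.max(tb)]), 0),
       variance = vapply(pars, function(p) var(prog[[p]]), 0))
}
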