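# Replicated study conditions used by the acceptance suite. Runs are
# cached per session so several test blocks can share one batch.

.condCache <- new.env(parent = emptyenv())

conditionParams <- function(name) {
  switch(name,
    base = presetParams("base"),
    organ = presetParams("base"),
    lambda1 = presetParams("base", fppLambdaCleft = 1),
    lambda30 = presetParams("base", fppLambdaCleft = 30),
    no_fpp = presetParams("no_fpp"),
    cc1 = presetParams("base", ccCleft = 1),
    cc5 = presetParams("base", ccCleft = 5),
    cc15 = presetParams("base", ccCleft = 15),
    cc20 = presetParams("base", ccCleft = 20),
    cm5 = presetParams("base", cmCleft = 5),
    rock_kd = presetParams("rock_kd"),
    stop("unknown condition ", name))
}

conditionMeasurements <- function(name, reps = 20L, seed = 1L) {
  key <- paste(name, reps, seed, sep = "/")
  if (!is.null(.condCache[[key]])) return(.condCache[[key]])
  cfg <- if (name == "organ") organConfig() else glandConfig()
  m <- runCondition(params = conditionParams(name), config = cfg,
                    reps = reps, seed = seed, mcs = 1500L)
  .condCache[[key]] <- m
  m
}

conditionDepth <- function(name, reps = 20L, seed = 1L) {
  mean(conditionMeasurements(name, reps, seed)$depth_px)
}

conditionSpanning <- function(name, reps = 20L, seed = 1L) {
  mean(conditionMeasurements(name, reps, seed)$spanning_deg)
}

# printed-number tolerance: 15% relative or one standard error of the
# replicate mean, whichever is larger
printedTol <- function(printed, values) {
  max(0.15 * abs(printed), sd(values) / sqrt(length(values)))
}
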