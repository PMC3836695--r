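# Engine: Hamiltonian terms, incremental delta-H, Metropolis dynamics,
# bookkeeping integrity.

makeUniformCells <- function(n, type = 1L, A = 36, lamA = 2, P = 24, lamP = 1) {
  data.frame(type = c(5L, rep(type, n - 1)), targetArea = A, lambdaArea = lamA,
             targetPerim = P, lambdaPerim = lamP,
             constrained = c(FALSE, rep(TRUE, n - 1)))
}

flatJ <- function(v = 5) matrix(v, 5, 5)

test_that("contact energy matches hand-countable configurations", {
  # lattice entirely owned by one (matrix) cell: the Kronecker delta
  # removes every same-cell pair
  own <- matrix(1L, 6, 6)
  cells <- data.frame(type = 5L, targetArea = 0, lambdaArea = 0,
                      targetPerim = 0, lambdaPerim = 0, constrained = FALSE)
  sim <- newLattice(own, cells, flatJ(7), contactOrder = 1)
  expect_identical(contactEnergy(sim), 0)

  # two adjacent single-site cells, first-order neighbourhood: one pair
  own <- matrix(c(1L, 2L), 2, 1)
  cells <- data.frame(type = c(1L, 2L), targetArea = 1, lambdaArea = 0,
                      targetPerim = 4, lambdaPerim = 0, constrained = TRUE)
  J <- flatJ(0); J[1, 2] <- J[2, 1] <- 5
  sim <- newLattice(own, cells, J, contactOrder = 1)
  expect_equal(contactEnergy(sim), 5)

  # linearity in J: doubling every entry doubles the energy
  rl <- buildRandomSim(seed = 3, withLinks = FALSE)
  e1 <- contactEnergy(rl$sim)
  sim2 <- newLattice(rl$own, rl$cells, 2 * rl$J, contactOrder = 2)
  expect_equal(contactEnergy(sim2), 2 * e1)
})

test_that("area and perimeter energies follow the quadratic constraint", {
  own <- matrix(1L, 12, 12)
  own[4:9, 4:9] <- 2L                      # 6x6 block: area 36, perimeter 24
  cells <- makeUniformCells(2, A = 36, lamA = 2, P = 24, lamP = 1)
  sim <- newLattice(own, cells, flatJ(), contactOrder = 1)
  expect_equal(areaEnergy(sim), c(0, 0))       # a = A = 36; matrix always 0
  expect_equal(perimeterEnergy(sim), c(0, 0))  # p = P = 24 for a 6x6 block
  ct <- cellTable(sim)
  expect_equal(ct$perimeter[2], 24)

  # a = 38, A = 36, lambda = 2 -> 8
  own <- matrix(1L, 12, 12); own[4:9, 4:9] <- 2L; own[4:5, 10] <- 2L  # 38
  sim <- newLattice(own, cells, flatJ(), contactOrder = 1)
  expect_equal(areaEnergy(sim)[2], 2 * (38 - 36)^2)

  # the matrix compartment contributes zero regardless of its size
  expect_equal(areaEnergy(sim)[1], 0)
  expect_equal(perimeterEnergy(sim)[1], 0)

  # perimeter example: p = 26, P = 24, lambda = 1 -> 4
  own <- matrix(1L, 12, 12); own[4:9, 4:9] <- 2L; own[6, 10] <- 2L  # p = 26
  sim <- newLattice(own, cells, flatJ(), contactOrder = 1)
  expect_equal(cellTable(sim)$perimeter[2], 26)
  expect_equal(perimeterEnergy(sim)[2], 1 * (26 - 24)^2)
})

test_that("FPP energy sums lambda (l - L)^2 over links", {
  own <- matrix(1L, 20, 10)
  own[3:8, 3:8] <- 2L
  own[11:16, 3:8] <- 3L                     # centroid distance 8
  cells <- makeUniformCells(3)
  sim <- newLattice(own, cells, flatJ(), contactOrder = 1)
  expect_length(fppEnergy(sim), 0)          # empty link set -> no terms
  cleftsim:::cpm_set_links(sim@ptr, 2L, 3L, 10, 6)
  expect_equal(sum(fppEnergy(sim)), 10 * (8 - 6)^2)   # 40
  cleftsim:::cpm_set_links(sim@ptr, 2L, 3L, 10, 8)
  expect_equal(sum(fppEnergy(sim)), 0)      # l = L contributes 0
})

test_that("total energy equals the sum of terms and an independent oracle", {
  for (seed in 1:5) {
    rl <- buildRandomSim(W = 20, H = 20, nCells = 6, seed = seed)
    e <- energyTerms(rl$sim)
    expect_equal(e[["total"]],
                 e[["contact"]] + e[["area"]] + e[["perimeter"]] + e[["fpp"]])
    ref <- refEnergy(rl$own, rl$cells, rl$J, contactOrder = 2,
                     links = rl$links)
    expect_equal(e[["contact"]], ref$contact)
    expect_equal(e[["area"]], ref$area)
    expect_equal(e[["perimeter"]], ref$perimeter)
    expect_equal(e[["fpp"]], ref$fpp, tolerance = 1e-12)
    expect_equal(e[["total"]], ref$total, tolerance = 1e-12)
  }

  # all lambdas zero and all J zero -> zero total energy
  own <- randomLattice(16, 16, 4, seed = 9)
  cells <- randomCells(own, seed = 9)
  cells$lambdaArea <- 0; cells$lambdaPerim <- 0
  sim <- newLattice(own, cells, flatJ(0))
  expect_equal(totalEnergy(sim), 0)
})

test_that("incremental delta-H equals apply-and-recompute on random attempts", {
  # a lighter sweep than the acceptance-suite oracle (which runs 1000)
  nChecked <- 0
  for (seed in 1:40) {
    rl <- buildRandomSim(W = sample(15:30, 1), H = sample(15:30, 1),
                         nCells = sample(3:7, 1), seed = seed)
    own <- ownerMatrix(rl$sim)
    W <- nrow(own); H <- ncol(own)
    set.seed(seed * 7)
    tries <- 0
    while (nChecked < 300 && tries < 200) {
      tries <- tries + 1
      x <- sample(2:(W - 1), 1); y <- sample(2:(H - 1), 1)
      dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
      d <- dirs[sample(4, 1), ]
      tx <- x + d[1]; ty <- y + d[2]
      if (own[x, y] == own[tx, ty]) next
      if (sum(own == own[tx, ty]) <= 1) next   # would annihilate a cell
      dH <- deltaEnergy(rl$sim, c(x, y), c(tx, ty))
      before <- refEnergy(own, rl$cells, rl$J, 2, rl$links)$total
      applyCopy(rl$sim, c(x, y), c(tx, ty))
      own <- ownerMatrix(rl$sim)
      after <- refEnergy(own, rl$cells, rl$J, 2, rl$links)$total
      expect_equal(dH, after - before, tolerance = 1e-6)
      nChecked <- nChecked + 1
    }
    if (nChecked >= 300) break
  }
  expect_gte(nChecked, 300)
})

test_that("delta-H respects mirror symmetry and matrix-copy area penalty", {
  # mirror-symmetric two-cell configuration: the mirrored attempt has the
  # same energy change
  own <- matrix(1L, 20, 12)
  own[5:10, 4:9] <- 2L
  own[11:16, 4:9] <- 3L
  cells <- makeUniformCells(3, type = 1L)
  sim <- newLattice(own, cells, flatJ(5))
  d1 <- deltaEnergy(sim, c(10, 6), c(11, 6))   # cell 2 invades cell 3
  d2 <- deltaEnergy(sim, c(11, 6), c(10, 6))   # mirrored attempt
  expect_equal(d1, d2)

  # copying matrix into a cell at its target area strictly raises the
  # area term: (a - 1 - A)^2 > 0 when a = A
  own2 <- matrix(1L, 14, 14); own2[5:10, 5:10] <- 2L
  cells2 <- makeUniformCells(2)
  cells2$lambdaPerim <- 0
  sim2 <- newLattice(own2, cells2, flatJ(0))
  dH <- deltaEnergy(sim2, c(4, 7), c(5, 7))    # matrix overwrites edge site
  expect_gt(dH, 0)

  # same-owner pair short-circuits with an error signal
  expect_error(deltaEnergy(sim2, c(2, 2), c(2, 3)), "share an owner")
})

test_that("Metropolis acceptance follows min(1, exp(-dH/T))", {
  own <- matrix(1L, 10, 10)
  cells <- data.frame(type = 5L, targetArea = 0, lambdaArea = 0,
                      targetPerim = 0, lambdaPerim = 0, constrained = FALSE)
  sim <- newLattice(own, cells, flatJ(), temperature = 10, seed = 99)

  expect_equal(metropolisTrials(sim, -1, 500), 500)   # dH < 0: always
  expect_equal(metropolisTrials(sim, 0, 500), 500)    # ties accepted (e^0)

  # dH = 20, T = 10: frequency within 3 binomial SE of exp(-2)
  n <- 1e5
  p <- exp(-2)
  acc <- metropolisTrials(sim, 20, n)
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))

  # binned acceptance law across a dH grid at 1e4 samples each
  for (dH in c(2, 5, 10, 30)) {
    p <- exp(-dH / 10)
    acc <- metropolisTrials(sim, dH, 1e4)
    expect_lt(abs(acc / 1e4 - p), 3 * sqrt(p * (1 - p) / 1e4) + 1e-12)
  }
})

test_that("the MCS loop is deterministic, counted, and conserving", {
  build <- function(seed) {
    own <- matrix(1L, 30, 30)
    own[6:11, 6:11] <- 2L; own[14:19, 6:11] <- 3L; own[6:11, 14:19] <- 4L
    cells <- makeUniformCells(4)
    J <- flatJ(5); J[, 5] <- J[5, ] <- 8; J[5, 5] <- 0
    newLattice(own, cells, J, temperature = 10, seed = seed)
  }
  simA <- build(123); simB <- build(123)

  expect_identical(ownerMatrix(runMCS(simA, 0)), ownerMatrix(simB))  # n = 0

  runMCS(simA, 50); runMCS(simB, 50)
  expect_identical(ownerMatrix(simA), ownerMatrix(simB))  # fixed seed

  info <- cleftsim:::cpm_info(simA@ptr)
  expect_equal(info$attempts, 50 * 30 * 30)               # N attempts per MCS
  expect_equal(currentStep(simA), 50)

  a <- auditState(simA)
  expect_equal(a$totalArea, a$latticeSites)               # area conservation
  expect_lt(a$maxAreaError + a$maxPerimError + a$maxCentroidError, 1e-9)

  # a different seed diverges (the generator is doing something)
  simC <- build(124); runMCS(simC, 50)
  expect_false(identical(ownerMatrix(simA), ownerMatrix(simC)))
})

test_that("cached bookkeeping matches a full recount after long segments", {
  sim <- buildSingleCleft(seed = 5)
  runMCS(sim, 100, hooks = list(targets = cleftTargetHook(10)))
  a <- auditState(sim)
  expect_lt(max(a$maxAreaError, a$maxPerimError, a$maxCentroidError), 1e-6)
  runMCS(sim, 100)
  a <- auditState(sim)
  expect_lt(max(a$maxAreaError, a$maxPerimError, a$maxCentroidError), 1e-6)
  expect_true(validObject(sim))
})

test_that("neutral energies leave type composition without systematic drift", {
  # all lambdas 0 and uniform J: no cell type is energetically preferred
  # over another, so the OCC share of epithelial area performs an unbiased
  # random walk (overall interface tension still coarsens blobs, so total
  # epithelial area is allowed to change) and the cell count is invariant
  drifts <- sapply(1:4, function(seed) {
    own <- randomLattice(36, 36, 8, seed = seed)
    cells <- randomCells(own, seed)
    cells$type[cells$type != 5L] <- rep_len(c(1L, 2L),
                                            sum(cells$type != 5L))
    cells$lambdaArea <- 0; cells$lambdaPerim <- 0
    sim <- newLattice(own, cells, flatJ(5), temperature = 10, seed = seed)
    ct0 <- cellTable(sim)
    share0 <- sum(ct0$area[ct0$type == "OCC"]) /
      sum(ct0$area[ct0$type != "MATRIX"])
    runMCS(sim, 500)
    ct1 <- cellTable(sim)
    expect_equal(nrow(ct1), nrow(ct0))
    share1 <- sum(ct1$area[ct1$type == "OCC"]) /
      sum(ct1$area[ct1$type != "MATRIX"])
    share1 - share0
  })
  expect_gt(t.test(drifts, mu = 0)$p.value, 0.01)
})

test_that("all stochasticity flows through the injected generator", {
  set.seed(111)
  simA <- buildSingleCleft(seed = 77)
  set.seed(999)                    # perturbing R's global RNG is irrelevant
  simB <- buildSingleCleft(seed = 77)
  runMCS(simA, 30); runMCS(simB, 30)
  expect_identical(ownerMatrix(simA), ownerMatrix(simB))
})

test_that("the fragmentation monitor reports connected components", {
  own <- matrix(1L, 12, 12)
  own[3:4, 3:4] <- 2L
  own[9:10, 9:10] <- 2L          # deliberately split cell
  cells <- makeUniformCells(2)
  sim <- newLattice(own, cells, flatJ())
  expect_equal(fragmentCounts(sim)[2], 2L)
})
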