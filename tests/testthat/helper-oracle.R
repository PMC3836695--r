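# Independent R reference implementation of the model Hamiltonian, used as
# the oracle against the compiled engine. Deliberately built from padded
# matrix shifts and tabulation — it shares no code path with the engine.

offsetsForOrder <- function(order) {
  DX <- c(1, -1, 0, 0, 1, 1, -1, -1, 2, -2, 0, 0, 2, 2, -2, -2, 1, 1, -1, -1)
  DY <- c(0, 0, 1, -1, 1, -1, 1, -1, 0, 0, 2, -2, 1, -1, 1, -1, 2, -2, 2, -2)
  n <- c(4, 8, 12, 20)[order]
  cbind(DX[seq_len(n)], DY[seq_len(n)])
}

refEnergy <- function(own, cells, J, contactOrder = 2, links = NULL) {
  W <- nrow(own); H <- ncol(own)
  nc <- nrow(cells)
  type <- as.integer(cells$type)
  J <- as.matrix(J)
  if (nrow(J) == 5) J <- rbind(cbind(J, J[, 3]), c(J[3, ], J[3, 3]))

  pad <- matrix(0L, W + 4, H + 4)
  pad[3:(W + 2), 3:(H + 2)] <- own
  center <- own

  # contact: each unordered neighbouring pair once (offsets with
  # dy > 0 or (dy == 0 and dx > 0))
  off <- offsetsForOrder(contactOrder)
  keep <- off[, 2] > 0 | (off[, 2] == 0 & off[, 1] > 0)
  contact <- 0
  for (k in which(keep)) {
    nb <- pad[3:(W + 2) + off[k, 1], 3:(H + 2) + off[k, 2]]
    sel <- nb != 0L & nb != center
    if (any(sel)) contact <- contact + sum(J[cbind(type[center[sel]],
                                                   type[nb[sel]])])
  }

  a <- tabulate(own, nc)
  per <- numeric(nc)
  for (k in 1:4) {
    nb <- pad[3:(W + 2) + offsetsForOrder(1)[k, 1],
              3:(H + 2) + offsetsForOrder(1)[k, 2]]
    sel <- nb != center
    per <- per + tabulate(center[sel], nc)
  }
  owners <- sort(unique(as.vector(own)))
  sxFull <- syFull <- numeric(nc)
  sxFull[owners] <- rowsum(as.numeric(row(own)), as.vector(own))[, 1]
  syFull[owners] <- rowsum(as.numeric(col(own)), as.vector(own))[, 1]

  constrained <- cells$constrained %||% (type != 5L)
  areaE <- sum(ifelse(constrained, cells$lambdaArea * (a - cells$targetArea)^2, 0))
  perE <- sum(ifelse(constrained, cells$lambdaPerim * (per - cells$targetPerim)^2, 0))

  fppE <- 0
  if (!is.null(links) && nrow(links)) {
    cx <- sxFull / a; cy <- syFull / a
    l <- sqrt((cx[links$a] - cx[links$b])^2 + (cy[links$a] - cy[links$b])^2)
    fppE <- sum(links$lambda * (l - links$L)^2)
  }
  list(contact = contact, area = areaE, perimeter = perE, fpp = fppE,
       total = contact + areaE + perE + fppE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random blob lattice: nCells compact seeds grown by nearest-seed
# assignment inside a matrix bath (cell 1)
randomLattice <- function(W, H, nCells, seed = 1) {
  set.seed(seed)
  px <- runif(nCells, W * 0.25, W * 0.75)
  py <- runif(nCells, H * 0.25, H * 0.75)
  own <- matrix(1L, W, H)
  for (x in 2:(W - 1)) for (y in 2:(H - 1)) {
    d2 <- (px - x)^2 + (py - y)^2
    j <- which.min(d2)
    if (d2[j] < (min(W, H) / 5)^2) own[x, y] <- j + 1L
  }
  own
}

randomCells <- function(own, seed = 1) {
  set.seed(seed + 1)
  nc <- max(own)
  type <- c(5L, sample(c(1L, 2L, 3L), nc - 1, replace = TRUE))
  data.frame(type = type,
             targetArea = round(runif(nc, 20, 60)),
             lambdaArea = round(runif(nc, 0.5, 3), 2),
             targetPerim = round(runif(nc, 16, 40)),
             lambdaPerim = round(runif(nc, 0.5, 2), 2),
             constrained = type != 5L)
}

randomJ <- function(seed = 1, lo = 0, hi = 12) {
  set.seed(seed + 2)
  J <- matrix(runif(25, lo, hi), 5, 5)
  (J + t(J)) / 2
}

randomLinks <- function(own, seed = 1, n = 3) {
  nc <- max(own)
  live <- which(tabulate(own, nc) > 0)
  live <- setdiff(live, 1L)
  if (length(live) < 2) return(NULL)
  set.seed(seed + 3)
  a <- b <- integer(n)
  for (i in seq_len(n)) {
    ab <- sample(live, 2)
    a[i] <- ab[1]; b[i] <- ab[2]
  }
  data.frame(a = a, b = b, lambda = runif(n, 0, 15), L = runif(n, 2, 20))
}

buildRandomSim <- function(W = 24, H = 20, nCells = 5, seed = 1,
                           contactOrder = 2, withLinks = TRUE) {
  own <- randomLattice(W, H, nCells, seed)
  cells <- randomCells(own, seed)
  J <- randomJ(seed)
  sim <- newLattice(own, cells, J, contactOrder = contactOrder,
                    temperature = 10, seed = seed)
  links <- if (withLinks) randomLinks(own, seed) else NULL
  if (!is.null(links)) {
    cleftsim:::cpm_set_links(sim@ptr, links$a, links$b, links$lambda, links$L)
  }
  list(sim = sim, own = own, cells = cells, J = J, links = links)
}
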