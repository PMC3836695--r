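# Persistence: plain-text snapshot format (owner grid + cell table + links
# + engine settings), PNG rendering with the fixed type colour map, CSV
# emitters and the experiment manifest.

SNAPSHOT_MAGIC <- "cleftsim-snapshot 1"

#' Write / read a lattice snapshot
#'
#' The snapshot is a plain-text, lossless serialization of the simulation:
#' engine header, owner grid (one line of site owners per lattice row),
#' cell table, link table, contact-energy table and a JSON metadata block
#' (configuration, parameter set, cleft descriptors, conversions). Reading
#' reconstructs a [GlandSim-class] whose owner grid, bookkeeping, links and
#' energies are identical; the engine generator is reseeded with
#' \code{seed}.
#'
#' @param sim A [GlandSim-class].
#' @param path File path.
#' @return \code{writeSnapshot}: the path, invisibly.
#' @export
writeSnapshot <- function(sim, path) {
  info <- cpm_info(sim@ptr)
  own <- ownerMatrix(sim)
  ct <- cpm_cells(sim@ptr)
  lk <- linkTable(sim)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SNAPSHOT_MAGIC, con)
  writeLines(sprintf("width %d height %d step %d temperature %.17g contactOrder %d",
                     info$width, info$height, as.integer(info$step),
                     info$temperature, info$contactOrder), con)
  writeLines("owner", con)
  for (y in seq_len(info$height))
    writeLines(paste(own[, y], collapse = " "), con)
  writeLines(sprintf("cells %d", length(ct$id)), con)
  writeLines("id type targetArea lambdaArea targetPerim lambdaPerim constrained", con)
  for (i in seq_along(ct$id))
    writeLines(sprintf("%d %d %.17g %.17g %.17g %.17g %d", ct$id[i],
                       ct$type[i], ct$targetArea[i], ct$lambdaArea[i],
                       ct$targetPerim[i], ct$lambdaPerim[i],
                       as.integer(ct$constrained[i])), con)
  writeLines(sprintf("links %d", nrow(lk)), con)
  if (nrow(lk))
    writeLines(sprintf("%d %d %.17g %.17g %s %s %s", lk$a, lk$b, lk$lambda,
                       lk$L, lk$orientation, as.character(lk$cleft),
                       as.character(lk$rank)), con)
  writeLines("contact", con)
  J <- contactTableOf(sim)
  for (i in seq_len(nrow(J))) writeLines(paste(sprintf("%.17g", J[i, ]), collapse = " "), con)
  writeLines("meta", con)
  meta <- list(config = unclass(sim@config), params = unclass(sim@params),
               clefts = sim@clefts, conv = unclass(sim@conv))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"), con)
  invisible(path)
}

# the engine does not expose J back; keep a copy on first construction
contactTableOf <- function(sim) {
  J <- sim@store$J
  if (is.null(J)) stop("contact table unavailable; was the state built by this package?")
  J
}

#' @rdname writeSnapshot
#' @param seed Seed for the reconstructed simulation's generator.
#' @export
readSnapshot <- function(path, seed = 1L) {
  lines <- readLines(path)
  if (lines[1] != SNAPSHOT_MAGIC) stop("not a cleftsim snapshot: ", path)
  hdr <- strsplit(lines[2], " ")[[1]]
  getv <- function(key) hdr[which(hdr == key) + 1]
  W <- as.integer(getv("width")); H <- as.integer(getv("height"))
  step <- as.integer(getv("step"))
  Tval <- as.numeric(getv("temperature"))
  corder <- as.integer(getv("contactOrder"))
  stopifnot(lines[3] == "owner")
  own <- matrix(0L, W, H)
  for (y in seq_len(H))
    own[, y] <- as.integer(strsplit(lines[3 + y], " ")[[1]])
  pos <- 4 + H
  nc <- as.integer(sub("cells ", "", lines[pos])); pos <- pos + 2
  cellRows <- do.call(rbind, lapply(lines[pos:(pos + nc - 1)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  pos <- pos + nc
  nl <- as.integer(sub("links ", "", lines[pos])); pos <- pos + 1
  linkMeta <- emptyLinkMeta()
  if (nl > 0) {
    parts <- strsplit(lines[pos:(pos + nl - 1)], " ")
    linkMeta <- data.frame(
      a = vapply(parts, function(p) as.integer(p[1]), 0L),
      b = vapply(parts, function(p) as.integer(p[2]), 0L),
      lambda = vapply(parts, function(p) as.numeric(p[3]), 0),
      L = vapply(parts, function(p) as.numeric(p[4]), 0),
      orientation = vapply(parts, function(p) p[5], ""),
      cleft = vapply(parts, function(p) suppressWarnings(as.integer(p[6])), 0L),
      rank = vapply(parts, function(p) suppressWarnings(as.integer(p[7])), 0L),
      stringsAsFactors = FALSE)
    pos <- pos + nl
  }
  stopifnot(lines[pos] == "contact")
  J <- do.call(rbind, lapply(lines[(pos + 1):(pos + 6)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  dimnames(J) <- list(c(names(CELL_TYPES), "CLEFT"), c(names(CELL_TYPES), "CLEFT"))
  pos <- pos + 7
  stopifnot(lines[pos] == "meta")
  meta <- jsonlite::fromJSON(paste(lines[(pos + 1):length(lines)], collapse = "\n"),
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)

  cells <- data.frame(type = as.integer(cellRows[, 2]),
                      targetArea = cellRows[, 3], lambdaArea = cellRows[, 4],
                      targetPerim = cellRows[, 5], lambdaPerim = cellRows[, 6],
                      constrained = cellRows[, 7] == 1)
  conv <- do.call(unitConversions, meta$conv %||% list())
  sim <- newLattice(own, cells, J, contactOrder = corder, temperature = Tval,
                    seed = seed, conv = conv)
  cpm_set_step(sim@ptr, step)
  if (nrow(linkMeta)) {
    cpm_set_links(sim@ptr, linkMeta$a, linkMeta$b, linkMeta$lambda, linkMeta$L)
    sim@linkMeta <- linkMeta
  }
  if (length(meta$config)) {
    cfg <- meta$config
    cfg$rule <- do.call(widthDepthRule, cfg$rule %||% list())
    class(cfg) <- c("glandConfig", "list")
    sim@config <- cfg
  }
  if (length(meta$params)) {
    p <- meta$params
    class(p) <- c("parameterSet", "list")
    sim@params <- p
  }
  if (length(meta$clefts)) {
    sim@clefts <- lapply(meta$clefts, function(d) {
      d$wallA <- as.integer(unlist(d$wallA))
      d$wallB <- as.integer(unlist(d$wallB))
      d$window <- as.integer(unlist(d$window))
      d$lateralIdx <- as.integer(unlist(d$lateralIdx))
      d
    })
  }
  sim@store$J <- J
  sim
}

# the two cleft walls get the two blue tones
TYPE_COLORS <- c(OCC = "#006400", IPC = "#90EE90", CLEFT = "#4682B4",
                 MITOTIC = "#FFFF00", MATRIX = "#00FFFF", CLEFT2 = "#27408B")

#' Render a simulation state to PNG
#'
#' Fixed type colour map: OCC dark green, IPC light green, cleft-wall cells
#' blue, mitotic cells yellow, matrix cyan; optional white FPP-link overlay
#' between linked cell centroids.
#'
#' @param sim A [GlandSim-class].
#' @param path Output PNG path.
#' @param scale Integer pixel magnification.
#' @param drawLinks Overlay FPP links as white lines.
#' @return The path, invisibly.
#' @export
renderSnapshot <- function(sim, path, scale = 1L, drawLinks = FALSE) {
  own <- ownerMatrix(sim)
  ct <- cpm_cells(sim@ptr)
  typeOf <- ct$type[own]                 # site type codes
  cols <- col2rgb(TYPE_COLORS) / 255
  W <- nrow(own); H <- ncol(own)
  img <- array(0, dim = c(H, W, 3))      # writePNG expects row = y
  for (ch in 1:3)
    img[, , ch] <- t(matrix(cols[ch, typeOf], W, H))
  if (drawLinks) {
    lk <- linkTable(sim)
    for (i in seq_len(nrow(lk))) {
      a <- lk$a[i]; b <- lk$b[i]
      ax <- ct$cx[a]; ay <- ct$cy[a]
      bx <- ct$cx[b]; by <- ct$cy[b]
      npt <- max(2L, ceiling(2 * sqrt((ax - bx)^2 + (ay - by)^2)))
      xs <- round(seq(ax, bx, length.out = npt))
      ys <- round(seq(ay, by, length.out = npt))
      keep <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
      for (ch in 1:3) img[cbind(ys[keep], xs[keep], ch)] <- 1
    }
  }
  if (scale > 1L) {
    img <- img[rep(seq_len(H), each = scale), rep(seq_len(W), each = scale), ,
               drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Write measurement / track / sweep tables as CSV
#'
#' Thin wrappers fixing the column layout of the package's CSV artifacts.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeMetricsCsv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Experiment manifest
#'
#' Records what produced a set of artifacts: configuration snapshot,
#' package version, master seed, derived per-run seeds (a pure function of
#' master seed, combination and replicate), output paths and a timestamp.
#'
#' @param path Output path (JSON).
#' @param config Configuration list.
#' @param params Parameter set.
#' @param masterSeed Master seed.
#' @param derivedSeeds Named vector/list of derived seeds.
#' @param outputs Character vector of artifact paths.
#' @return The path, invisibly.
#' @export
writeManifest <- function(path, config = NULL, params = NULL,
                          masterSeed = NULL, derivedSeeds = NULL,
                          outputs = character()) {
  manifest <- list(
    package = "cleftsim",
    version = as.character(utils::packageVersion("cleftsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    masterSeed = masterSeed,
    derivedSeeds = derivedSeeds,
    config = if (!is.null(config)) unclass(config) else NULL,
    params = if (!is.null(params)) unclass(params) else NULL,
    outputs = outputs)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}
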