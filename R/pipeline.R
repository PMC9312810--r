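#' @include AllClasses.R AllGenerics.R utils.R io.R rmsd-space.R landscape.R
#' @include contacts.R phi.R synthetic-protein.R
NULL

#' Assemble and validate a pipeline configuration
#'
#' Central configuration record for \code{\link{runPipeline}}. Every default
#' matches the corresponding function default, so the configuration and the
#' module-level documentation cannot drift. Inputs may be file paths
#' (validated to exist here, before any compute) or in-memory objects: a
#' \linkS4class{Trajectory} plus native coordinates, or an
#' \code{\link{unfoldingScenario}} for a fully synthetic run.
#'
#' @param trajectory path to a trajectory file, a \linkS4class{Trajectory},
#'   or NULL when \code{scenario} is given.
#' @param native path to a native PDB, or a \code{\link{makeToyNative}}-style
#'   list; generated from \code{nResidues} when NULL and \code{scenario}
#'   drives a synthetic run.
#' @param topology path to a topology PDB for trajectory files (default:
#'   the native structure's topology).
#' @param scenario optional \code{\link{unfoldingScenario}} generating the
#'   trajectory at run time.
#' @param nResidues toy-protein size for synthetic runs (default 30).
#' @param outputDir directory for artifacts.
#' @param temperature analysis temperature, K (default 498).
#' @param stride 2DRMSD stride (default NULL: automatic cap).
#' @param k embedding dimension (default 3).
#' @param nBins landscape bins per axis (default 50).
#' @param exitC,exitM,exitWindowFrac exit-detection threshold multiplier,
#'   persistence and reference-window fraction (defaults 5, 10, 0.05).
#' @param cutoff,minSeqSep contact definition (defaults 8 A, 3).
#' @param qLo,expansionMin,qFloor,qHi molten-globule thresholds
#'   (defaults 0.6, 1.05, 0.3, 0.8).
#' @param gapTolerance demarcation merge gap, frames (default 10).
#' @param stabilityThreshold intermediate-well stability threshold,
#'   kcal/mol (default NULL: RT).
#' @param prefactor TST prefactor, 1/s (default 1e6).
#' @param phiEnsembles optional \code{\link{makePhiEnsembles}} result for a
#'   phi-value stage.
#' @param frameInterval ns per frame for file-based trajectories (default 1).
#' @param seed integer base seed.
#' @return a validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(trajectory = NULL, native = NULL, topology = NULL,
                           scenario = NULL, nResidues = 30L,
                           outputDir = tempfile("unfoldscape"),
                           temperature = 498, stride = NULL, k = 3L,
                           nBins = 50L, exitC = 5, exitM = 10L,
                           exitWindowFrac = 0.05, cutoff = 8,
                           minSeqSep = 3L, qLo = 0.6, expansionMin = 1.05,
                           qFloor = 0.3, qHi = 0.8, gapTolerance = 10L,
                           stabilityThreshold = NULL, prefactor = 1e6,
                           phiEnsembles = NULL, frameInterval = 1,
                           seed = 1L) {
  if (is.null(trajectory) && is.null(scenario)) {
    stop("either a trajectory or a synthetic scenario must be supplied")
  }
  for (p in list(trajectory, native, topology)) {
    if (is.character(p) && !file.exists(p)) {
      stop("input file not found: ", p)
    }
  }
  if (!is.null(scenario)) stopifnot(inherits(scenario, "UnfoldingScenario"))
  temperature <- .assertPositive(temperature, "temperature")
  structure(
    list(
      trajectory = trajectory, native = native, topology = topology,
      scenario = scenario, nResidues = .assertCount(nResidues, "nResidues",
                                                    min = 20L),
      outputDir = outputDir, temperature = temperature, stride = stride,
      k = .assertCount(k, "k"), nBins = .assertCount(nBins, "nBins", 2L),
      exitC = .assertPositive(exitC, "exitC"),
      exitM = .assertCount(exitM, "exitM"),
      exitWindowFrac = .assertPositive(exitWindowFrac, "exitWindowFrac"),
      cutoff = .assertPositive(cutoff, "cutoff"),
      minSeqSep = .assertCount(minSeqSep, "minSeqSep"),
      qLo = qLo, expansionMin = expansionMin, qFloor = qFloor, qHi = qHi,
      gapTolerance = .assertCount(gapTolerance, "gapTolerance", 0L),
      stabilityThreshold = stabilityThreshold,
      prefactor = .assertPositive(prefactor, "prefactor"),
      phiEnsembles = phiEnsembles,
      frameInterval = .assertPositive(frameInterval, "frameInterval"),
      seed = as.integer(seed)
    ),
    class = "PipelineConfig"
  )
}

# Resolve the configured inputs into (Trajectory, native coords, topology).
.resolveInputs <- function(config) {
  native <- config$native
  if (is.character(native)) {
    s <- loadStructure(native)
    native <- list(topology = s$topology, coords = s$coords)
  }
  if (!is.null(config$scenario)) {
    if (is.null(native)) {
      native <- makeToyNative(config$nResidues)
    }
    traj <- makeUnfoldingTrajectory(native, config$scenario)
  } else if (is(config$trajectory, "Trajectory")) {
    traj <- config$trajectory
  } else {
    topo <- if (!is.null(config$topology)) {
      loadStructure(config$topology)$topology
    } else if (!is.null(native)) {
      native$topology
    } else {
      stop("a topology or native structure is required for file input")
    }
    traj <- loadTrajectory(config$trajectory, topo,
                           frameInterval = config$frameInterval)
  }
  if (is.null(native)) stop("a native reference structure is required")
  list(traj = traj, native = native)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full unfolding-analysis pipeline
#'
#' Executes, in order: 2DRMSD matrix, classical-MDS embedding, step
#' vectors, native-exit detection, landscape grid with statistical free
#' energy, reaction path with barrier/channel/intermediate statistics and
#' TST rate, contact and Rg series, secondary-structure timeline,
#' molten-globule classification, transition-ensemble demarcation, and
#' (when ensembles are configured) a phi-value table. Every artifact is
#' written under \code{outputDir} as CSV/JSON and recorded in a
#' machine-readable run manifest together with all parameters and the
#' physical constants used; outputs are byte-identical across reruns with
#' the same configuration and seed. A stage failure aborts with the stage
#' name; artifacts of completed stages persist.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return (invisibly) a list with every intermediate object and the
#'   manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outputDir, f)
  artifacts <- character(0)
  inp <- .stage("input", .resolveInputs(config))
  traj <- inp$traj
  native <- inp$native

  D <- .stage("2drmsd", pairwiseRmsdMatrix(traj, stride = config$stride))
  utils::write.csv(as.matrix(D), out("distance_matrix.csv"),
                   row.names = FALSE)
  artifacts <- c(artifacts, "distance_matrix.csv")

  emb <- .stage("mds", classicalMDS(D, k = config$k))
  sv <- .stage("stepvectors",
               stepVectors(emb, frameInterval(traj) * D@strideUsed))
  writeTable(
    data.frame(
      frame = D@frameIndices,
      time = (D@frameIndices - 1) * frameInterval(traj),
      coords(emb),
      stepNorm = c(NA, stepNorms(sv))
    ),
    out("embedding.csv")
  )
  artifacts <- c(artifacts, "embedding.csv")

  exit <- .stage("exit", {
    win <- seq_len(max(10L, floor(config$exitWindowFrac * nFrames(emb))))
    detectNativeExit(sv, referenceWindow = win, c = config$exitC,
                     m = config$exitM)
  })

  grid <- .stage("landscape", {
    freeEnergy(populationGrid(sv, nBins = config$nBins),
               temperature = config$temperature)
  })
  writeTable(
    data.frame(
      binX = rep(seq_len(nrow(gridCounts(grid))), ncol(gridCounts(grid))),
      binY = rep(seq_len(ncol(gridCounts(grid))),
                 each = nrow(gridCounts(grid))),
      count = as.vector(gridCounts(grid)),
      deltaF = as.vector(deltaF(grid))
    ),
    out("landscape_grid.csv")
  )
  artifacts <- c(artifacts, "landscape_grid.csv")

  path <- .stage("path", {
    barrierStats(extractReactionPath(grid),
                 stabilityThreshold = config$stabilityThreshold)
  })
  rate <- tstRate(deltaFActivation(path), config$temperature,
                  config$prefactor)
  writeTable(
    data.frame(
      arcLength = arcLength(path),
      deltaF = pathProfile(path)
    ),
    out("reaction_path.csv")
  )
  artifacts <- c(artifacts, "reaction_path.csv")

  cs <- .stage("contacts", {
    contactTimeseries(traj, native, cutoff = config$cutoff,
                      minSeqSep = config$minSeqSep)
  })
  ss <- .stage("secondary_structure",
               secondaryStructureTimeline(traj, native))
  classes <- .stage("classify", {
    classifyMoltenGlobule(cs, ss, qLo = config$qLo,
                          expansionMin = config$expansionMin,
                          qFloor = config$qFloor, qHi = config$qHi)
  })
  writeTable(
    data.frame(
      frame = seq_len(nFrames(cs)),
      q = nativeContactCount(cs),
      total = totalContactCount(cs),
      qFraction = qFraction(cs),
      rg = rgSeries(cs),
      ssPersistence = persistenceByFrame(ss),
      class = as.character(classes)
    ),
    out("contact_series.csv")
  )
  artifacts <- c(artifacts, "contact_series.csv")

  ensemble <- .stage("demarcate", {
    if (is.na(exitFrame(exit))) NULL else {
      demarcateTransition(exit, classes, config$gapTolerance)
    }
  })

  phiTable <- NULL
  if (!is.null(config$phiEnsembles)) {
    phiTable <- .stage("phi", {
      pe <- config$phiEnsembles
      phiBatch(pe$wt, pe$mutants, pe$nativeSet, cutoff = config$cutoff,
               minSeqSep = config$minSeqSep)
    })
    writeTable(phiTable, out("phi_values.csv"))
    artifacts <- c(artifacts, "phi_values.csv")
  }

  manifest <- list(
    package = "unfoldscape",
    version = as.character(utils::packageVersion("unfoldscape")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("trajectory", "native", "topology",
                                  "scenario", "phiEnsembles"))],
    constants = list(R_kcal_per_mol_K = .RGAS,
                     temperature_K = config$temperature,
                     tst_prefactor_per_s = config$prefactor),
    results = list(
      nFrames = nFrames(traj),
      explainedFraction = explainedFraction(emb),
      exitFrame = exitFrame(exit),
      exitTime = exitTime(exit),
      deltaFActivation = deltaFActivation(path),
      channelIndex = channelIndex(path),
      ku = rate$ku,
      transitionRange = if (is.null(ensemble)) NULL else frameRange(ensemble)
    ),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(
    trajectory = traj, native = native, distanceMatrix = D, embedding = emb,
    stepVectors = sv, exit = exit, grid = grid, path = path, rate = rate,
    contactSeries = cs, ssTimeline = ss, classes = classes,
    transitionEnsemble = ensemble, phiTable = phiTable,
    manifest = manifest
  ))
}

#' Run replicate synthetic pipelines and aggregate
#'
#' Repeats a synthetic-scenario pipeline with per-replicate seeds derived
#' deterministically from the base seed, and aggregates the recovered exit
#' times, activation free energies and channel indices (multiple
#' independent trajectories are needed to capture average unfolding
#' properties; single runs are anecdotes). Individual replicate failures
#' are recorded and aggregation proceeds with the survivors.
#'
#' @param config a \code{\link{pipelineConfig}} with a scenario.
#' @param nReplicates number of replicates (>= 2).
#' @return list with \code{perReplicate} (data.frame) and \code{summary}
#'   (mean and SD of each recovered quantity).
#' @export
runReplicates <- function(config, nReplicates) {
  stopifnot(inherits(config, "PipelineConfig"))
  nReplicates <- .assertCount(nReplicates, "nReplicates", min = 2L)
  if (is.null(config$scenario)) {
    stop("runReplicates requires a synthetic scenario configuration")
  }
  rows <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    cfg <- config
    cfg$seed <- config$seed + 7919L * r
    cfg$scenario$seed <- cfg$seed
    cfg$outputDir <- file.path(config$outputDir, sprintf("replicate_%02d", r))
    rows[[r]] <- tryCatch({
      res <- runPipeline(cfg)
      data.frame(
        replicate = r, seed = cfg$seed,
        exitFrame = exitFrame(res$exit),
        exitTime = exitTime(res$exit),
        deltaFActivation = deltaFActivation(res$path),
        channelIndex = channelIndex(res$path),
        error = NA_character_, stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(
        replicate = r, seed = cfg$seed, exitFrame = NA_integer_,
        exitTime = NA_real_, deltaFActivation = NA_real_,
        channelIndex = NA_real_, error = conditionMessage(e),
        stringsAsFactors = FALSE
      )
    })
  }
  per <- do.call(rbind, rows)
  ok <- is.na(per$error)
  summarize <- function(v) c(mean = mean(v[ok]), sd = stats::sd(v[ok]))
  list(
    perReplicate = per,
    summary = data.frame(
      quantity = c("exitTime", "deltaFActivation", "channelIndex"),
      mean = c(mean(per$exitTime[ok]), mean(per$deltaFActivation[ok]),
               mean(per$channelIndex[ok])),
      sd = c(stats::sd(per$exitTime[ok]), stats::sd(per$deltaFActivation[ok]),
             stats::sd(per$channelIndex[ok]))
    ),
    nFailed = sum(!ok)
  )
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig: T =", x$temperature, "K; k =", x$k, "; bins =",
      x$nBins, "; seed =", x$seed, "\n  output:", x$outputDir, "\n")
  invisible(x)
}
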