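#' @include AllClasses.R AllGenerics.R utils.R
NULL

# Build a Topology from a bio3d atom table (ATOM/HETATM records of one model).
.topologyFromAtoms <- function(atom) {
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  insert <- atom$insert
  insert[is.na(insert)] <- ""
  resKey <- paste(chain, atom$resno, insert, sep = "|")
  residueIndex <- as.integer(factor(resKey, levels = unique(resKey)))
  elety <- trimws(atom$elety)
  caMask <- elety == "CA"
  # one CA per residue at most; keep the first if a malformed file repeats it
  dupCA <- caMask & duplicated(paste(residueIndex, elety))
  caMask[dupCA] <- FALSE
  if (!any(caMask)) {
    stop("structure contains no C-alpha atoms")
  }
  elesy <- atom$elesy
  if (is.null(elesy) || all(is.na(elesy))) {
    elesy <- substr(elety, 1L, 1L)
  }
  elesy[is.na(elesy) | elesy == ""] <- substr(elety, 1L, 1L)[
    is.na(elesy) | elesy == ""]
  # flag breaks in the author's residue numbering within a chain
  for (ch in unique(chain)) {
    rn <- unique(atom$resno[chain == ch])
    if (length(rn) > 1L && any(diff(rn) > 1L)) {
      warning("chain '", ch, "' has discontinuous residue numbering",
              call. = FALSE)
    }
  }
  new("Topology",
    atomNames = elety,
    residueIndex = residueIndex,
    residueNames = as.character(atom$resid),
    masses = .massFromElement(elesy),
    calphaMask = caMask,
    sourceResno = as.integer(atom$resno),
    sourceChain = as.character(chain)
  )
}

#' Load a reference structure from a PDB file
#'
#' Reads a (possibly multi-model) PDB file and returns its topology together
#' with the coordinates of one model. PDB residue numbering is retained in
#' the topology for reporting; internal residue indices are 1-based and
#' contiguous. A residue without a CA atom is simply excluded from the
#' C-alpha mask; a chain with discontinuous residue numbering raises a
#' warning, not an error.
#'
#' @param path path to a PDB file.
#' @param model which MODEL to return (default 1; NMR ensembles often carry
#'   several near-identical models, so the choice is exposed rather than
#'   guessed).
#' @return a list with elements \code{topology} (a \linkS4class{Topology})
#'   and \code{coords} (atoms x 3 numeric matrix, Angstrom).
#' @examples
#' pdb <- system.file("extdata", "toy3.pdb", package = "unfoldscape")
#' s <- loadStructure(pdb)
#' sum(calphaMask(s$topology))
#' @export
loadStructure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  model <- .assertCount(model, "model")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nModels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > nModels) {
    stop("model ", model, " requested but file has ", nModels, " model(s)")
  }
  topo <- .topologyFromAtoms(pdb$atom)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  coords <- matrix(xyz, ncol = 3L, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y", "z")))
  list(topology = topo, coords = coords)
}

#' Load a coordinate trajectory
#'
#' Reads a trajectory from a multi-model PDB or a binary DCD file against a
#' known topology, optionally subsampling frames by a stride. The saved-frame
#' interval is scaled by the stride so times stay physical. XTC input is not
#' supported (no reader available in the R stack this package builds on);
#' convert to DCD or multi-model PDB first.
#'
#' @param path path to a multi-model PDB (.pdb) or DCD (.dcd) file.
#' @param topology the \linkS4class{Topology} the frames refer to.
#' @param stride keep every stride-th frame (default 1).
#' @param frameInterval ns between frames \emph{as stored in the file}
#'   (default 1); the returned trajectory's interval is
#'   \code{frameInterval * stride}.
#' @return a \linkS4class{Trajectory}.
#' @export
loadTrajectory <- function(path, topology, stride = 1L, frameInterval = 1) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  stopifnot(is(topology, "Topology"))
  stride <- .assertCount(stride, "stride")
  frameInterval <- .assertPositive(frameInterval, "frameInterval")
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  } else if (ext == "xtc") {
    stop("XTC trajectories are not supported; convert to DCD or PDB")
  } else {
    stop("unrecognised trajectory format: .", ext)
  }
  nAtomsFile <- ncol(xyz) / 3L
  if (nAtomsFile != length(topology@atomNames)) {
    stop(
      "atom-count mismatch: trajectory has ", nAtomsFile,
      " atoms, topology has ", length(topology@atomNames)
    )
  }
  if (nrow(xyz) < 1L) stop("trajectory contains no frames")
  keep <- seq(1L, nrow(xyz), by = stride)
  nT <- length(keep)
  arr <- array(NA_real_, dim = c(nT, nAtomsFile, 3L))
  for (f in seq_len(nT)) {
    arr[f, , ] <- matrix(xyz[keep[f], ], ncol = 3L, byrow = TRUE)
  }
  new("Trajectory",
    topology = topology, coords = arr,
    frameInterval = frameInterval * stride,
    originLabel = path, metadata = list(stride = stride)
  )
}

#' Write a trajectory as a multi-model PDB
#'
#' Serializes a \linkS4class{Trajectory} as MODEL/ENDMDL blocks in standard
#' fixed-width PDB format (coordinates to 0.001 Angstrom, the format's
#' precision). Source PDB residue numbering and chain identifiers are
#' preserved.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  topo <- traj@topology
  nA <- nAtoms(traj)
  elety <- topo@atomNames
  # PDB columns 13-16: names of <4 characters start in column 14
  nameField <- ifelse(
    nchar(elety) >= 4L, substr(elety, 1L, 4L),
    sprintf(" %-3s", elety)
  )
  elesy <- toupper(substr(elety, 1L, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyzF <- coords(traj, frame = f)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nA), nameField, substr(topo@residueNames, 1L, 3L),
      substr(topo@sourceChain, 1L, 1L), topo@sourceResno,
      xyzF[, 1L], xyzF[, 2L], xyzF[, 3L], 1, 0, elesy
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write and read tabular results
#'
#' Tabular outputs (time series, summaries) are serialized as CSV or JSON
#' with a lossless numeric round trip to at least 12 significant digits.
#' \code{NaN}/\code{NA} fields are written as an explicit null token and read
#' back as missing.
#'
#' @param records a data.frame (rectangular; zero rows allowed).
#' @param path output file path.
#' @param format "csv" or "json".
#' @return \code{writeTable}: the path, invisibly. \code{readTable}: a
#'   data.frame.
#' @export
writeTable <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) stop("records must be a data.frame")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist")
  if (format == "csv") {
    out <- records
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) {
        out[[j]] <- vapply(out[[j]], function(v) {
          if (is.na(v)) NA_character_ else format(v, digits = 15L)
        }, character(1L))
      }
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    jsonlite::write_json(records, path,
      dataframe = "rows", digits = NA, na = "null", auto_unbox = FALSE
    )
  }
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("table file not found: ", path)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

# Internal constructor used by generators: coords is frames x atoms x 3.
.newTrajectory <- function(topology, coordsArray, frameInterval, originLabel,
                           metadata = list()) {
  new("Trajectory",
    topology = topology, coords = coordsArray,
    frameInterval = frameInterval, originLabel = originLabel,
    metadata = metadata
  )
}

# Stack a list of atoms x 3 matrices into a frames x atoms x 3 array.
.stackFrames <- function(frameList) {
  nT <- length(frameList)
  nA <- nrow(frameList[[1L]])
  arr <- array(NA_real_, dim = c(nT, nA, 3L))
  for (f in seq_len(nT)) arr[f, , ] <- frameList[[f]]
  arr
}
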