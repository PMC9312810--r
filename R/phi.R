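#' @include AllClasses.R AllGenerics.R utils.R contacts.R
NULL

#' Mean native contacts of a frame ensemble
#'
#' Arithmetic mean over the ensemble of the per-frame count of native-set
#' pairs within the cutoff.
#'
#' @param frames a \linkS4class{Trajectory} (optionally restricted to an
#'   ensemble with \code{[}) whose frames form the ensemble.
#' @param nativeSet integer m x 2 native contact map (wild-type map by
#'   default convention; see \code{\link{phiBatch}}).
#' @param cutoff contact cutoff, Angstrom (default 8).
#' @return mean native-contact count (real).
#' @export
ensembleMeanContacts <- function(frames, nativeSet, cutoff = 8) {
  stopifnot(is(frames, "Trajectory"))
  if (nFrames(frames) < 1L) stop("empty ensemble")
  topo <- topology(frames)
  q <- vapply(seq_len(nFrames(frames)), function(f) {
    Xf <- coords(frames, frame = f)[topo@calphaMask, , drop = FALSE]
    d <- sqrt(rowSums((Xf[nativeSet[, 1L], , drop = FALSE] -
                         Xf[nativeSet[, 2L], , drop = FALSE])^2))
    sum(d <= cutoff)
  }, numeric(1L))
  mean(q)
}

#' Contact-ratio phi-value
#'
#' phi = (mean TS contacts, mutant - wild type) /
#' (mean folded contacts, mutant - wild type): the fraction of a mutation's
#' native-contact perturbation already felt in the transition-state
#' ensemble. A denominator smaller in magnitude than \code{eps} (below the
#' resolution of a single contact the ratio is noise) yields an
#' undefined-phi result carried as a flag, not an exception, so batch runs
#' complete. A phi outside [0, 1] is flagged as outside the physically
#' interpretable range, never clipped.
#'
#' @param meanTSMut,meanTSWt mean native contacts in the mutant and
#'   wild-type transition-state ensembles.
#' @param meanFMut,meanFWt same for the folded ensembles.
#' @param mutant mutant identifier (default "mutant").
#' @param eps undefined-denominator guard, contacts (default 0.5).
#' @return one-row data.frame: mutant, meanTSMut, meanTSWt, meanFMut,
#'   meanFWt, numerator, denominator, phi, undefined, outOfRange.
#' @examples
#' phiValue(45, 50, 50, 60)$phi # (45-50)/(50-60) = 0.5
#' @export
phiValue <- function(meanTSMut, meanTSWt, meanFMut, meanFWt,
                     mutant = "mutant", eps = 0.5) {
  num <- meanTSMut - meanTSWt
  den <- meanFMut - meanFWt
  undefined <- abs(den) < eps
  phi <- if (undefined) NA_real_ else num / den
  data.frame(
    mutant = as.character(mutant),
    meanTSMut = meanTSMut, meanTSWt = meanTSWt,
    meanFMut = meanFMut, meanFWt = meanFWt,
    numerator = num, denominator = den,
    phi = phi,
    undefined = undefined,
    outOfRange = !undefined && (phi < 0 || phi > 1),
    stringsAsFactors = FALSE
  )
}

#' Batch phi-values over a mutant panel
#'
#' Computes one contact-ratio phi per mutant from wild-type and mutant
#' {TS, F} ensembles. The wild-type native contact set is used for every
#' ensemble by default (\code{nativeSetMode = "wt"}); per-mutant contact
#' maps recomputed from each mutant's folded ensemble are available behind
#' \code{nativeSetMode = "per-mutant"}. Per-mutant failures are isolated:
#' the affected row carries NA and the error message, and the batch
#' completes.
#'
#' @param wt list with \code{TS} and \code{F} \linkS4class{Trajectory}
#'   ensembles.
#' @param mutants named list; each element a list with \code{TS} and
#'   \code{F} ensembles.
#' @param nativeSet wild-type native contact map (m x 2 integer matrix).
#' @param cutoff contact cutoff, Angstrom (default 8).
#' @param minSeqSep sequence separation of the contact definition, used
#'   when per-mutant maps are recomputed (default 3).
#' @param nativeSetMode "wt" (default) or "per-mutant".
#' @param eps undefined-denominator guard (default 0.5 contacts).
#' @return data.frame with one \code{\link{phiValue}} row per mutant,
#'   ordered by mutant id, plus ensemble sizes and an \code{error} column.
#' @export
phiBatch <- function(wt, mutants, nativeSet, cutoff = 8, minSeqSep = 3L,
                     nativeSetMode = c("wt", "per-mutant"), eps = 0.5) {
  nativeSetMode <- match.arg(nativeSetMode)
  ids <- names(mutants)
  if (is.null(ids) || any(ids == "")) stop("mutants must be a named list")
  ids <- sort(ids)
  tsWt <- ensembleMeanContacts(wt$TS, nativeSet, cutoff)
  fWt <- ensembleMeanContacts(wt$F, nativeSet, cutoff)
  rows <- lapply(ids, function(id) {
    mut <- mutants[[id]]
    res <- tryCatch({
      nset <- nativeSet
      if (nativeSetMode == "per-mutant") {
        topo <- topology(mut$F)
        nset <- nativeContacts(
          coords(mut$F, frame = 1L)[topo@calphaMask, , drop = FALSE],
          cutoff = cutoff, minSeqSep = minSeqSep
        )
      }
      r <- phiValue(
        ensembleMeanContacts(mut$TS, nset, cutoff),
        if (nativeSetMode == "wt") tsWt else
          ensembleMeanContacts(wt$TS, nset, cutoff),
        ensembleMeanContacts(mut$F, nset, cutoff),
        if (nativeSetMode == "wt") fWt else
          ensembleMeanContacts(wt$F, nset, cutoff),
        mutant = id, eps = eps
      )
      r$nFramesTS <- nFrames(mut$TS)
      r$nFramesF <- nFrames(mut$F)
      r$error <- NA_character_
      r
    }, error = function(e) {
      data.frame(
        mutant = id, meanTSMut = NA_real_, meanTSWt = NA_real_,
        meanFMut = NA_real_, meanFWt = NA_real_, numerator = NA_real_,
        denominator = NA_real_, phi = NA_real_, undefined = NA,
        outOfRange = NA, nFramesTS = NA_integer_, nFramesF = NA_integer_,
        error = conditionMessage(e), stringsAsFactors = FALSE
      )
    })
    res
  })
  do.call(rbind, rows)
}
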