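#' TPSequence: per-position triplet-periodicity phase counts
#'
#' One row per sequence position t holding the TP vector
#' \eqn{s_t = (Z_1, Z_2, Z_3)}: the counts of the residue at position t
#' within the posterior (suffix) subsequence, split by phase offset mod 3.
#' The final row is always \code{(0, 0, 0)} (empty suffix).
#'
#' @slot counts integer matrix, N x 3, columns Z1..Z3.
#' @slot base uppercase residues of the source sequence (length N).
#' @slot seqid label of the source sequence.
#'
#' @seealso [tpSequence()], [tpWalk()]
#' @exportClass TPSequence
setClass("TPSequence",
  representation(counts = "matrix", base = "character", seqid = "character"))

setValidity("TPSequence", function(object) {
  z <- object@counts
  if (ncol(z) != 3L) return("counts must have 3 columns (Z1, Z2, Z3)")
  if (!is.integer(z)) return("counts must be integer")
  if (nrow(z) != length(object@base))
    return("counts and base must have the same length")
  if (length(object@seqid) != 1L) return("seqid must be a single string")
  if (any(z < 0L)) return("phase counts must be non-negative")
  if (nrow(z) > 0L && any(z[nrow(z), ] != 0L))
    return("the last TP vector must be (0,0,0): the posterior is empty")
  TRUE
})

#' WalkTrace: cumulative triplet-periodicity walk in the complex plane
#'
#' The trajectory \eqn{W_0, \ldots, W_N} obtained by, at each position with
#' a non-degenerate TP vector, moving one unit in the direction of the
#' complex image of that vector. \eqn{W_0} is the origin and every
#' consecutive pair of points is at distance exactly 0 or 1.
#'
#' @slot positions complex vector of length N + 1 (\eqn{W_0} first).
#' @slot moved logical vector of length N; \code{TRUE} where a unit step
#'   was taken at that position.
#' @slot seqid label of the source sequence.
#'
#' @seealso [tpWalk()], [driftProfile()], [netDisplacement()]
#' @exportClass WalkTrace
setClass("WalkTrace",
  representation(positions = "complex", moved = "logical",
                 seqid = "character"))

setValidity("WalkTrace", function(object) {
  w <- object@positions
  if (length(w) < 1L) return("a trace has at least the origin point")
  if (w[1L] != 0 + 0i) return("W_0 must be the origin")
  if (length(object@moved) != length(w) - 1L)
    return("moved must have one flag per step (length N)")
  if (length(object@seqid) != 1L) return("seqid must be a single string")
  if (length(w) > 1L) {
    d <- Mod(diff(w))
    if (any(abs(d - ifelse(object@moved, 1, 0)) > 1e-9))
      return("every step must have length exactly 0 or 1, matching moved")
  }
  TRUE
})

#' SegmentationParams: tuning parameters for the region caller
#'
#' @slot window odd integer >= 3; span (in positions) of the drift window.
#' @slot threshold per-step drift level in (0, 1] above which a position is
#'   considered coding.
#' @slot minLength minimum call length in bases (>= window).
#' @slot mergeGap candidate runs closer than this many bases are merged.
#' @slot depth maximum number of recursive re-scanning passes after the
#'   first (0 disables refinement by excision).
#' @slot mode detection statistic: \code{"drift-magnitude"} (default,
#'   rotation-invariant) or \code{"real-part-slope"} (signed real-axis
#'   drift, faithful to reading the walk's real part).
#' @slot bidirectional also profile the reversed sequence and take the
#'   pointwise maximum; sharpens 3' boundaries (the TP vector is a suffix
#'   statistic, so coherence decays toward a region's end).
#' @slot refineBoundaries extend each call edge to the half-height point
#'   of its own drift plateau, removing the inward bias of a fixed
#'   threshold crossing.
#'
#' @seealso [SegmentationParams()], [callRegions()], [scanSequence()]
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(window = "integer", threshold = "numeric",
                 minLength = "integer", mergeGap = "integer",
                 depth = "integer", mode = "character",
                 bidirectional = "logical", refineBoundaries = "logical"))

setValidity("SegmentationParams", function(object) {
  w <- object@window
  if (length(w) != 1L || w < 3L || w %% 2L == 0L)
    return("window must be a single odd integer >= 3")
  if (object@threshold <= 0 || object@threshold > 1)
    return("threshold must lie in (0, 1]")
  if (object@minLength < w)
    return("minLength must be >= window")
  if (object@mergeGap < 0L) return("mergeGap must be >= 0")
  if (object@depth < 0L) return("depth must be >= 0")
  if (!object@mode %in% c("drift-magnitude", "real-part-slope"))
    return("mode must be 'drift-magnitude' or 'real-part-slope'")
  TRUE
})
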