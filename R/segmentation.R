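# Automated region calling on top of the walk.
#
# A coding region shows up as a stretch where the walk advances ~0.2 units
# per position in a consistent direction, while random DNA yields windowed
# drift an order of magnitude smaller. The caller thresholds a windowed
# drift profile, merges nearby runs, drops short ones, refines boundaries
# to the half-height of each call's own drift plateau, and then excises
# the calls and re-scans the flanking fragments: the TP vector is a
# statistic of the whole suffix, so a strongly biased region can mask
# weaker regions elsewhere in the same fragment until it is cut out.

#' Construct segmentation parameters
#'
#' Defaults: \code{window = 351} (odd, about a third of the shortest
#' region of interest), \code{threshold = 0.15} per-step drift (roughly
#' midway between the diffusion level of random DNA, ~0.03 at this window,
#' and the ~0.2 drift of strongly codon-biased DNA), \code{minLength =
#' 400}, \code{mergeGap = 200}, \code{depth = 2} refinement passes,
#' rotation-invariant drift statistic, bidirectional profiling and
#' half-height boundary refinement on.
#'
#' @param window,threshold,minLength,mergeGap,depth,mode,bidirectional,refineBoundaries
#'   see [SegmentationParams-class].
#' @return a validated [SegmentationParams-class] object.
#' @examples
#' SegmentationParams(threshold = 0.2)
#' @export
SegmentationParams <- function(window = 351L, threshold = 0.15,
                               minLength = 400L, mergeGap = 200L,
                               depth = 2L, mode = "drift-magnitude",
                               bidirectional = TRUE,
                               refineBoundaries = TRUE) {
  new("SegmentationParams", window = as.integer(window),
      threshold = as.numeric(threshold), minLength = as.integer(minLength),
      mergeGap = as.integer(mergeGap), depth = as.integer(depth),
      mode = as.character(mode), bidirectional = as.logical(bidirectional),
      refineBoundaries = as.logical(refineBoundaries))
}

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams:",
      sprintf("window=%d threshold=%.3g minLength=%d mergeGap=%d depth=%d",
              object@window, object@threshold, object@minLength,
              object@mergeGap, object@depth),
      sprintf("\n  mode=%s bidirectional=%s refineBoundaries=%s\n",
              object@mode, object@bidirectional, object@refineBoundaries))
})

#' Windowed drift profile of a walk trace
#'
#' For each sequence position t the displacement of the walk across a
#' window of \code{window} positions centred at t, normalised per step:
#' \eqn{|W_{hi} - W_{lo}| / (hi - lo)} with \eqn{lo = \max(0, t - h)},
#' \eqn{hi = \min(N, t + h)}, \eqn{h = \lfloor window/2 \rfloor} (edges
#' clamp the window). Values lie in [0, 1]. In \code{"real-part-slope"}
#' mode the numerator is the signed real-coordinate difference, matching a
#' reading of the walk's real part.
#'
#' @param x a [WalkTrace-class].
#' @param window odd integer window span, \code{window <= N}.
#' @param mode \code{"drift-magnitude"} or \code{"real-part-slope"}.
#' @param ... unused.
#' @return numeric vector of length N (one value per sequence position).
#' @examples
#' driftProfile(tpWalk(strrep("ACGACG", 100)), window = 51)[300]
#' @rdname driftProfile
#' @export
setMethod("driftProfile", "WalkTrace",
  function(x, window, mode = "drift-magnitude", ...) {
    mode <- match.arg(mode, c("drift-magnitude", "real-part-slope"))
    w <- as.integer(window)
    N <- length(x@positions) - 1L
    if (w < 3L || w %% 2L == 0L) stop("window must be an odd integer >= 3")
    if (w > N) stop("window (", w, ") larger than trace (", N, " steps)")
    h <- w %/% 2L
    t <- seq_len(N)
    lo <- pmax(0L, t - h)
    hi <- pmin(N, t + h)
    d <- x@positions[hi + 1L] - x@positions[lo + 1L]
    num <- if (mode == "drift-magnitude") Mod(d) else Re(d)
    num / (hi - lo)
  })

# Profile of a raw residue vector, honouring bidirectional combination:
# the suffix statistic is sharp at a region's 5' edge but decays toward
# its 3' edge; profiling the reversed residues swaps the two, and the
# pointwise maximum is sharp at both.
.profileOfChars <- function(chars, params) {
  id <- "fragment"
  pf <- driftProfile(tpWalk(tpSequence(chars, id = id)),
                     window = params@window, mode = params@mode)
  if (!params@bidirectional) return(pf)
  pr <- driftProfile(tpWalk(tpSequence(rev(chars), id = id)),
                     window = params@window, mode = params@mode)
  pmax(pf, rev(pr))
}

#' Call candidate regions from a drift profile
#'
#' Maximal runs with profile >= threshold become candidates; candidates
#' separated by fewer than \code{mergeGap} positions are merged;
#' candidates shorter than \code{minLength} are dropped; if
#' \code{refineBoundaries} is on, each surviving call's edges are extended
#' outward to the last position at or above half of the call's plateau
#' drift (75th percentile of the profile inside the call). Calls are
#' disjoint, sorted, and scored by their mean profile value.
#'
#' @param profile numeric vector as returned by [driftProfile()].
#' @param params a [SegmentationParams-class].
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive) and \code{score}; zero rows when nothing exceeds the
#'   threshold.
#' @examples
#' prof <- c(rep(0, 100), rep(1, 500), rep(0, 100))
#' callRegions(prof, SegmentationParams(window = 51, minLength = 51))
#' @export
callRegions <- function(profile, params = SegmentationParams()) {
  stopifnot(is.numeric(profile), length(profile) > 0L,
            is(params, "SegmentationParams"))
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0))
  r <- rle(profile >= params@threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  if (nrow(iv) == 0L) return(empty)
  merged <- list(iv[1L, ])
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (iv[i, 1L] - last[2L] - 1L < params@mergeGap)
      merged[[length(merged)]] <- c(last[1L], iv[i, 2L])
    else merged[[length(merged) + 1L]] <- iv[i, ]
  }
  iv <- do.call(rbind, merged)
  iv <- iv[iv[, 2L] - iv[, 1L] + 1L >= params@minLength, , drop = FALSE]
  if (nrow(iv) == 0L) return(empty)
  if (params@refineBoundaries) {
    N <- length(profile)
    for (i in seq_len(nrow(iv))) {
      core <- profile[iv[i, 1L]:iv[i, 2L]]
      half <- 0.5 * quantile(core, 0.75, names = FALSE)
      s <- iv[i, 1L]
      while (s > 1L && profile[s - 1L] >= half) s <- s - 1L
      e <- iv[i, 2L]
      while (e < N && profile[e + 1L] >= half) e <- e + 1L
      iv[i, ] <- c(s, e)
    }
    # refinement can only grow intervals; re-merge any that now touch
    if (nrow(iv) > 1L) {
      merged <- list(iv[1L, ])
      for (i in 2:nrow(iv)) {
        last <- merged[[length(merged)]]
        if (iv[i, 1L] <= last[2L] + 1L)
          merged[[length(merged)]] <- c(last[1L], max(last[2L], iv[i, 2L]))
        else merged[[length(merged) + 1L]] <- iv[i, ]
      }
      iv <- do.call(rbind, merged)
    }
  }
  data.frame(start = as.integer(iv[, 1L]), end = as.integer(iv[, 2L]),
             score = vapply(seq_len(nrow(iv)), function(i)
               mean(profile[iv[i, 1L]:iv[i, 2L]]), numeric(1)))
}

# Recursive scanner over a residue vector. Returns calls in absolute
# coordinates of the original sequence (offset-corrected), with the pass
# number on which each call was made.
.refineChars <- function(chars, params, offset = 0L, pass = 1L,
                         depthLeft = NULL) {
  if (is.null(depthLeft)) depthLeft <- params@depth
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0), pass = integer(0))
  n <- length(chars)
  if (n < max(params@minLength, params@window + 1L)) return(empty)
  calls <- callRegions(.profileOfChars(chars, params), params)
  if (nrow(calls) == 0L) return(empty)
  calls$pass <- pass
  out <- calls
  out$start <- out$start + offset
  out$end <- out$end + offset
  if (depthLeft > 0L) {
    # excise the calls; re-scan each flanking fragment independently
    # (never across an excision join, to avoid chimeric periodicity)
    starts <- sort(calls$start)
    ends <- sort(calls$end)
    fl <- cbind(c(1L, ends + 1L), c(starts - 1L, n))
    for (i in seq_len(nrow(fl))) {
      a <- fl[i, 1L]; b <- fl[i, 2L]
      if (b < a) next
      sub <- .refineChars(chars[a:b], params, offset = offset + a - 1L,
                          pass = pass + 1L, depthLeft = depthLeft - 1L)
      out <- rbind(out, sub)
    }
  }
  out[order(out$start), , drop = FALSE]
}

#' Recursively scan a sequence for coding regions
#'
#' Runs the full chain (TP sequence, walk, drift profile, region calls) on
#' the input, excises the called intervals, and re-runs the chain on each
#' remaining flanking fragment, up to \code{depth} additional passes or
#' until no new calls appear. Re-scanning matters because the TP vector is
#' computed over the whole remaining fragment: one strongly biased region
#' can mask a weaker one until it is cut out. Nested coordinates are
#' mapped back to the original frame; the result is disjoint and sorted.
#'
#' @param x a single DNA sequence (as in [tpSequence()]).
#' @param params a [SegmentationParams-class].
#' @param id sequence label.
#' @return data.frame with columns \code{start}, \code{end}, \code{score}
#'   (mean per-step drift) and \code{pass} (1 = found on the initial scan).
#' @seealso [scanSequence()] for a GRanges interface over multi-record
#'   inputs.
#' @export
refineRecursive <- function(x, params = SegmentationParams(), id = NULL) {
  chars <- .asChars(x)
  .refineChars(chars, params)
}

.callsAsGRanges <- function(df, id, seqlens, strand = "*") {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(rep(id, nrow(df)), levels = names(seqlens)),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = rep(strand, nrow(df)),
    seqlengths = seqlens)
  S4Vectors::mcols(gr)$score <- df$score
  S4Vectors::mcols(gr)$pass <- df$pass
  gr
}

#' Scan sequences and return coding-region calls as GRanges
#'
#' Applies [refineRecursive()] to each record of the input and collects
#' the calls into a [GenomicRanges::GRanges-class] (1-based, inclusive)
#' with metadata columns \code{score} (mean per-step drift) and
#' \code{pass} (refinement pass of discovery). With \code{bothStrands =
#' TRUE} the reverse complement is scanned as well and calls are reported
#' with strand \code{-} in forward coordinates; by default only the given
#' orientation is scanned and strand is \code{*}.
#'
#' @param x a [Biostrings::DNAStringSet-class], [Biostrings::DNAString-class]
#'   or character vector of sequences (names become sequence ids).
#' @param params a [SegmentationParams-class].
#' @param bothStrands also scan the reverse complement.
#' @param ... unused.
#' @return a sorted \code{GRanges} of calls.
#' @examples
#' fx <- buildFixture(backgroundLength = 3000, insertLengths = 1500,
#'                    insertPositions = 1000, seed = 7)
#' scanSequence(fx$sequence, SegmentationParams(window = 151,
#'              minLength = 300, depth = 0))
#' @rdname scanSequence
#' @export
setMethod("scanSequence", "DNAStringSet",
  function(x, params = SegmentationParams(), bothStrands = FALSE, ...) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    seqlens <- stats::setNames(Biostrings::width(x), ids)
    grs <- lapply(seq_along(x), function(i) {
      chars <- .asChars(x[i])
      N <- length(chars)
      df <- .refineChars(chars, params)
      gr <- .callsAsGRanges(df, ids[i], seqlens,
                            strand = if (bothStrands) "+" else "*")
      if (bothStrands) {
        rc <- .asChars(Biostrings::reverseComplement(x[[i]]))
        dfr <- .refineChars(rc, params)
        if (nrow(dfr)) {
          dfr2 <- data.frame(start = N - dfr$end + 1L,
                             end = N - dfr$start + 1L,
                             score = dfr$score, pass = dfr$pass)
          gr <- c(gr, .callsAsGRanges(dfr2[order(dfr2$start), , drop = FALSE],
                                      ids[i], seqlens, strand = "-"))
        }
      }
      gr
    })
    BiocGenerics::sort(do.call(c, grs), ignore.strand = TRUE)
  })

#' @rdname scanSequence
#' @export
setMethod("scanSequence", "DNAString",
  function(x, params = SegmentationParams(), bothStrands = FALSE, ...) {
    scanSequence(Biostrings::DNAStringSet(x), params,
                 bothStrands = bothStrands, ...)
  })

#' @rdname scanSequence
#' @export
setMethod("scanSequence", "character",
  function(x, params = SegmentationParams(), bothStrands = FALSE, ...) {
    xs <- Biostrings::DNAStringSet(x)
    scanSequence(xs, params, bothStrands = bothStrands, ...)
  })
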