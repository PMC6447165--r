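# The TP walk: each TP vector s = (Z1, Z2, Z3) is mapped to
#   L(s) = Z1 e^{-i 2pi/3} + Z2 e^{-i 4pi/3} + Z3
# and the walk takes a unit step in the direction of L(s) whenever
# L(s) != 0. Because the three coefficients are the cube roots of unity,
# L(s) = 0 exactly when Z1 = Z2 = Z3, so the zero-step guard is an exact
# integer test; directions are computed from integer differences before
# normalization and are therefore bit-reproducible.

#' Map a TP vector to its complex-plane image
#'
#' \eqn{L(s) = Z_1 e^{-i2\pi/3} + Z_2 e^{-i4\pi/3} + Z_3}, i.e.
#' \eqn{(Z_3 - (Z_1+Z_2)/2) + i\,\sqrt{3}(Z_2 - Z_1)/2}. The image is zero
#' exactly when the three components are equal.
#'
#' @param v numeric vector of length 3 (\code{Z1, Z2, Z3}).
#' @return a complex scalar.
#' @examples
#' mapToComplex(c(1, 1, 1))  # 0+0i
#' mapToComplex(c(0, 0, 1))  # 1+0i
#' @export
mapToComplex <- function(v) {
  stopifnot(length(v) == 3L)
  complex(real = v[3L] - (v[1L] + v[2L]) / 2,
          imaginary = sqrt(3) * (v[2L] - v[1L]) / 2)
}

.walkFromCounts <- function(Z, id) {
  N <- nrow(Z)
  if (N == 0L)
    return(new("WalkTrace", positions = complex(real = 0, imaginary = 0),
               moved = logical(0), seqid = id))
  # doubled real / sqrt(3)-scaled imaginary parts stay integer
  re2 <- 2L * Z[, 3L] - Z[, 1L] - Z[, 2L]
  im2 <- Z[, 2L] - Z[, 1L]
  nz <- unname(re2 != 0L | im2 != 0L)
  stp <- complex(real = re2, imaginary = sqrt(3) * im2)
  stp[nz] <- stp[nz] / Mod(stp[nz])
  stp[!nz] <- 0 + 0i
  new("WalkTrace", positions = unname(c(0 + 0i, cumsum(stp))), moved = nz,
      seqid = id)
}

#' Accumulate the TP walk of a sequence
#'
#' Starting from the origin, for each position whose TP vector has a
#' nonzero complex image the walk moves one unit in that image's
#' direction; degenerate vectors (all components equal) leave the walk in
#' place. The result has N + 1 points for a sequence of length N.
#'
#' @param x a [TPSequence-class], or any sequence input accepted by
#'   [tpSequence()] (computed on the fly).
#' @param ... passed to [tpSequence()] for sequence inputs.
#' @return a [WalkTrace-class].
#' @examples
#' realPart(tpWalk("AAAA"))  # 0 0 -1 -1.5 -1.5
#' @rdname tpWalk
#' @export
setMethod("tpWalk", "TPSequence",
  function(x, ...) .walkFromCounts(tpCounts(x), seqId(x)))

#' @rdname tpWalk
#' @export
setMethod("tpWalk", "character",
  function(x, ...) tpWalk(tpSequence(x, ...)))

#' @rdname tpWalk
#' @export
setMethod("tpWalk", "DNAString",
  function(x, ...) tpWalk(tpSequence(x, ...)))

#' @rdname tpWalk
#' @export
setMethod("tpWalk", "DNAStringSet",
  function(x, ...) tpWalk(tpSequence(x, ...)))

#' @rdname accessors
#' @export
setMethod("walkPositions", "WalkTrace", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("stepMoved", "WalkTrace", function(x) x@moved)

#' @rdname accessors
#' @export
setMethod("seqId", "WalkTrace", function(x) x@seqid)

#' Accessors for TPSequence and WalkTrace
#'
#' \code{tpCounts} returns the N x 3 phase-count matrix; \code{realPart} /
#' \code{imagPart} return the N + 1 walk coordinates; \code{stepMoved}
#' flags the positions where a unit step was taken; \code{seqId} returns
#' the source label; \code{walkPositions} the complex trajectory.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("realPart", "WalkTrace", function(x) Re(x@positions))

#' @rdname accessors
#' @export
setMethod("imagPart", "WalkTrace", function(x) Im(x@positions))

#' @describeIn tpWalk number of trace points (N + 1).
#' @export
setMethod("length", "WalkTrace", function(x) length(x@positions))

setMethod("show", "WalkTrace", function(object) {
  n <- length(object@positions) - 1L
  endp <- object@positions[n + 1L]
  cat("WalkTrace for sequence", sQuote(object@seqid), "\n",
      " steps:", n, "(", sum(object@moved), "moves )\n",
      sprintf("  endpoint: (%.2f, %.2f), net displacement %.2f\n",
              Re(endp), Im(endp), Mod(endp)))
})

#' Net displacement of a walk trace
#'
#' Magnitude and direction of \eqn{W_N - W_0}. A drifting (coding) walk
#' has displacement a sizable fraction of the number of steps; a diffusing
#' (random) walk stays near the origin. The angle of a zero vector is 0 by
#' convention.
#'
#' @param x a [WalkTrace-class].
#' @return named numeric vector \code{c(magnitude, angle)}; the angle is in
#'   radians, counterclockwise, in \eqn{(-\pi, \pi]}.
#' @examples
#' netDisplacement(tpWalk("AA"))  # magnitude 1, angle -2*pi/3
#' @rdname netDisplacement
#' @export
setMethod("netDisplacement", "WalkTrace", function(x) {
  w <- x@positions
  d <- w[length(w)] - w[1L]
  c(magnitude = Mod(d), angle = if (Mod(d) == 0) 0 else Arg(d))
})

#' Write a walk trace to a TSV file
#'
#' Columns: t (0-based trace index), real, imag, moved (0/1; 0 for the
#' origin row).
#'
#' @param x a [WalkTrace-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportTrace <- function(x, path) {
  stopifnot(is(x, "WalkTrace"))
  n <- length(x@positions)
  df <- data.frame(t = 0:(n - 1L), real = Re(x@positions),
                   imag = Im(x@positions),
                   moved = c(0L, as.integer(x@moved)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-panel TP walk figure
#'
#' Panel (a): the trajectory in the complex plane. Panel (b): real (red)
#' and imaginary (green) coordinates against position, the view in which
#' coding regions appear as sustained slopes.
#'
#' @param x a [WalkTrace-class].
#' @param main title prefix; defaults to the sequence id.
#' @return invisibly, \code{NULL}.
#' @importFrom graphics par plot lines legend abline
#' @export
plotWalk <- function(x, main = seqId(x)) {
  stopifnot(is(x, "WalkTrace"))
  w <- x@positions
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(par(op))
  plot(Re(w), Im(w), type = "l", col = "steelblue",
       xlab = "real", ylab = "imaginary",
       main = paste0(main, " (a) walk trace"))
  t <- seq_along(w) - 1L
  plot(t, Re(w), type = "l", col = "red", xlab = "t", ylab = "coordinate",
       ylim = range(c(Re(w), Im(w))),
       main = paste0(main, " (b) components"))
  lines(t, Im(w), col = "darkgreen")
  legend("topleft", legend = c("real", "imaginary"), bty = "n",
         col = c("red", "darkgreen"), lty = 1)
  invisible(NULL)
}
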