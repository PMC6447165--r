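# Triplet-periodicity matrix recursion.
#
# For sequence X = x_1..x_N the posterior subsequence at t is the suffix
# strictly after t. The TPM of that suffix holds, for each base, the counts
# of its occurrences by phase offset (u - t - 1) mod 3. The defining
# backward recursion is: at t = N all vectors are (0,0,0); moving from
# t + 1 to t, every base vector is circular-shifted right once and the
# vector of base x_{t+1} gains (1,0,0). Unrolled, component j of base b's
# vector at t counts positions u > t with x_u = b and u = t + j (mod 3) --
# which is what .tpStates evaluates directly with suffix sums, in O(N) and
# exact integer arithmetic.

# Full recursion state: list with one N x 3 integer matrix per base
# (A, C, G, T); row t is that base's TP vector over the suffix after t.
.tpStates <- function(code) {
  N <- length(code)
  states <- rep(list(matrix(0L, N, 3L)), 4L)
  names(states) <- .BASES
  if (N == 0L) return(states)
  umod <- seq_len(N) %% 3L
  for (b in 1:4) {
    isb <- !is.na(code) & code == b
    # S[t, r+1] = #{u > t : x_u = base b, u mod 3 = r}
    S <- matrix(0L, N, 3L)
    for (r in 0:2) {
      ind <- as.integer(isb & umod == r)
      S[, r + 1L] <- rev(cumsum(rev(ind))) - ind
    }
    Z <- states[[b]]
    t <- seq_len(N)
    for (j in 1:3) Z[, j] <- S[cbind(t, ((t + j) %% 3L) + 1L)]
    states[[b]] <- Z
  }
  states
}

.tpSequenceFromChars <- function(chars, id) {
  code <- .baseCode(chars)
  states <- .tpStates(code)
  N <- length(chars)
  counts <- matrix(0L, N, 3L, dimnames = list(NULL, c("Z1", "Z2", "Z3")))
  for (b in 1:4) {
    rows <- which(!is.na(code) & code == b)
    if (length(rows)) counts[rows, ] <- states[[b]][rows, , drop = FALSE]
  }
  # ambiguous residues keep s_t = (0,0,0)
  new("TPSequence", counts = counts, base = chars, seqid = id)
}

#' Convert a DNA sequence into its triplet-periodicity sequence
#'
#' Runs the backward TPM recursion and returns, for every position t, the
#' TP vector of the residue at t over the posterior subsequence (the
#' suffix strictly after t). Ambiguous residues (anything outside
#' A/C/G/T after uppercasing) are never counted and receive the zero
#' vector at their own position.
#'
#' @param x a single DNA sequence: character scalar, character vector of
#'   residues, [Biostrings::DNAString-class], or a length-one
#'   [Biostrings::DNAStringSet-class].
#' @param id sequence label; defaults to the FASTA name when available.
#' @param maskLowercase treat soft-masked (lowercase) residues as
#'   ambiguous instead of ordinary residues.
#' @param ... unused.
#' @return a [TPSequence-class] with one row per position.
#'
#' @examples
#' tpCounts(tpSequence("AAAA"))
#' @rdname tpSequence
#' @export
setMethod("tpSequence", "character",
  function(x, id = NULL, maskLowercase = FALSE, ...) {
    .tpSequenceFromChars(.asChars(x, maskLowercase), .seqIdOf(x, id))
  })

#' @rdname tpSequence
#' @export
setMethod("tpSequence", "DNAString",
  function(x, id = NULL, maskLowercase = FALSE, ...) {
    .tpSequenceFromChars(.asChars(x, maskLowercase), .seqIdOf(x, id))
  })

#' @rdname tpSequence
#' @export
setMethod("tpSequence", "DNAStringSet",
  function(x, id = NULL, maskLowercase = FALSE, ...) {
    .tpSequenceFromChars(.asChars(x, maskLowercase), .seqIdOf(x, id))
  })

#' Brute-force posterior phase counts (verification oracle)
#'
#' Counts, by direct enumeration of the suffix, how often \code{base}
#' occurs after position \code{t} at each phase offset
#' \eqn{((u - t - 1) \bmod 3) + 1}. This is the independent oracle for the
#' TPM recursion behind [tpSequence()]; the two are compared in the test
#' suite and must agree entrywise.
#'
#' @param x a DNA sequence (as in [tpSequence()]).
#' @param t 1-based position, \code{1 <= t <= N}.
#' @param base one of \code{"A"}, \code{"C"}, \code{"G"}, \code{"T"}.
#' @return integer vector \code{c(Z1, Z2, Z3)}.
#' @examples
#' posteriorPhaseCounts("AAAA", 1, "A")  # (1, 1, 1)
#' @export
posteriorPhaseCounts <- function(x, t, base) {
  chars <- .asChars(x)
  N <- length(chars)
  if (t < 1L || t > N) stop("position t = ", t, " out of range 1..", N)
  base <- toupper(base)
  if (!base %in% .BASES) stop("base must be one of A, C, G, T")
  u <- seq_len(N)
  sel <- u > t & chars == base
  off <- ((u - t - 1L) %% 3L) + 1L
  c(Z1 = sum(sel & off == 1L), Z2 = sum(sel & off == 2L),
    Z3 = sum(sel & off == 3L))
}

#' Triplet-periodicity matrix of the posterior subsequence at a position
#'
#' The full 4 x 3 TPM (rows A, T, C, G; columns phases 1..3) maintained by
#' the recursion at position \code{t}. On an ambiguity-free input its 12
#' entries sum to \code{N - t}.
#'
#' @inheritParams posteriorPhaseCounts
#' @return integer matrix with rownames \code{A, T, C, G}.
#' @examples
#' tpMatrix("ACGT", 1)
#' @export
tpMatrix <- function(x, t) {
  chars <- .asChars(x)
  N <- length(chars)
  if (t < 1L || t > N) stop("position t = ", t, " out of range 1..", N)
  states <- .tpStates(.baseCode(chars))
  m <- rbind(A = states[["A"]][t, ], T = states[["T"]][t, ],
             C = states[["C"]][t, ], G = states[["G"]][t, ])
  colnames(m) <- c("Z1", "Z2", "Z3")
  m
}

#' Right circular shift of a TP vector
#'
#' One application maps \code{(Z1, Z2, Z3)} to \code{(Z3, Z1, Z2)}; n
#' applications compose, so shifting by 3 is the identity.
#'
#' @param v numeric vector of length 3.
#' @param n number of shifts, \code{n >= 0}.
#' @return the rotated vector.
#' @examples
#' circularShiftRight(c(1, 2, 3))      # 3 1 2
#' circularShiftRight(c(1, 2, 3), 3)   # identity
#' @export
circularShiftRight <- function(v, n = 1L) {
  stopifnot(length(v) == 3L, n >= 0L)
  k <- as.integer(n) %% 3L
  if (k == 0L) return(v)
  v[(((seq_len(3L) - 1L) - k) %% 3L) + 1L]
}

#' @rdname accessors
#' @param x a TPSequence or WalkTrace object.
#' @export
setMethod("tpCounts", "TPSequence", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("seqId", "TPSequence", function(x) x@seqid)

#' @describeIn tpSequence number of positions.
#' @export
setMethod("length", "TPSequence", function(x) nrow(x@counts))

setMethod("show", "TPSequence", function(object) {
  N <- length(object)
  cat("TPSequence of", N, "positions for sequence", sQuote(object@seqid),
      "\n")
  if (N > 0L) {
    k <- min(N, 4L)
    df <- data.frame(position = seq_len(k), base = object@base[seq_len(k)],
                     object@counts[seq_len(k), , drop = FALSE])
    print(df, row.names = FALSE)
    if (N > k) cat("... and", N - k, "more positions\n")
  }
})

#' @describeIn tpSequence tabular view: position, base, Z1, Z2, Z3.
#' @param row.names,optional,... passed on conventionally (unused).
#' @export
as.data.frame.TPSequence <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(position = seq_len(length(x)), base = x@base, x@counts,
             stringsAsFactors = FALSE)
}

#' Write a TPSequence to a TSV file
#'
#' Columns: position (1-based), base, Z1, Z2, Z3.
#'
#' @param x a [TPSequence-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportTPSequence <- function(x, path) {
  stopifnot(is(x, "TPSequence"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
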