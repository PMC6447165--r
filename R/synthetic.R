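# Synthetic sequences with known coding structure.
#
# The generator emulates exactly the statistical contrast the scanner
# relies on: i.i.d. background nucleotides (no periodicity, walk
# diffuses) versus concatenated codons drawn from a biased usage table
# (positional base concentration, walk drifts). Inserts are spliced
# *between* background residues, growing the total length, so a 5000-bp
# background with a 5244-bp insert at position 2000 yields a 10244-bp
# sequence whose coding interval is 2000..7243.

# Dominant-codon rule for the beta = 1 table: within each synonymous
# family prefer the alphabetically first C-ending codon, else G-ending,
# else first -- the GC3-rich usage typical of high-GC bacteria. The stop
# class is treated like any other family (inserts are statistical
# stand-ins for coding DNA, not translatable ORFs).
.highBiasTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    code <- Biostrings::GENETIC_CODE
    p <- stats::setNames(numeric(length(code)), names(code))
    fams <- unique(code)
    for (a in fams) {
      cods <- sort(names(code)[code == a])
      cand <- cods[endsWith(cods, "C")]
      if (!length(cand)) cand <- cods[endsWith(cods, "G")]
      dom <- if (length(cand)) cand[1L] else cods[1L]
      k <- length(cods)
      if (k == 1L) p[cods] <- 1
      else {
        p[cods] <- 0.3 / (k - 1L)
        p[dom] <- 0.7
      }
      p[cods] <- p[cods] / sum(p[cods]) / length(fams)
    }
    tab <<- p / sum(p)
    tab
  }
})

#' Codon usage table with tunable bias strength
#'
#' Interpolates between the uniform table (\code{beta = 0}: every codon
#' 1/64, no triplet periodicity) and a fixed high-bias table
#' (\code{beta = 1}: within each synonymous family one dominant codon
#' carries weight 0.7 and the rest share 0.3 evenly; families weighted
#' equally). The high-bias table prefers C-ending, then G-ending codons,
#' emulating the GC3-rich usage of high-GC bacteria; sequences drawn from
#' it drive the TP walk at roughly 0.2 units per step.
#'
#' @param beta bias strength in [0, 1].
#' @return named numeric vector of 64 codon probabilities summing to 1.
#' @examples
#' sum(codonUsageTable(0.5))
#' @export
codonUsageTable <- function(beta = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1)
  p <- (1 - beta) / 64 + beta * .highBiasTable()
  p / sum(p)
}

.checkTable <- function(table) {
  if (!is.numeric(table) || length(table) != 64L || is.null(names(table)))
    stop("usage table must be a named numeric vector of 64 codons")
  if (any(table < 0) || abs(sum(table) - 1) > 1e-12)
    stop("usage table probabilities must be >= 0 and sum to 1")
  invisible(table)
}

#' Random non-coding background sequence
#'
#' I.i.d. nucleotide draws with \eqn{P(G) = P(C) = gc/2} and
#' \eqn{P(A) = P(T) = (1 - gc)/2}. Such a sequence has no triplet
#' periodicity: its TP walk diffuses near the origin.
#'
#' @param length number of residues (>= 0).
#' @param gc GC fraction in [0, 1]; 0.5 gives the uniform background.
#' @param seed optional integer for reproducible output (caller RNG state
#'   is preserved).
#' @return a [Biostrings::DNAString-class].
#' @examples
#' randomBackground(30, seed = 1)
#' @export
randomBackground <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length >= 0)
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- withSeed(seed,
    sample(.BASES, size = length, replace = TRUE, prob = probs))
  Biostrings::DNAString(paste(chars, collapse = ""))
}

#' Synthetic codon-biased coding sequence
#'
#' Concatenates \code{nCodons} i.i.d. codon draws from a usage table. With
#' the default high-bias table the resulting sequence carries a strong
#' triplet-periodicity signal and its TP walk drifts directionally.
#'
#' @param nCodons number of codons (sequence length is \code{3 * nCodons}).
#' @param table a codon usage table from [codonUsageTable()].
#' @param seed optional integer for reproducibility.
#' @return a [Biostrings::DNAString-class].
#' @examples
#' codingSequence(10, seed = 1)
#' @export
codingSequence <- function(nCodons, table = codonUsageTable(1),
                           seed = NULL) {
  stopifnot(nCodons >= 0)
  .checkTable(table)
  cods <- withSeed(seed,
    sample(names(table), size = nCodons, replace = TRUE, prob = table))
  Biostrings::DNAString(paste(cods, collapse = ""))
}

#' Build a synthetic genome fixture with known coding coordinates
#'
#' Generates an i.i.d. background and splices codon-biased inserts between
#' background residues at the requested 1-based positions of the *final*
#' sequence (insert i occupies \code{insertPositions[i] ..
#' insertPositions[i] + insertLengths[i] - 1}). Total length is
#' \code{backgroundLength + sum(insertLengths)}. Intervals must be
#' disjoint and fit inside the final sequence. All randomness flows from
#' one master seed (background first, then each insert in order), so the
#' same call reproduces the identical sequence.
#'
#' @param backgroundLength background residue count.
#' @param insertLengths integer vector of insert lengths in bases (each
#'   rounded up to whole codons internally, then trimmed to length).
#' @param insertPositions start position of each insert in the final
#'   sequence.
#' @param gc background GC fraction.
#' @param table codon usage table for the inserts, or a list of tables
#'   (one per insert).
#' @param seed master seed.
#' @param id sequence label for the output.
#' @return list with elements \code{sequence}
#'   ([Biostrings::DNAString-class]), \code{truth}
#'   ([GenomicRanges::GRanges-class] of the true coding intervals) and
#'   \code{id}.
#' @examples
#' fx <- buildFixture(5000, insertLengths = 5244, insertPositions = 2000,
#'                    seed = 1)
#' length(fx$sequence)   # 10244
#' fx$truth              # 2000-7243
#' @export
buildFixture <- function(backgroundLength, insertLengths = integer(0),
                         insertPositions = integer(0), gc = 0.5,
                         table = codonUsageTable(1), seed = NULL,
                         id = "synthetic") {
  stopifnot(backgroundLength >= 0,
            length(insertLengths) == length(insertPositions))
  insertLengths <- as.integer(insertLengths)
  insertPositions <- as.integer(insertPositions)
  if (any(insertLengths < 1L)) stop("insert lengths must be >= 1")
  tables <- if (is.list(table)) table else
    rep(list(table), length(insertLengths))
  if (length(tables) != length(insertLengths))
    stop("need one usage table per insert")
  lapply(tables, .checkTable)
  ord <- order(insertPositions)
  insertLengths <- insertLengths[ord]
  insertPositions <- insertPositions[ord]
  tables <- tables[ord]
  finalLen <- backgroundLength + sum(insertLengths)
  starts <- insertPositions
  ends <- insertPositions + insertLengths - 1L
  if (any(starts < 1L) || any(ends > finalLen))
    stop("insert beyond sequence bounds (final length ", finalLen, ")")
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("inserts overlap")
  chars <- withSeed(seed, {
    bg <- sample(.BASES, size = backgroundLength, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    insChars <- lapply(seq_along(insertLengths), function(i) {
      nc <- ceiling(insertLengths[i] / 3)
      cods <- sample(names(tables[[i]]), size = nc, replace = TRUE,
                     prob = tables[[i]])
      strsplit(paste(cods, collapse = ""), "", fixed = TRUE)[[1L]][
        seq_len(insertLengths[i])]
    })
    out <- character(finalLen)
    isIns <- logical(finalLen)
    for (i in seq_along(starts)) {
      out[starts[i]:ends[i]] <- insChars[[i]]
      isIns[starts[i]:ends[i]] <- TRUE
    }
    out[!isIns] <- bg
    out
  })
  truth <- GenomicRanges::GRanges(
    seqnames = rep(id, length(starts)),
    ranges = IRanges::IRanges(start = starts, end = ends),
    seqlengths = stats::setNames(finalLen, id))
  list(sequence = Biostrings::DNAString(paste(chars, collapse = "")),
       truth = truth, id = id)
}

#' Write a fixture to FASTA plus a BED file of the true intervals
#'
#' @param fixture result of [buildFixture()].
#' @param fastaPath,bedPath output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
writeFixture <- function(fixture, fastaPath, bedPath) {
  xs <- Biostrings::DNAStringSet(fixture$sequence)
  names(xs) <- fixture$id
  Biostrings::writeXStringSet(xs, fastaPath)
  rtracklayer::export(fixture$truth, bedPath, format = "bed")
  invisible(c(fastaPath, bedPath))
}
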