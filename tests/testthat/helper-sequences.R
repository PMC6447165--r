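# shared helpers: all fixtures are generated in code, never stored

BASES <- c("A", "C", "G", "T")

randomChars <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(BASES, n, replace = TRUE)
}

charsToString <- function(chars) paste(chars, collapse = "")

# mean |W_N| / N over sequences supplied as character strings
meanEndpointRate <- function(seqs) {
  mean(vapply(seqs, function(s) {
    tr <- tpWalk(s)
    netDisplacement(tr)[["magnitude"]] / (length(tr) - 1L)
  }, numeric(1)))
}

# overlap-matched boundary errors of calls (GRanges) against truth (GRanges)
boundaryErrors <- function(calls, truth) {
  if (length(calls) == 0L) return(NULL)
  s <- GenomicRanges::start(calls); e <- GenomicRanges::end(calls)
  ts <- GenomicRanges::start(truth); te <- GenomicRanges::end(truth)
  ov <- pmin(e, te) - pmax(s, ts)
  if (max(ov) <= 0L) return(NULL)
  i <- which.max(ov)
  c(abs(s[i] - ts), abs(e[i] - te))
}
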