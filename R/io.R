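# Export of coding-region calls. Calls are GRanges (1-based inclusive)
# throughout the package; the 0-based half-open convention appears only
# at the BED boundary, which rtracklayer handles.

.checkCalls <- function(calls) {
  stopifnot(is(calls, "GRanges"))
  if (is.null(S4Vectors::mcols(calls)$score))
    stop("calls must carry a 'score' metadata column")
  invisible(calls)
}

#' Write calls as BED6
#'
#' Score column is \code{round(1000 * mean drift)}, capped at 1000;
#' strand is taken from the calls (\code{*} becomes \code{.} in the
#' file).
#'
#' @param calls a \code{GRanges} from [scanSequence()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCallsBED <- function(calls, path) {
  .checkCalls(calls)
  out <- calls
  S4Vectors::mcols(out) <- NULL
  S4Vectors::mcols(out)$name <- sprintf("call_%d", seq_along(out))
  S4Vectors::mcols(out)$score <-
    pmin(1000, round(1000 * S4Vectors::mcols(calls)$score))
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Write calls as GFF3
#'
#' Features of type \code{CDS_prediction}, source \code{tpscan}, with the
#' mean per-step drift as the score attribute.
#'
#' @inheritParams writeCallsBED
#' @return the path, invisibly.
#' @export
writeCallsGFF3 <- function(calls, path) {
  .checkCalls(calls)
  out <- calls
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    source = rep("tpscan", length(out)),
    type = rep("CDS_prediction", length(out)),
    score = S4Vectors::mcols(calls)$score,
    pass = S4Vectors::mcols(calls)$pass)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Write calls as a TSV report
#'
#' Columns: id, start, end (1-based inclusive), length, strand, score,
#' pass.
#'
#' @inheritParams writeCallsBED
#' @return the path, invisibly.
#' @export
writeCallsTSV <- function(calls, path) {
  .checkCalls(calls)
  df <- data.frame(
    id = as.character(GenomicRanges::seqnames(calls)),
    start = GenomicRanges::start(calls),
    end = GenomicRanges::end(calls),
    length = GenomicRanges::width(calls),
    strand = as.character(GenomicRanges::strand(calls)),
    score = S4Vectors::mcols(calls)$score,
    pass = S4Vectors::mcols(calls)$pass)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a (multi-record) FASTA file of DNA sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions to the first word so record ids are usable as sequence
#' names, and gives a clearer error for unreadable input.
#'
#' @param path FASTA file (wrapped lines and CRLF endings are fine).
#' @return a named [Biostrings::DNAStringSet-class].
#' @export
readFastaDNA <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  xs <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e)
                   stop("cannot parse FASTA ", path, ": ",
                        conditionMessage(e)))
  if (!is.null(names(xs)))
    names(xs) <- sub("\\s.*$", "", names(xs))
  xs
}
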