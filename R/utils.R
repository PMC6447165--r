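# internal helpers shared across modules

.BASES <- c("A", "C", "G", "T")

# Evaluate expr with a temporarily seeded RNG; the caller's RNG state is
# restored afterwards so seeded helpers never perturb an ongoing simulation.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Coerce any supported sequence input to an uppercase character vector of
# single residues. Lowercase (soft-masked) residues are uppercased unless
# maskLowercase = TRUE, in which case they are turned into "N".
.asChars <- function(x, maskLowercase = FALSE) {
  if (is(x, "XString")) x <- as.character(x)
  if (is(x, "XStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence; got an XStringSet of length ",
           length(x))
    x <- as.character(x[[1L]])
  }
  if (!is.character(x))
    stop("unsupported sequence input of class ", class(x)[1L])
  if (length(x) == 1L && (nchar(x) > 1L || nchar(x) == 0L))
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (maskLowercase) x[x %in% c("a", "c", "g", "t")] <- "N"
  toupper(x)
}

# Integer codes 1..4 for A,C,G,T; NA for ambiguity codes (N, IUPAC, etc.).
.baseCode <- function(chars) match(chars, .BASES)

.seqIdOf <- function(x, id) {
  if (!is.null(id)) return(as.character(id))
  if (is(x, "XStringSet") && !is.null(names(x))) return(names(x)[1L])
  "seq"
}
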