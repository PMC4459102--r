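# Internal helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a stage seed from a run seed, kept below 2^31.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 1000003 + stage * 7919) %% 2147483647
}

phred_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)

qual_sum <- function(qual) {
  vapply(qual, function(x) sum(utf8ToInt(x)) - 33L * nchar(x), numeric(1),
         USE.NAMES = FALSE)
}

# Extract a (possibly origin-wrapping) fragment from a reference.
#' Decode a fragment interval from a reference genome
#'
#' Returns the forward-strand sequence of the 0-based half-open interval
#' `[start, end)`; on circular references the interval may wrap the origin
#' (`end` may exceed the reference length).
#'
#' @param ref a [ReferenceGenome-class].
#' @param start,end 0-based half-open coordinates (`end` may exceed the
#'   sequence length on circular references).
#' @return character sequence of length `end - start`.
#' @export
decodeFragment <- function(ref, start, end) {
  L <- length(ref@sequence)
  s <- as.character(ref@sequence)
  if (end <= L) return(substr(s, start + 1, end))
  if (!ref@circular) stop("fragment exceeds a linear reference")
  paste0(substr(s, start + 1, L), substr(s, 1, end - L))
}

reverseComplement_chr <- function(x) cpp_revcomp(x)

# Closed-form expected terminal substitution frequency for a DamageModel:
# the profiler's conditional C->T (5') / G->A (3') frequency at 1-based
# terminal position p. Under the double-strand protocol only half the reads
# are in the deaminated template's sense, giving the factor 1/2 and the 50%
# theoretical maximum.
#' Expected terminal misincorporation frequency under a damage model
#'
#' Analytic expectation of the profiled 5'-terminal C-to-T (equivalently
#' 3'-terminal G-to-A) conditional frequency at terminal position `p`.
#'
#' @param model a [DamageModel-class].
#' @param p 1-based distance from the read terminus.
#' @return expected conditional substitution frequency.
#' @export
expectedTerminalFrequency <- function(model, p = 1) {
  pss <- model@overhangDecay^p
  r <- pss * model@deltaSS + (1 - pss) * model@deltaDS
  if (model@bothStrands) r / 2 else r
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar", name))
}
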