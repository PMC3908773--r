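# Exhaustive enumeration of FCC self-avoiding walks: exact optima for
# short chains, the ground truth against which operators and the
# evolutionary search are validated.

#' Exact optimum by exhaustive enumeration
#'
#' Enumerates every self-avoiding walk of n residues on the FCC lattice by
#' depth-first search and returns the exact maximum HH-contact count for
#' the given sequence, together with the exact number of walks rooted at
#' the origin.  The walk count grows by roughly an order of magnitude per
#' residue, so enumeration is capped (default n = 7, about two million
#' walks); raise `cap` explicitly for one-off longer runs.
#'
#' With `symmetryReduction` (default) the first step is fixed to label 1
#' and the first non-collinear step is restricted to orbit representatives
#' under the twofold rotation about the first-step axis, shrinking the
#' search 24-fold; walk counts are multiplied back out exactly and the
#' optimum is unchanged, but any retained optimal walks are symmetry
#' representatives only.
#'
#' @param s HP sequence string.
#' @param symmetryReduction exploit lattice symmetry (default TRUE).
#' @param cap refuse chains longer than this (default 7).
#' @param keepOptimal retain optimal label sequences (up to `maxKeep`).
#' @param maxKeep cap on retained optimal walks (default 100).
#' @return An [EnumerationResult-class].
#' @examples
#' optimalContacts(enumerateOptimum("HPH"))    # 1: a 60-degree bend
#' optimalContacts(enumerateOptimum("HH"))     # 0: consecutive pair excluded
#' @export
enumerateOptimum <- function(s, symmetryReduction = TRUE, cap = 7L,
                             keepOptimal = FALSE, maxKeep = 100L) {
  isH <- .asHP(s)
  n <- length(isH)
  if (n > cap)
    stop("chain length ", n, " exceeds the enumeration cap (", cap,
         "); raise `cap` explicitly if you really want this")
  res <- .enumerate_optimum(isH, isTRUE(symmetryReduction),
                            isTRUE(keepOptimal), as.integer(maxKeep))
  new("EnumerationResult", n = n, walksCounted = res$walks,
      optimalContacts = as.integer(res$optimal),
      optimalLabels = as.list(res$optimal_labels))
}

#' @describeIn enumerateOptimum the exact optimal HH-contact count.
#' @param x an [EnumerationResult-class].
#' @export
setGeneric("optimalContacts", function(x) standardGeneric("optimalContacts"))

#' @rdname enumerateOptimum
#' @export
setMethod("optimalContacts", "EnumerationResult",
          function(x) x@optimalContacts)

#' @rdname enumerateOptimum
#' @param object an \code{EnumerationResult}.
#' @export
setMethod("show", "EnumerationResult", function(object) {
  cat(sprintf(paste0(
    "EnumerationResult: n = %d\n  walks counted: %.0f\n",
    "  optimal HH contacts: %d%s\n"),
    object@n, object@walksCounted, object@optimalContacts,
    if (length(object@optimalLabels))
      sprintf(" (%d optimal walks retained)", length(object@optimalLabels))
    else ""))
})
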