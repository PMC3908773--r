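# HP sequences, conformation encoding/decoding, self-avoidance and the
# HH-contact energy.

# validate an HP sequence string, return logical hydrophobicity vector
.asHP <- function(s) {
  if (length(s) != 1L || is.na(s) || !is.character(s))
    stop("HP sequence must be a single character string")
  res <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  if (length(res) < 1L) stop("HP sequence must have length >= 1")
  bad <- setdiff(unique(res), c("H", "P"))
  if (length(bad))
    stop("HP sequence may contain only H and P (found: ",
         paste(bad, collapse = ", "), ")")
  res == "H"
}

#' Build a conformation from its direction labels
#'
#' Decodes an absolute direction-label sequence into residue coordinates:
#' the first residue sits at the origin and residue i+1 is displaced from
#' residue i by the step vector of label i.  The result may or may not be
#' self-avoiding; see [isValidSAW()].
#'
#' @param labels integer vector of direction labels (1..12); may be empty
#'   for a single-residue chain.
#' @return A [Conformation-class].
#' @examples
#' conf <- Conformation(c(1, 1, 6, 4))
#' coordinates(conf)
#' @export
Conformation <- function(labels = integer()) {
  labels <- as.integer(labels)
  coords <- .decode_labels(labels)
  new("Conformation", labels = labels, coords = coords)
}

#' Encode coordinates as a conformation
#'
#' Inverse of decoding: converts a sequence of pairwise-consecutive
#' lattice-adjacent points into direction labels, translating the chain so
#' that the first residue sits at the origin.
#'
#' @param coords integer matrix (n x 3), consecutive rows lattice-adjacent.
#' @return A [Conformation-class].
#' @examples
#' encodeConformation(rbind(c(0, 0, 0), c(1, 1, 0)))   # single step FL
#' @export
encodeConformation <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  Conformation(.encode_coords(coords))
}

#' @describeIn Conformation the direction-label vector.
#' @param x,object a \code{Conformation}.
#' @export
setGeneric("directionLabels", function(x) standardGeneric("directionLabels"))

#' @rdname Conformation
#' @export
setMethod("directionLabels", "Conformation", function(x) x@labels)

#' @describeIn Conformation residue coordinates (n x 3 integer matrix).
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' @rdname Conformation
#' @export
setMethod("coordinates", "Conformation", function(x) x@coords)

#' @rdname Conformation
#' @export
setMethod("length", "Conformation", function(x) nrow(x@coords))

#' @rdname Conformation
#' @export
setMethod("show", "Conformation", function(object) {
  n <- length(object)
  cat(sprintf("Conformation of %d residues (%s)\n  labels: %s\n", n,
              if (isValidSAW(object)) "self-avoiding" else "NOT self-avoiding",
              if (n > 1L) paste(object@labels, collapse = ",") else "<none>"))
})

#' Self-avoidance test
#'
#' A conformation is valid exactly when its residues occupy pairwise
#' distinct lattice sites.
#'
#' @param conf a [Conformation-class].
#' @return Logical scalar.
#' @examples
#' isValidSAW(Conformation(c(1, 1)))   # TRUE
#' isValidSAW(Conformation(c(1, 4)))   # FALSE: returns to the origin
#' @export
isValidSAW <- function(conf) {
  stopifnot(is(conf, "Conformation"))
  .is_saw_labels(conf@labels)
}

#' HH contacts and free energy of a conformation
#'
#' `hhContacts()` counts residue pairs (i, j) with j >= i + 2 in which both
#' residues are hydrophobic and their lattice sites are adjacent --
#' topological neighbours, excluding pairs consecutive along the chain.
#' `foldEnergy()` is its negation: each HH contact contributes -1, so
#' minimizing the energy maximizes the contact count.
#'
#' @param s HP sequence string (over H/P) of the same length as the chain.
#' @param conf a valid (self-avoiding) [Conformation-class].
#' @return `hhContacts()` a non-negative integer; `foldEnergy()` a
#'   non-positive integer.
#' @examples
#' conf <- Conformation(c(1, 11))
#' hhContacts("HPH", conf)    # 1: residues 1 and 3 on adjacent sites
#' foldEnergy("HPH", conf)    # -1
#' @export
hhContacts <- function(s, conf) {
  isH <- .asHP(s)
  stopifnot(is(conf, "Conformation"))
  if (length(isH) != length(conf))
    stop("sequence length and chain length differ")
  if (!isValidSAW(conf))
    stop("conformation is not self-avoiding")
  .contacts_coords(conf@coords, isH)
}

#' @rdname hhContacts
#' @export
foldEnergy <- function(s, conf) -hhContacts(s, conf)

#' Random self-avoiding walk
#'
#' Generates a uniformly randomized depth-first self-avoiding walk: at each
#' extension the 12 directions are tried in random order and the walk
#' backtracks from dead ends, so a chain of any requested length is always
#' produced.  Draws from R's RNG; use [set.seed()] for reproducibility.
#'
#' @param n chain length (number of residues, >= 1).
#' @return A valid [Conformation-class] of n residues.
#' @examples
#' set.seed(1)
#' isValidSAW(randomSAW(25))   # TRUE
#' @export
randomSAW <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("chain length must be >= 1")
  Conformation(.random_saw(n))
}
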