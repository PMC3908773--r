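# Local-search operators: rotation-based one-point crossover, generalized
# pull move, and the K-site segment move with admissible pruning.

#' Rotation-based one-point crossover
#'
#' Classic one-point crossover on the absolute direction encoding, enhanced
#' by lattice rotation: the head labels (before the cut) come from
#' `parentA`, the tail labels from `parentB`, and in addition to the plain
#' concatenation every one of the 17 lattice rotations is applied to the
#' tail label sequence, giving up to 18 candidate children per oriented
#' parent pair.  Candidates violating self-avoidance are discarded, which
#' is the point of the rotations: they greatly raise the chance that some
#' child is a valid walk.  One call produces the oriented family
#' (head from `parentA`); call again with the parents swapped for the
#' mirror family.
#'
#' @param parentA,parentB valid [Conformation-class] objects of equal chain
#'   length n >= 3.
#' @param cut index of the last head label, in 1..n-2; drawn uniformly when
#'   `NULL` (uses R's RNG).
#' @param includeIdentity also emit the unrotated concatenation (default
#'   TRUE).
#' @return A list with `offspring` (list of valid [Conformation-class]),
#'   `rotationsUsed` (character ids, `"identity"` for the unrotated child),
#'   and `cutPoint`.
#' @examples
#' set.seed(1)
#' a <- randomSAW(10); b <- randomSAW(10)
#' res <- rotationCrossover(a, b)
#' all(vapply(res$offspring, isValidSAW, logical(1)))
#' @export
rotationCrossover <- function(parentA, parentB, cut = NULL,
                              includeIdentity = TRUE) {
  stopifnot(is(parentA, "Conformation"), is(parentB, "Conformation"))
  if (length(parentA) != length(parentB))
    stop("incompatible parents: chain lengths differ")
  n <- length(parentA)
  if (n < 3L) stop("crossover needs chains of length >= 3")
  if (is.null(cut)) cut <- sample.int(n - 2L, 1L)
  cut <- as.integer(cut)
  res <- .crossover_candidates(parentA@labels, parentB@labels, cut,
                               .rotationPermMatrix(), includeIdentity)
  ids <- c("identity", names(fccRotations()))
  list(offspring = lapply(res$offspring, Conformation),
       rotationsUsed = ids[res$rotation + 1L],
       cutPoint = res$cut)
}

#' Generalized pull move
#'
#' A pull move in which each pulled residue may relocate to any free common
#' neighbour of the new position of its already-moved chain neighbour and
#' its own current position (at most 4 candidate sites on the FCC lattice),
#' rather than only to the vacated site of the classic pull move.  One
#' attempt picks a start residue and a pull orientation uniformly, moves
#' the start residue to a random free neighbour of its predecessor (for a
#' chain end: of its single chain neighbour), and propagates until the
#' chain reconnects; if a pulled residue has no free candidate the attempt
#' aborts.  An attempt is accepted only when it strictly increases the
#' HH-contact count (strictly lowers the free energy); otherwise the input
#' conformation is kept.
#'
#' @param s HP sequence string.
#' @param conf a valid [Conformation-class] (n >= 2).
#' @param attempts number of successive attempts to run (default 1); each
#'   accepted attempt updates the conformation the next attempt starts
#'   from.
#' @return A list with `accepted` (TRUE if any attempt was accepted),
#'   `conformation` (the input object when nothing was accepted),
#'   `deltaContacts`, `contacts`, and `acceptedMoves`.
#' @examples
#' set.seed(1)
#' conf <- randomSAW(20)
#' out <- generalizedPullMove("HPHPPHHPHPPHPHHPPHPH", conf, attempts = 20)
#' out$deltaContacts >= 0
#' @export
generalizedPullMove <- function(s, conf, attempts = 1L) {
  isH <- .asHP(s)
  stopifnot(is(conf, "Conformation"))
  if (length(isH) != length(conf))
    stop("sequence length and chain length differ")
  if (!isValidSAW(conf)) stop("conformation is not self-avoiding")
  attempts <- as.integer(attempts)
  stopifnot(attempts >= 1L)
  before <- .contacts_coords(conf@coords, isH)
  res <- .gpm_sweep(conf@labels, isH, attempts)
  accepted <- res$accepted > 0L
  list(accepted = accepted,
       conformation = if (accepted) Conformation(res$labels) else conf,
       deltaContacts = res$contacts - before,
       contacts = res$contacts,
       acceptedMoves = res$accepted)
}

#' K-site segment move
#'
#' The mutation operator: relocates K consecutive residues between their
#' flanking anchor residues (one anchor when the segment touches a chain
#' end).  All self-avoiding replacement paths of exactly K free interior
#' sites connecting the anchors are enumerated depth-first, with a partial
#' path pruned as soon as the steps already taken plus an admissible lower
#' bound on the remaining steps to the far anchor exceed K + 1 (see
#' [stepLowerBound()]; the pruning never removes a feasible path).  The
#' candidate with the most HH contacts wins, ties broken by the first path
#' found in deterministic direction order 1..12; it replaces the input when
#' its contact count is at least the original's and it differs from the
#' original, so equal-energy sideways moves are allowed, injecting
#' diversity.
#'
#' @param s HP sequence string.
#' @param conf a valid [Conformation-class].
#' @param K segment length, 1 <= K <= n (default 3).  With K = n there is
#'   no anchor and the move degenerates to a no-op.
#' @param start first residue of the segment (1-based); drawn uniformly
#'   when `NULL` (uses R's RNG).
#' @param prune apply the lower-bound pruning (default TRUE; FALSE gives
#'   the plain exhaustive search, useful for validation).
#' @return A list with `accepted`, `conformation` (the input object when
#'   not accepted), `deltaContacts`, `candidates` (number of complete
#'   replacement paths examined), and `start`.
#' @examples
#' set.seed(1)
#' conf <- randomSAW(12)
#' out <- kSiteMove("PHHPPPPHPHPH", conf, K = 3)
#' out$deltaContacts >= 0
#' @export
kSiteMove <- function(s, conf, K = 3L, start = NULL, prune = TRUE) {
  isH <- .asHP(s)
  stopifnot(is(conf, "Conformation"))
  n <- length(conf)
  if (length(isH) != n) stop("sequence length and chain length differ")
  if (!isValidSAW(conf)) stop("conformation is not self-avoiding")
  K <- as.integer(K)
  if (is.na(K) || K < 1L || K > n)
    stop("invalid K: must satisfy 1 <= K <= chain length")
  start0 <- if (is.null(start)) -1L else as.integer(start) - 1L
  res <- .ksite_move(conf@labels, isH, K, start0, isTRUE(prune))
  list(accepted = res$accepted,
       conformation = if (res$accepted) Conformation(res$labels) else conf,
       deltaContacts = res$delta,
       candidates = res$candidates,
       start = res$start)
}

#' Lower bound on the FCC step distance
#'
#' An admissible lower bound on the number of lattice steps between two FCC
#' sites, used to prune the K-site path search: every step changes each
#' coordinate by at most 1 (so at least the Chebyshev distance is needed)
#' and reduces the L1 distance by at most 2 (so at least half of it,
#' rounded up).  The bound is 0 exactly when the points coincide and never
#' exceeds the true shortest-path length.
#'
#' @param p,q integer triples with even coordinate sum.
#' @return A non-negative integer.
#' @examples
#' stepLowerBound(c(0, 0, 0), c(1, 1, 0))   # 1
#' stepLowerBound(c(0, 0, 0), c(4, 0, 0))   # 4
#' @export
stepLowerBound <- function(p, q) {
  .step_bound(.checkPoint(p), .checkPoint(q, "second point"))
}
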