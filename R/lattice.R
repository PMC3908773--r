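# FCC lattice geometry: the 12 step directions, adjacency, common
# neighbours, and the 17 rotations usable as direction-label permutations.

.DIRECTIONS <- local({
  m <- rbind(FL = c( 1,  1,  0), FR = c( 1, -1,  0),
             FU = c(-1,  1,  0), FD = c(-1, -1,  0),
             BL = c( 1,  0,  1), BR = c( 1,  0, -1),
             BU = c(-1,  0,  1), BD = c(-1,  0, -1),
             LU = c( 0,  1,  1), LD = c( 0,  1, -1),
             RU = c( 0, -1,  1), RD = c( 0, -1, -1))
  storage.mode(m) <- "integer"
  m
})

#' Direction vectors of the FCC lattice
#'
#' The 12 unit steps of the face-centered-cubic lattice, each with two
#' nonzero components of magnitude 1.  Labels 1--12 correspond to the fold
#' directions FL, FR, FU, FD, BL, BR, BU, BD, LU, LD, RU, RD; opposite
#' directions carry labels \code{c(4,3,2,1,8,7,6,5,12,11,10,9)}.
#'
#' @return An integer 12 x 3 matrix; row l is the step vector of label l.
#' @examples
#' directionVectors()[1, ]            # FL = (+1, +1, 0)
#' directionVector(6)                 # BR = (+1, 0, -1)
#' @export
directionVectors <- function() .DIRECTIONS

#' @rdname directionVectors
#' @param label integer direction label in 1..12.
#' @export
directionVector <- function(label) {
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label < 1L || label > 12L)
    stop("invalid direction label: must be a single integer in 1..12")
  .DIRECTIONS[label, ]
}

.checkPoint <- function(p, what = "point") {
  p <- as.integer(p)
  if (length(p) != 3L || anyNA(p))
    stop(what, " must be an integer triple")
  if (sum(p) %% 2L != 0L)
    stop(what, " is not an FCC lattice site (coordinate sum must be even)")
  p
}

#' Lattice neighbourhood and adjacency
#'
#' `fccNeighbors()` lists the 12 sites adjacent to a lattice point;
#' `areAdjacent()` tests adjacency (all coordinate differences at most 1 in
#' magnitude and summing to 2); `commonNeighbors()` returns the sites
#' adjacent to both of two points -- exactly 4 of them whenever the points
#' are themselves adjacent, which is the candidate set of one
#' generalized-pull-move propagation step.
#'
#' @param p,q integer triples with even coordinate sum.
#' @return `fccNeighbors()` and `commonNeighbors()` an integer matrix with
#'   one site per row; `areAdjacent()` a logical scalar.
#' @examples
#' nrow(fccNeighbors(c(0, 0, 0)))                 # 12
#' areAdjacent(c(0, 0, 0), c(1, 1, 0))            # TRUE
#' commonNeighbors(c(0, 0, 0), c(1, 1, 0))        # 4 sites
#' @export
fccNeighbors <- function(p) {
  p <- .checkPoint(p)
  sweep(.DIRECTIONS, 2L, -p)
}

#' @rdname fccNeighbors
#' @export
areAdjacent <- function(p, q) {
  d <- abs(.checkPoint(p) - .checkPoint(q))
  all(d <= 1L) && sum(d) == 2L
}

#' @rdname fccNeighbors
#' @export
commonNeighbors <- function(p, q) {
  p <- .checkPoint(p); q <- .checkPoint(q, "second point")
  if (all(p == q)) stop("points must differ")
  np <- sweep(.DIRECTIONS, 2L, -p)
  d <- abs(sweep(np, 2L, q))
  np[rowSums(d) == 2L & apply(d <= 1L, 1L, all), , drop = FALSE]
}

.rotationMatrix <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  t <- angle * pi / 180
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3L, 3L, byrow = TRUE)
  m <- round(cos(t) * diag(3) + sin(t) * K + (1 - cos(t)) * (k %*% t(k)))
  storage.mode(m) <- "integer"
  m
}

.labelPermutation <- function(m) {
  w <- .DIRECTIONS %*% t(m)
  perm <- match(
    paste(w[, 1], w[, 2], w[, 3]),
    paste(.DIRECTIONS[, 1], .DIRECTIONS[, 2], .DIRECTIONS[, 3]))
  if (anyNA(perm)) stop("matrix does not permute the FCC direction set")
  as.integer(perm)
}

.rotationCache <- new.env(parent = emptyenv())

#' The 17 FCC lattice rotations
#'
#' Enumerates, in a fixed deterministic order, the 17 proper rotations of
#' the FCC neighbourhood used by rotation-based crossover: 9 square-based
#' rotations (fourfold axes x, y, z at 90, 180, 270 degrees, each of which
#' rotates three parallel squares of neighbours synchronously) and 8
#' triangle-hexagon-based rotations (the four threefold body-diagonal axes
#' at 120 and 240 degrees, rotating two triangles and a hexagon).  Each
#' rotation is returned with its integer matrix and the induced permutation
#' of the direction labels 1--12.  The identity is not among the 17; it is
#' available separately via `identityRotation()`.
#'
#' @return A named list of 17 [LatticeRotation-class] objects.
#' @examples
#' length(fccRotations())                    # 17
#' fccRotations()[["sq-z-90"]]@permutation
#' @export
fccRotations <- function() {
  if (!is.null(.rotationCache$rotations)) return(.rotationCache$rotations)
  sq <- list(x = c(1L, 0L, 0L), y = c(0L, 1L, 0L), z = c(0L, 0L, 1L))
  th <- list(ppp = c(1L, 1L, 1L), ppm = c(1L, 1L, -1L),
             pmp = c(1L, -1L, 1L), mpp = c(-1L, 1L, 1L))
  out <- list()
  for (ax in names(sq)) for (ang in c(90, 180, 270)) {
    m <- .rotationMatrix(sq[[ax]], ang)
    id <- sprintf("sq-%s-%d", ax, ang)
    out[[id]] <- new("LatticeRotation", id = id, family = "square",
                     axis = sq[[ax]], angle = ang, matrix = m,
                     permutation = .labelPermutation(m))
  }
  for (ax in names(th)) for (ang in c(120, 240)) {
    m <- .rotationMatrix(th[[ax]], ang)
    id <- sprintf("th-%s-%d", ax, ang)
    out[[id]] <- new("LatticeRotation", id = id, family = "triangle-hexagon",
                     axis = th[[ax]], angle = ang, matrix = m,
                     permutation = .labelPermutation(m))
  }
  .rotationCache$rotations <- out
  out
}

#' @rdname fccRotations
#' @export
identityRotation <- function() {
  m <- diag(3L); storage.mode(m) <- "integer"
  new("LatticeRotation", id = "identity", family = "identity",
      axis = c(0L, 0L, 0L), angle = 0, matrix = m, permutation = 1:12)
}

# 17 x 12 permutation matrix handed to the compiled crossover kernel
.rotationPermMatrix <- function() {
  if (is.null(.rotationCache$permMatrix))
    .rotationCache$permMatrix <-
      do.call(rbind, lapply(fccRotations(), slot, "permutation"))
  .rotationCache$permMatrix
}

#' Apply a rotation to a direction-label sequence
#'
#' Rotating a whole conformation about a lattice point is equivalent to
#' applying the rotation's label permutation elementwise to its absolute
#' direction encoding; this is how crossover rotates the exchanged tail.
#'
#' @param rotation a [LatticeRotation-class] (from [fccRotations()] or
#'   [identityRotation()]) or a length-12 integer permutation.
#' @param labels integer vector of direction labels in 1..12.
#' @return The permuted label vector.
#' @examples
#' z90 <- fccRotations()[["sq-z-90"]]
#' rotateLabels(z90, c(1, 1, 6, 4))          # 3 3 10 2
#' @export
rotateLabels <- function(rotation, labels) {
  perm <- if (is(rotation, "LatticeRotation")) rotation@permutation
          else as.integer(rotation)
  if (length(perm) != 12L || anyNA(perm) || !setequal(perm, 1:12))
    stop("rotation must supply a permutation of 1..12")
  labels <- as.integer(labels)
  if (length(labels) && (anyNA(labels) || any(labels < 1L | labels > 12L)))
    stop("invalid direction label: labels must be integers in 1..12")
  perm[labels]
}

#' Tabulate the lattice rotations
#'
#' A flat data frame of the 17 rotations (id, family, axis, angle, matrix
#' rows, label permutation), convenient for export as JSON and for
#' cross-implementation comparisons.
#'
#' @return A data frame with one row per rotation.
#' @export
rotationsTable <- function() {
  rots <- fccRotations()
  do.call(rbind, lapply(rots, function(r) {
    data.frame(id = r@id, family = r@family,
               axis = paste(r@axis, collapse = ","),
               angle = r@angle,
               matrix = paste(apply(r@matrix, 1L, paste, collapse = " "),
                              collapse = "; "),
               permutation = paste(r@permutation, collapse = ","),
               row.names = NULL)
  }))
}

#' @describeIn fccRotations compact display of a rotation.
#' @param object a \code{LatticeRotation}.
#' @export
setMethod("show", "LatticeRotation", function(object) {
  cat(sprintf("LatticeRotation %s [%s], axis (%s), %g deg\n  permutation: %s\n",
              object@id, object@family, paste(object@axis, collapse = ","),
              object@angle, paste(object@permutation, collapse = " ")))
})
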