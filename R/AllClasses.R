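#' Lattice conformation of a residue chain
#'
#' A chain embedding on the FCC lattice, stored as the absolute
#' direction-label sequence (integers 1--12, one per chain bond) together
#' with the derived residue coordinates, anchored with the first residue at
#' the origin.  A conformation object may violate self-avoidance (operators
#' generate and then filter such candidates); use [isValidSAW()] to test it.
#'
#' @slot labels integer vector of length n-1, values in 1..12.
#' @slot coords integer matrix (n x 3) of residue positions; row 1 is the
#'   origin and consecutive rows are lattice-adjacent.
#' @seealso [Conformation()], [encodeConformation()], [isValidSAW()],
#'   [hhContacts()]
#' @export
setClass("Conformation",
         slots = c(labels = "integer", coords = "matrix"))

setValidity("Conformation", function(object) {
  lab <- object@labels
  if (length(lab) && (anyNA(lab) || any(lab < 1L | lab > 12L)))
    return("labels must be integers in 1..12")
  if (nrow(object@coords) != length(lab) + 1L || ncol(object@coords) != 3L)
    return("coords must be an (n x 3) matrix with n = length(labels) + 1")
  if (any(object@coords[1L, ] != 0L))
    return("first residue must sit at the origin")
  if (any((rowSums(object@coords) %% 2L) != 0L))
    return("all lattice points must have even coordinate sum")
  TRUE
})

#' One proper rotation of the FCC lattice
#'
#' A rotation of the FCC point group that maps the 12 step directions onto
#' themselves, stored both as an integer orthogonal matrix (determinant +1)
#' and as the permutation it induces on the direction labels 1--12.
#' Rotations come in two families: \code{"square"} (fourfold axes x, y, z;
#' angles 90/180/270) and \code{"triangle-hexagon"} (threefold body-diagonal
#' axes; angles 120/240), 9 + 8 = 17 in total; the identity is represented
#' separately with family \code{"identity"}.
#'
#' @slot id character identifier, e.g. \code{"sq-z-90"}.
#' @slot family \code{"square"}, \code{"triangle-hexagon"} or
#'   \code{"identity"}.
#' @slot axis integer rotation axis, e.g. \code{c(0, 0, 1)}.
#' @slot angle rotation angle in degrees.
#' @slot matrix 3x3 integer rotation matrix.
#' @slot permutation integer vector p of length 12 with p[l] the label whose
#'   vector equals \code{matrix \%*\% directionVector(l)}.
#' @seealso [fccRotations()], [rotateLabels()]
#' @export
setClass("LatticeRotation",
         slots = c(id = "character", family = "character", axis = "integer",
                   angle = "numeric", matrix = "matrix",
                   permutation = "integer"))

#' Evolutionary-search configuration
#'
#' Hyperparameters of the evolutionary algorithm.  Defaults follow the
#' short-benchmark settings: population 10, crossover rate 0.85, mutation
#' rate 0.4, K = 3, 30 iterations.
#'
#' @slot populationSize number of individuals kept after truncation (>= 2).
#' @slot crossoverRate probability that a selected parent pair undergoes
#'   rotation-based crossover (otherwise the parents are cloned).
#' @slot mutationRate probability that an offspring undergoes a K-site move.
#' @slot iterations number of generations.
#' @slot K segment length of the K-site mutation move.
#' @slot tournamentSize tournament size for parent selection (fixed at 2).
#' @slot gpmAttempts generalized-pull-move attempts per new offspring;
#'   \code{NA} means four attempts per residue.
#' @slot seed RNG seed used by [runEA()].
#' @slot restarts number of independent restarts; the best result over all
#'   restarts is reported.
#' @seealso [eaConfig()], [runEA()]
#' @export
setClass("EAConfig",
         slots = c(populationSize = "integer", crossoverRate = "numeric",
                   mutationRate = "numeric", iterations = "integer",
                   K = "integer", tournamentSize = "integer",
                   gpmAttempts = "integer", seed = "integer",
                   restarts = "integer"))

setValidity("EAConfig", function(object) {
  if (object@populationSize < 2L) return("populationSize must be >= 2")
  if (object@crossoverRate < 0 || object@crossoverRate > 1)
    return("crossoverRate must be in [0, 1]")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    return("mutationRate must be in [0, 1]")
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@K < 1L) return("K must be >= 1")
  if (object@tournamentSize != 2L) return("tournamentSize must be 2")
  if (object@restarts < 1L) return("restarts must be >= 1")
  TRUE
})

#' Result of an evolutionary-search run
#'
#' @slot sequence the HP sequence searched.
#' @slot best the best [Conformation-class] found over all restarts.
#' @slot bestContacts its HH-contact count.
#' @slot bestPerGeneration list (one integer vector per restart) of the best
#'   contact count in the population after each generation; non-decreasing
#'   within a restart under elitist truncation.
#' @slot restartBests best contact count attained by each restart.
#' @slot config the [EAConfig-class] used.
#' @slot seed the seed the run started from.
#' @seealso [runEA()], [foldHP()]
#' @export
setClass("FoldResult",
         slots = c(sequence = "character", best = "Conformation",
                   bestContacts = "integer", bestPerGeneration = "list",
                   restartBests = "integer", config = "EAConfig",
                   seed = "integer"))

#' Result of exhaustive conformation enumeration
#'
#' @slot n chain length.
#' @slot walksCounted total number of self-avoiding walks of n residues
#'   rooted at the origin (exact; stored as double).
#' @slot optimalContacts maximum HH-contact count over all walks.
#' @slot optimalLabels list of label sequences attaining the optimum (only
#'   when requested; representatives only under symmetry reduction).
#' @seealso [enumerateOptimum()]
#' @export
setClass("EnumerationResult",
         slots = c(n = "integer", walksCounted = "numeric",
                   optimalContacts = "integer", optimalLabels = "list"))
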