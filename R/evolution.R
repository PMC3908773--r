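# The evolutionary driver: initialization, tournament parent selection,
# rotation-based crossover, generalized-pull-move local search, K-site
# mutation, elitist (mu + lambda) truncation, fixed-iteration termination.
#
# A population is a plain list of individuals, each a list with elements
# `labels` (direction labels) and `contacts` (cached HH-contact count),
# kept sorted by contacts in decreasing order.

#' Evolutionary-search configuration
#'
#' Builds an [EAConfig-class].  The defaults are the short-benchmark
#' settings (population 10, crossover rate 0.85, mutation rate 0.4, K = 3,
#' 30 iterations); longer chains warrant more iterations (100--150) or a
#' larger population (40 for the 48-residue benchmark set).
#'
#' @param populationSize individuals kept after truncation (>= 2).
#' @param crossoverRate per-pair crossover probability in [0, 1].
#' @param mutationRate per-offspring K-site-move probability in [0, 1].
#' @param iterations number of generations (>= 1).
#' @param K K-site segment length (default 3).
#' @param gpmAttempts generalized-pull-move attempts applied to each new
#'   offspring; `NA` (default) means four per residue.  Most attempts
#'   abort or are rejected, so this is the budget that makes the pull-move
#'   hill climb the workhorse of the search.
#' @param seed RNG seed for [runEA()].
#' @param restarts independent restarts; the best over all is kept.
#' @return An [EAConfig-class].
#' @examples
#' eaConfig(populationSize = 10, iterations = 30, seed = 7)
#' @export
eaConfig <- function(populationSize = 10L, crossoverRate = 0.85,
                     mutationRate = 0.4, iterations = 30L, K = 3L,
                     gpmAttempts = NA_integer_, seed = 1L, restarts = 1L) {
  new("EAConfig",
      populationSize = as.integer(populationSize),
      crossoverRate = as.numeric(crossoverRate),
      mutationRate = as.numeric(mutationRate),
      iterations = as.integer(iterations),
      K = as.integer(K), tournamentSize = 2L,
      gpmAttempts = as.integer(gpmAttempts),
      seed = as.integer(seed), restarts = as.integer(restarts))
}

.newIndividual <- function(labels, isH) {
  list(labels = labels,
       contacts = .contacts_coords(.decode_labels(labels), isH))
}

#' Initial population of random walks
#'
#' Generates `populationSize` random self-avoiding walks (randomized
#' depth-first search with backtracking), evaluates their HH-contact
#' counts, and returns them sorted fittest-first.  This sorted population
#' is the basis of the subsequent reproduction steps.
#'
#' @param s HP sequence string.
#' @param cfg an [EAConfig-class].
#' @return A list of individuals (`labels`, `contacts`), sorted by
#'   `contacts` decreasing.
#' @examples
#' set.seed(1)
#' pop <- initializePopulation("HPHPPHHPHPPHPHHPPHPH", eaConfig())
#' vapply(pop, `[[`, integer(1), "contacts")
#' @export
initializePopulation <- function(s, cfg) {
  isH <- .asHP(s)
  stopifnot(is(cfg, "EAConfig"))
  n <- length(isH)
  pop <- lapply(seq_len(cfg@populationSize),
                function(i) .newIndividual(.random_saw(n), isH))
  pop[order(vapply(pop, `[[`, integer(1), "contacts"),
            decreasing = TRUE)]
}

#' Binary tournament parent selection
#'
#' Draws two individuals uniformly with replacement and returns the one
#' with more HH contacts; exact ties are resolved uniformly at random.
#'
#' @param population non-empty list of individuals.
#' @return One individual.
#' @export
tournamentSelect <- function(population) {
  if (!length(population)) stop("population is empty")
  idx <- sample.int(length(population), 2L, replace = TRUE)
  a <- population[[idx[1L]]]; b <- population[[idx[2L]]]
  if (a$contacts > b$contacts) a
  else if (b$contacts > a$contacts) b
  else if (runif(1L) < 0.5) a else b
}

#' Elitist truncation survivor selection
#'
#' (mu + lambda) truncation: parents and offspring are pooled, stably
#' sorted by contact count, and the top `populationSize` survive, so the
#' best individual can never be lost.
#'
#' @param parents,offspring lists of individuals.
#' @param cfg an [EAConfig-class].
#' @return The surviving population, sorted fittest-first.
#' @export
survivorSelection <- function(parents, offspring, cfg) {
  stopifnot(is(cfg, "EAConfig"))
  pool <- c(parents, offspring)
  if (!length(pool)) stop("empty selection pool")
  pool <- pool[order(vapply(pool, `[[`, integer(1), "contacts"),
                     decreasing = TRUE)]
  pool[seq_len(min(cfg@populationSize, length(pool)))]
}

# one restart of the generational loop; returns list(best, trajectory)
.runGeneration <- function(isH, cfg, gpmAttempts, permMatrix, verbose) {
  n <- length(isH)
  pop <- lapply(seq_len(cfg@populationSize),
                function(i) .newIndividual(.random_saw(n), isH))
  pop <- pop[order(vapply(pop, `[[`, integer(1), "contacts"),
                   decreasing = TRUE)]
  trajectory <- integer(cfg@iterations)
  npairs <- ceiling(cfg@populationSize / 2)
  for (gen in seq_len(cfg@iterations)) {
    offspring <- vector("list", 0L)
    for (pair in seq_len(npairs)) {
      p1 <- tournamentSelect(pop)
      p2 <- tournamentSelect(pop)
      kids <- list()
      if (n >= 3L && runif(1L) <= cfg@crossoverRate) {
        cut1 <- sample.int(n - 2L, 1L)
        r1 <- .crossover_candidates(p1$labels, p2$labels, cut1,
                                    permMatrix, TRUE)
        cut2 <- sample.int(n - 2L, 1L)
        r2 <- .crossover_candidates(p2$labels, p1$labels, cut2,
                                    permMatrix, TRUE)
        kids <- c(r1$offspring, r2$offspring)
      } else {
        kids <- list(p1$labels, p2$labels)
      }
      offspring <- c(offspring, kids)
    }
    evaluated <- vector("list", length(offspring))
    for (i in seq_along(offspring)) {
      lab <- offspring[[i]]
      res <- .gpm_sweep(lab, isH, gpmAttempts)
      lab <- res$labels
      contacts <- res$contacts
      if (runif(1L) <= cfg@mutationRate) {
        ks <- .ksite_move(lab, isH, min(cfg@K, n), -1L, TRUE)
        if (ks$accepted) {
          lab <- ks$labels
          contacts <- contacts + ks$delta
        }
      }
      evaluated[[i]] <- list(labels = lab, contacts = contacts)
    }
    pop <- survivorSelection(pop, evaluated, cfg)
    trajectory[gen] <- pop[[1L]]$contacts
    if (verbose) {
      meanc <- mean(vapply(pop, `[[`, integer(1), "contacts"))
      message(sprintf("generation %d: best %d, mean %.2f",
                      gen, trajectory[gen], meanc))
    }
  }
  list(best = pop[[1L]], trajectory = trajectory)
}

#' Run the evolutionary search
#'
#' The full generational loop: per generation, `populationSize / 2` parent
#' pairs are drawn by binary tournament; with probability `crossoverRate`
#' each pair undergoes rotation-based crossover in both orientations and
#' contributes every valid child (otherwise the two parents are cloned);
#' every new offspring receives a sweep of generalized pull moves (one
#' attempt per residue by default) and, with probability `mutationRate`, a
#' K-site move; parents and offspring then compete under elitist
#' truncation.  After `iterations` generations the best conformation in
#' the population is returned.  With `restarts > 1` the whole search is
#' repeated independently and the best result over all restarts reported.
#' The run is fully reproducible from `cfg@seed`.
#'
#' @param s HP sequence string (length >= 3).
#' @param cfg an [EAConfig-class].
#' @param stopAt optional contact count at which remaining restarts are
#'   skipped (useful when the optimum is known); the reported best is
#'   still whatever the completed restarts attained.
#' @param verbose log per-generation best/mean contact counts to stderr.
#' @return A [FoldResult-class].
#' @examples
#' res <- runEA("PHHPPPPHPHPH", eaConfig(iterations = 10, seed = 3))
#' bestContacts(res)
#' @export
runEA <- function(s, cfg = eaConfig(), stopAt = NA_integer_,
                  verbose = FALSE) {
  isH <- .asHP(s)
  if (length(isH) < 3L) stop("need a sequence of length >= 3")
  stopifnot(is(cfg, "EAConfig"))
  validObject(cfg)
  n <- length(isH)
  gpmAttempts <- if (is.na(cfg@gpmAttempts)) 4L * n else cfg@gpmAttempts
  permMatrix <- .rotationPermMatrix()
  set.seed(cfg@seed)
  trajectories <- vector("list", 0L)
  restartBests <- integer(0L)
  best <- NULL
  for (r in seq_len(cfg@restarts)) {
    run <- .runGeneration(isH, cfg, gpmAttempts, permMatrix, verbose)
    trajectories[[r]] <- run$trajectory
    restartBests[r] <- run$best$contacts
    if (is.null(best) || run$best$contacts > best$contacts) best <- run$best
    if (!is.na(stopAt) && best$contacts >= stopAt) break
  }
  new("FoldResult", sequence = paste(ifelse(isH, "H", "P"), collapse = ""),
      best = Conformation(best$labels),
      bestContacts = best$contacts,
      bestPerGeneration = trajectories,
      restartBests = restartBests,
      config = cfg, seed = cfg@seed)
}

#' Fold an HP sequence
#'
#' Convenience wrapper around [runEA()] taking the hyperparameters
#' directly.
#'
#' @param s HP sequence string.
#' @param ... passed to [eaConfig()].
#' @param stopAt,verbose passed to [runEA()].
#' @return A [FoldResult-class].
#' @examples
#' res <- foldHP("PHHPPPPHPHPH", iterations = 10, seed = 3)
#' @export
foldHP <- function(s, ..., stopAt = NA_integer_, verbose = FALSE) {
  runEA(s, eaConfig(...), stopAt = stopAt, verbose = verbose)
}

#' @describeIn runEA best conformation of a result.
#' @param x a [FoldResult-class].
#' @export
setGeneric("bestConformation", function(x) standardGeneric("bestConformation"))

#' @rdname runEA
#' @export
setMethod("bestConformation", "FoldResult", function(x) x@best)

#' @describeIn runEA best HH-contact count of a result.
#' @export
setGeneric("bestContacts", function(x) standardGeneric("bestContacts"))

#' @rdname runEA
#' @export
setMethod("bestContacts", "FoldResult", function(x) x@bestContacts)

#' @describeIn runEA mean of the per-restart best contact counts.
#' @export
setGeneric("meanContacts", function(x) standardGeneric("meanContacts"))

#' @rdname runEA
#' @export
setMethod("meanContacts", "FoldResult", function(x) mean(x@restartBests))

#' @rdname runEA
#' @param object a \code{FoldResult}.
#' @export
setMethod("show", "FoldResult", function(object) {
  cat(sprintf(paste0(
    "FoldResult: %d-residue HP chain\n",
    "  best HH contacts: %d (energy %d)\n",
    "  restarts: %d (per-restart bests: %s; mean %.2f)\n",
    "  seed: %d\n"),
    nchar(object@sequence), object@bestContacts, -object@bestContacts,
    length(object@restartBests),
    paste(object@restartBests, collapse = ", "),
    mean(object@restartBests), object@seed))
})
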