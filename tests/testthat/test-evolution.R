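test_that("configuration validation catches out-of-range settings", {
  expect_s4_class(eaConfig(), "EAConfig")
  expect_error(eaConfig(populationSize = 1), "populationSize")
  expect_error(eaConfig(crossoverRate = 1.2), "crossoverRate")
  expect_error(eaConfig(mutationRate = -0.1), "mutationRate")
  expect_error(eaConfig(iterations = 0), "iterations")
  expect_error(eaConfig(restarts = 0), "restarts")
})

test_that("the initial population is valid, sorted and seeded", {
  cfg <- eaConfig(populationSize = 12)
  s <- "HPHPPHHPHPPHPHHPPHPH"
  set.seed(51)
  pop <- initializePopulation(s, cfg)
  expect_length(pop, 12L)
  contacts <- vapply(pop, `[[`, integer(1), "contacts")
  expect_true(all(diff(contacts) <= 0L))
  for (ind in pop) {
    conf <- Conformation(ind$labels)
    expect_true(isValidSAW(conf))
    expect_identical(length(conf), nchar(s))
    expect_identical(hhContacts(s, conf), ind$contacts)  # cache coherence
  }
  set.seed(51)
  pop2 <- initializePopulation(s, cfg)
  expect_identical(pop, pop2)
})

test_that("binary tournaments favour the fitter individual", {
  two <- list(list(labels = rep(1L, 4), contacts = 5L),
              list(labels = rep(2L, 4), contacts = 3L))
  # drawing with replacement from {5, 3}: the 5 wins unless 3 is drawn
  # twice, i.e. with probability 3/4
  set.seed(52)
  wins <- mean(vapply(1:2000, function(i) tournamentSelect(two)$contacts,
                      integer(1)) == 5L)
  expect_gt(wins, 0.70)
  expect_lt(wins, 0.80)
  one <- two[1L]
  expect_identical(tournamentSelect(one)$contacts, 5L)
  expect_error(tournamentSelect(list()), "empty")
  # frequency check against the closed-form selection probabilities: with
  # distinct fitnesses and ranks i = 1..N (best first), P(rank i wins a
  # binary tournament with replacement) = (2(N - i) + 1) / N^2
  pop <- lapply(5:1, function(cc) list(labels = rep(1L, 3),
                                       contacts = as.integer(cc)))
  set.seed(53)
  draws <- vapply(1:4000, function(i) tournamentSelect(pop)$contacts,
                  integer(1))
  freq <- tabulate(draws, 5L) / 4000
  expected <- (2 * (5 - (5:1)) + 1) / 25       # indexed by contacts 1..5
  expect_true(all(abs(freq - expected) < 0.05))
  expect_gt(freq[5L], freq[1L])                # fittest beats least fit
})

test_that("survivor selection is elitist top-N truncation", {
  cfg <- eaConfig(populationSize = 4)
  mk <- function(cc, tag) list(labels = rep(tag, 3L), contacts = cc)
  parents <- list(mk(6L, 1L), mk(2L, 1L))
  offspring <- list(mk(5L, 2L), mk(7L, 2L), mk(1L, 2L), mk(5L, 3L))
  surv <- survivorSelection(parents, offspring, cfg)
  expect_length(surv, 4L)
  cc <- vapply(surv, `[[`, integer(1), "contacts")
  expect_identical(cc, c(7L, 6L, 5L, 5L))
  expect_gte(max(cc), max(vapply(parents, `[[`, integer(1), "contacts")))
  # stable: among the two contact-5 entries the offspring listed first wins
  expect_identical(surv[[3L]]$labels, rep(2L, 3L))
  expect_error(survivorSelection(list(), list(), cfg), "empty")
})

test_that("runs are reproducible and the best-so-far trajectory is monotone", {
  s <- "PHHPPPPHPHPH"
  cfg <- eaConfig(populationSize = 10, iterations = 15, seed = 54,
                  restarts = 2)
  a <- runEA(s, cfg)
  b <- runEA(s, cfg)
  expect_identical(directionLabels(bestConformation(a)),
                   directionLabels(bestConformation(b)))
  expect_identical(a@bestPerGeneration, b@bestPerGeneration)
  expect_identical(a@restartBests, b@restartBests)
  for (tr in a@bestPerGeneration) expect_true(all(diff(tr) >= 0L))
  expect_identical(bestContacts(a), max(a@restartBests))
  expect_lte(meanContacts(a), bestContacts(a))
  expect_identical(hhContacts(s, bestConformation(a)), bestContacts(a))
  expect_error(runEA("HX", eaConfig()), "only H and P")
})

test_that("searches never beat the enumeration optimum and find it on short chains", {
  set.seed(55)
  for (i in 1:6) {
    n <- sample(5:7, 1L)
    s <- randomHP(n)
    opt <- optimalContacts(enumerateOptimum(s))
    r <- runEA(s, eaConfig(populationSize = 10, iterations = 15,
                           seed = 100 + i))
    expect_lte(bestContacts(r), opt)
    # degenerate configuration: pure parallel pull-move hill climbing
    r0 <- runEA(s, eaConfig(populationSize = 6, crossoverRate = 0,
                            mutationRate = 0, iterations = 10,
                            seed = 200 + i))
    expect_lte(bestContacts(r0), opt)
  }
  # an easy instance is solved to optimality
  opt <- optimalContacts(enumerateOptimum("HPHPH"))
  r <- runEA("HPHPH", eaConfig(populationSize = 10, iterations = 20,
                               seed = 56, restarts = 2))
  expect_identical(bestContacts(r), opt)
})

test_that("the convenience wrapper and accessors behave", {
  r <- foldHP("HPHPHHPH", iterations = 8, seed = 57)
  expect_s4_class(r, "FoldResult")
  expect_identical(r@sequence, "HPHPHHPH")
  expect_s4_class(bestConformation(r), "Conformation")
  expect_output(show(r), "best HH contacts")
})
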