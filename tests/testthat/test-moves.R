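test_that("crossover exchanges tails under lattice rotation", {
  set.seed(41)
  # cloning: identical parents with the identity rotation give the parent
  p <- randomSAW(12)
  res <- rotationCrossover(p, p, cut = 5)
  idx <- which(res$rotationsUsed == "identity")
  expect_length(idx, 1L)
  expect_identical(directionLabels(res$offspring[[idx]]),
                   directionLabels(p))
  expect_identical(res$cutPoint, 5L)
  # offspring structure: head from parent A, tail a rotated parent-B tail
  rots <- fccRotations()
  for (i in 1:40) {
    n <- sample(6:20, 1L)
    a <- randomSAW(n); b <- randomSAW(n)
    cut <- sample.int(n - 2L, 1L)
    res <- rotationCrossover(a, b, cut = cut)
    expect_lte(length(res$offspring), 18L)
    tailB <- directionLabels(b)[(cut + 1L):(n - 1L)]
    for (k in seq_along(res$offspring)) {
      kid <- res$offspring[[k]]
      expect_true(isValidSAW(kid))
      expect_identical(length(kid), n)
      lab <- directionLabels(kid)
      expect_identical(lab[seq_len(cut)], directionLabels(a)[seq_len(cut)])
      rid <- res$rotationsUsed[[k]]
      expTail <- if (rid == "identity") tailB
                 else rotateLabels(rots[[rid]], tailB)
      expect_identical(lab[(cut + 1L):(n - 1L)], expTail)
    }
  }
  expect_error(rotationCrossover(randomSAW(5), randomSAW(6)),
               "incompatible parents")
})

test_that("crossover candidate tails under the z-axis rotations match the worked example", {
  # a parent pair whose tail is the tabulated (1,1,6,4) label sequence
  head <- c(9L, 9L)
  a <- Conformation(c(head, 2L, 2L, 2L, 2L))
  b <- Conformation(c(head, 1L, 1L, 6L, 4L))
  res <- rotationCrossover(a, b, cut = 2)
  tails <- vapply(res$offspring, function(k)
    paste(directionLabels(k)[3:6], collapse = ","), "")
  names(tails) <- res$rotationsUsed
  expect_identical(unname(tails["identity"]), "1,1,6,4")
  expect_identical(unname(tails["sq-z-90"]), "3,3,10,2")
  expect_identical(unname(tails["sq-z-180"]), "4,4,8,1")
  expect_identical(unname(tails["sq-z-270"]), "2,2,12,3")
})

test_that("generalized pull moves preserve the chain and only accept strict gains", {
  set.seed(43)
  for (i in 1:150) {
    n <- sample(5:20, 1L)
    s <- randomHP(n)
    conf <- randomSAW(n)
    before <- hhContacts(s, conf)
    out <- generalizedPullMove(s, conf)
    expect_identical(length(out$conformation), n)
    expect_true(isValidSAW(out$conformation))
    if (out$accepted) {
      expect_gte(out$deltaContacts, 1L)
      expect_identical(hhContacts(s, out$conformation),
                       before + out$deltaContacts)
    } else {
      expect_identical(directionLabels(out$conformation),
                       directionLabels(conf))
      expect_identical(out$deltaContacts, 0L)
    }
  }
})

test_that("pull-move sweeps are seeded and monotone in contacts", {
  s <- "HPHHPHHPPHHPHHPH"
  set.seed(44)
  conf <- randomSAW(nchar(s))
  base <- hhContacts(s, conf)
  set.seed(45)
  a <- generalizedPullMove(s, conf, attempts = 60)
  set.seed(45)
  b <- generalizedPullMove(s, conf, attempts = 60)
  expect_identical(directionLabels(a$conformation),
                   directionLabels(b$conformation))
  expect_gte(a$contacts, base)
  expect_identical(a$contacts, base + a$deltaContacts)
})

test_that("the classic pull target stays among the generalized candidates", {
  # when the already-moved residue sits adjacent to its old site, that old
  # site is a common neighbour of the new site and the next residue, i.e.
  # the classic pull move is a special case of the generalized one
  set.seed(46)
  V <- directionVectors()
  for (i in 1:50) {
    A <- 2L * c(sample(-3:3, 1L), sample(-3:3, 1L), sample(-3:3, 1L))
    if (sum(A) %% 2L != 0L) A[1] <- A[1] + 1L
    C <- A + V[sample.int(12L, 1L), ]          # next residue, chain bond A-C
    for (k in 1:12) {
      B <- A + V[k, ]                          # candidate new site near A
      if (all(B == C) || !areAdjacent(B, C)) next
      cn <- apply(commonNeighbors(B, C), 1L, paste, collapse = ",")
      expect_true(paste(A, collapse = ",") %in% cn)
    }
  }
})

test_that("K-site moves keep anchors and the rest of the chain fixed", {
  set.seed(47)
  for (i in 1:80) {
    n <- sample(6:16, 1L)
    s <- randomHP(n)
    conf <- randomSAW(n)
    K <- sample(1:4, 1L)
    start <- sample.int(n - K + 1L, 1L)
    before <- hhContacts(s, conf)
    out <- kSiteMove(s, conf, K = K, start = start)
    expect_true(isValidSAW(out$conformation))
    expect_identical(length(out$conformation), n)
    expect_gte(out$deltaContacts, 0L)
    expect_identical(hhContacts(s, out$conformation),
                     before + out$deltaContacts)
    # residues outside the segment are unchanged (conformations are
    # compared up to translation: re-anchor both on the first kept residue)
    keep <- setdiff(seq_len(n), start:(start + K - 1L))
    co1 <- coordinates(out$conformation); co0 <- coordinates(conf)
    co1 <- sweep(co1, 2L, co1[keep[1L], ]); co0 <- sweep(co0, 2L, co0[keep[1L], ])
    expect_identical(co1[keep, , drop = FALSE], co0[keep, , drop = FALSE])
    if (!out$accepted)
      expect_identical(directionLabels(out$conformation),
                       directionLabels(conf))
  }
  expect_error(kSiteMove("HPH", Conformation(c(1, 11)), K = 5), "invalid K")
  expect_identical(formals(kSiteMove)$K, 3L)   # default segment length
})

test_that("lower-bound pruning never changes the chosen K-site candidate", {
  set.seed(48)
  for (i in 1:60) {
    n <- sample(6:12, 1L)
    s <- randomHP(n)
    conf <- randomSAW(n)
    K <- sample(2:4, 1L)
    start <- sample.int(n - K + 1L, 1L)
    pruned <- kSiteMove(s, conf, K = K, start = start, prune = TRUE)
    full <- kSiteMove(s, conf, K = K, start = start, prune = FALSE)
    expect_identical(pruned$accepted, full$accepted)
    expect_identical(directionLabels(pruned$conformation),
                     directionLabels(full$conformation))
    expect_identical(pruned$deltaContacts, full$deltaContacts)
    # pruning can only discard incompletable paths
    expect_lte(pruned$candidates, full$candidates)
  }
})

test_that("the step lower bound is admissible and exact at short range", {
  expect_identical(stepLowerBound(c(0, 0, 0), c(0, 0, 0)), 0L)
  expect_identical(stepLowerBound(c(0, 0, 0), c(1, 1, 0)), 1L)
  expect_identical(stepLowerBound(c(0, 0, 0), c(4, 0, 0)), 4L)
  dist <- oracleStepDistances(6L)   # covers all even sites in [-4, 4]^3
  pts <- as.matrix(expand.grid(x = -4:4, y = -4:4, z = -4:4))
  pts <- pts[rowSums(pts) %% 2L == 0L, , drop = FALSE]
  for (k in seq_len(nrow(pts))) {
    q <- pts[k, ]
    d <- get(paste(q, collapse = ","), envir = dist)
    b <- stepLowerBound(c(0L, 0L, 0L), q)
    expect_lte(b, d)
    expect_gte(b, (d > 0L) * 1L)
  }
})
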