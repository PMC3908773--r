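test_that("direction vectors form the FCC step set", {
  V <- directionVectors()
  expect_identical(dim(V), c(12L, 3L))
  # two nonzero components of magnitude 1 each
  expect_true(all(rowSums(abs(V)) == 2L))
  expect_true(all(abs(V) <= 1L))
  expect_identical(nrow(unique(V)), 12L)
  # printed assignments: FL, FR, BL; BR resolved to (+1, 0, -1)
  expect_identical(unname(V[1L, ]), c(1L, 1L, 0L))
  expect_identical(unname(V[2L, ]), c(1L, -1L, 0L))
  expect_identical(unname(V[5L, ]), c(1L, 0L, 1L))
  expect_identical(unname(directionVector(6L)), c(1L, 0L, -1L))
  # closure under negation with the expected opposite-label pairing
  for (l in 1:12)
    expect_identical(unname(V[oppositeLabels[l], ]), unname(-V[l, ]))
  # steps preserve the even-coordinate-sum parity
  expect_true(all(rowSums(V) %% 2L == 0L))
  expect_error(directionVector(0), "invalid direction label")
  expect_error(directionVector(13), "invalid direction label")
})

test_that("every lattice point has 12 neighbours, matching the adjacency rule", {
  nb <- fccNeighbors(c(0, 0, 0))
  expect_identical(nrow(nb), 12L)
  expect_identical(nrow(unique(nb)), 12L)
  expect_true(all(rowSums(nb) %% 2L == 0L))
  # agrees with a brute-force scan of the 3x3x3 cube
  o <- oracleNeighbors(c(0L, 0L, 0L))
  expect_setequal(unname(apply(nb, 1L, paste, collapse = ",")),
                  apply(o, 1L, paste, collapse = ","))
  # translation invariance and symmetry of the relation
  p <- c(4L, -2L, 6L)
  expect_equal(unname(fccNeighbors(p)), unname(sweep(nb, 2L, -p)))
  for (k in seq_len(nrow(nb)))
    expect_true(areAdjacent(nb[k, ], c(0, 0, 0)))
  expect_error(fccNeighbors(c(1, 0, 0)), "even")
})

test_that("adjacency follows the componentwise rule", {
  expect_true(areAdjacent(c(0, 0, 0), c(1, 1, 0)))
  expect_false(areAdjacent(c(0, 0, 0), c(2, 0, 0)))
  expect_false(areAdjacent(c(0, 0, 0), c(0, 0, 0)))
  expect_false(areAdjacent(c(0, 0, 0), c(1, 1, 2)))
})

test_that("adjacent sites share exactly four common neighbours", {
  cn <- commonNeighbors(c(0, 0, 0), c(1, 1, 0))
  expect_setequal(unname(apply(cn, 1L, paste, collapse = ",")),
                  c("1,0,1", "1,0,-1", "0,1,1", "0,1,-1"))
  V <- directionVectors()
  for (l in 1:12) {
    q <- V[l, ]
    cn <- commonNeighbors(c(0L, 0L, 0L), q)
    expect_identical(nrow(cn), 4L)
    # brute-force intersection of the two neighbourhoods
    a <- apply(oracleNeighbors(c(0L, 0L, 0L)), 1L, paste, collapse = ",")
    b <- apply(oracleNeighbors(q), 1L, paste, collapse = ",")
    expect_setequal(unname(apply(cn, 1L, paste, collapse = ",")), intersect(a, b))
    # symmetry
    cn2 <- commonNeighbors(q, c(0L, 0L, 0L))
    expect_setequal(unname(apply(cn2, 1L, paste, collapse = ",")),
                    apply(cn, 1L, paste, collapse = ","))
  }
  expect_error(commonNeighbors(c(0, 0, 0), c(0, 0, 0)), "differ")
})

test_that("the rotation set is the 9 + 8 fourfold/threefold family", {
  rots <- fccRotations()
  expect_length(rots, 17L)
  fam <- vapply(rots, slot, "", "family")
  expect_identical(sum(fam == "square"), 9L)
  expect_identical(sum(fam == "triangle-hexagon"), 8L)
  V <- directionVectors()
  vkey <- apply(V, 1L, paste, collapse = ",")
  perms <- t(vapply(rots, slot, integer(12), "permutation"))
  for (r in rots) {
    m <- r@matrix
    expect_identical(unname(t(m) %*% m), unname(diag(3L)))
    expect_equal(det(m), 1)
    # the matrix permutes the direction set and matches the permutation
    w <- V %*% t(m)
    expect_setequal(unname(apply(w, 1L, paste, collapse = ",")), unname(vkey))
    expect_identical(match(apply(w, 1L, paste, collapse = ","), vkey),
                     r@permutation)
    expect_setequal(r@permutation, 1:12)
    # equivariance under negation: rotating the opposite direction gives
    # the opposite of the rotated direction
    expect_identical(r@permutation[oppositeLabels],
                     oppositeLabels[r@permutation])
    expect_false(all(r@permutation == 1:12))
  }
  expect_identical(nrow(unique(perms)), 17L)
})

test_that("rotations match the independent cube-group enumeration", {
  # of the 24 proper rotations of the cube, exactly the 9 fourfold-axis and
  # 8 threefold-axis ones are used; edge 180s and the identity are not
  oracle <- oracleCubeRotations()
  cls <- vapply(oracle, `[[`, "", "class")
  expect_identical(sum(cls == "fourfold"), 9L)
  expect_identical(sum(cls == "threefold"), 8L)
  expect_identical(sum(cls == "edge"), 6L)
  expect_identical(sum(cls == "identity"), 1L)
  wanted <- vapply(oracle[cls %in% c("fourfold", "threefold")],
                   function(o) paste(o$matrix, collapse = ","), "")
  got <- vapply(fccRotations(), function(r) paste(r@matrix, collapse = ","),
                "")
  expect_setequal(unname(got), wanted)
})

test_that("label permutations reproduce the tabulated square-based example", {
  rots <- fccRotations()
  tup <- c(1L, 1L, 6L, 4L)
  expect_identical(rotateLabels(rots[["sq-z-90"]], tup), c(3L, 3L, 10L, 2L))
  expect_identical(rotateLabels(rots[["sq-z-180"]], tup), c(4L, 4L, 8L, 1L))
  expect_identical(rotateLabels(rots[["sq-z-270"]], tup), c(2L, 2L, 12L, 3L))
  expect_identical(rotateLabels(identityRotation(), tup), tup)
  # composition: the 90-degree permutation applied twice is the 180 one
  p90 <- rots[["sq-z-90"]]@permutation
  expect_identical(p90[p90], rots[["sq-z-180"]]@permutation)
  expect_error(rotateLabels(rots[[1L]], c(1, 13)), "invalid direction label")
  expect_error(rotateLabels(1:11, c(1, 2)), "permutation")
})

test_that("the rotation table exports one row per rotation", {
  tab <- rotationsTable()
  expect_identical(nrow(tab), 17L)
  expect_identical(sort(unique(tab$angle)), c(90, 120, 180, 240, 270))
})
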