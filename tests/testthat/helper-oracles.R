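# Independent oracles used to validate the package's geometry and
# counting routines: straight re-statements of the definitions, kept free
# of any package internals.

# the 12 FCC offsets straight from the adjacency definition
oracleOffsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) == 2L & apply(abs(g) <= 1L, 1L, all), , drop = FALSE]
}

oracleNeighbors <- function(p) sweep(oracleOffsets(), 2L, -as.integer(p))

oracleAdjacent <- function(p, q) {
  d <- abs(as.integer(p) - as.integer(q))
  all(d <= 1L) && sum(d) == 2L
}

# quadratic HH-contact count from the definition
oracleContacts <- function(s, coords) {
  isH <- strsplit(s, "")[[1]] == "H"
  n <- nrow(coords)
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i + 1L) next
    if (isH[i] && isH[j] && oracleAdjacent(coords[i, ], coords[j, ]))
      cnt <- cnt + 1L
  }
  cnt
}

# breadth-first shortest step count from the origin on the FCC graph
oracleStepDistances <- function(radius) {
  offs <- oracleOffsets()
  key <- function(p) paste(p, collapse = ",")
  dist <- new.env(parent = emptyenv())
  assign(key(c(0L, 0L, 0L)), 0L, envir = dist)
  frontier <- list(c(0L, 0L, 0L))
  for (r in seq_len(radius)) {
    nxt <- list()
    for (p in frontier) for (k in seq_len(nrow(offs))) {
      q <- p + offs[k, ]
      kq <- key(q)
      if (!exists(kq, envir = dist)) {
        assign(kq, r, envir = dist)
        nxt[[length(nxt) + 1L]] <- q
      }
    }
    frontier <- nxt
  }
  dist
}

# all 24 proper signed-permutation rotations of the cube, classified by
# axis type: fourfold face axes, threefold body diagonals, twofold edge
# axes, or the identity
oracleCubeRotations <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in seq_len(nrow(perms))) for (sx in c(-1, 1))
    for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
      m <- matrix(0L, 3, 3)
      signs <- c(sx, sy, sz)
      for (r in 1:3) m[r, perms[p, r]] <- signs[r]
      if (round(det(m)) != 1) next
      tr <- sum(diag(m))
      cls <- if (tr == 3) "identity"
      else if (tr == 0) "threefold"                  # 120/240 degrees
      else if (tr == 1) "fourfold"                   # 90/270 degrees
      else if (tr == -1) {
        # 180 degrees: face axis iff the +1 eigenvector is a coordinate axis
        ax <- which(diag(m) == 1)
        if (length(ax) == 1L) "fourfold" else "edge"
      } else stop("unexpected trace")
      out[[length(out) + 1L]] <- list(matrix = m, class = cls)
    }
  out
}

randomHP <- function(n) paste(sample(c("H", "P"), n, replace = TRUE),
                              collapse = "")

# label of the opposite direction, from negation closure
oppositeLabels <- c(4L, 3L, 2L, 1L, 8L, 7L, 6L, 5L, 12L, 11L, 10L, 9L)
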