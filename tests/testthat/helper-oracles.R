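# Independent oracles and fixture helpers for the test suite.

# Quaternion (Horn) superposition RMSD: the optimal proper-rotation residual
# comes from the largest eigenvalue of the 4x4 key matrix -- a wholly
# different route than the package's SVD-based Kabsch implementation.
oracle_rmsd <- function(P, Q) {
  P <- sweep(P, 2L, colMeans(P)); Q <- sweep(Q, 2L, colMeans(Q))
  S <- crossprod(P, Q)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4L, 4L, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P))
}

oracle_rmsd_structures <- function(a, b, heavy_only = TRUE) {
  sel <- if (heavy_only) which(a$symbols != "H") else seq_along(a$symbols)
  oracle_rmsd(a$coords[sel, , drop = FALSE], b$coords[sel, , drop = FALSE])
}

# Direct transcription of the sphere-exclusion clustering procedure, kept
# separate from the package implementation (same tie rule: lowest index).
oracle_butina <- function(M, threshold) {
  n <- nrow(M)
  assigned <- rep(FALSE, n)
  cluster <- integer(n)
  id <- 0L
  repeat {
    pool <- which(!assigned)
    if (length(pool) == 0L) break
    nb <- lapply(pool, function(a) pool[M[a, pool] < threshold])
    sizes <- lengths(nb)
    pick <- which(sizes == max(sizes))[1L]
    id <- id + 1L
    cluster[nb[[pick]]] <- id
    assigned[nb[[pick]]] <- TRUE
  }
  cluster
}

# Exhaustive predecessor-check deduplication (kept in plain index arithmetic,
# no ensemble machinery): member k survives iff its RMSD to every surviving
# lower-energy member is >= threshold.
oracle_prune_rmsd <- function(structures, threshold, heavy_only = TRUE) {
  keep <- integer(0)
  for (k in seq_along(structures)) {
    ok <- TRUE
    for (m in keep) {
      if (oracle_rmsd_structures(structures[[k]], structures[[m]],
                                 heavy_only) < threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, k)
  }
  keep
}

random_rigid_transform <- function(coords) {
  A <- matrix(stats::rnorm(9), 3L)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2L, stats::rnorm(3, sd = 5), `+`)
}

# Random synthetic ensemble around a base geometry: a mix of fresh jittered
# conformers, exact duplicates of earlier members (rigid-transformed), and
# near-duplicates, with random energies. Returns an energy-sorted ensemble.
random_test_ensemble <- function(n_members, base, jitter_sd = 0.35) {
  structures <- list()
  for (k in seq_len(n_members)) {
    roll <- stats::runif(1)
    if (k > 1L && roll < 0.25) {            # exact duplicate, rigid-moved
      src <- structures[[sample(k - 1L, 1L)]]
      s <- src; s$coords <- random_rigid_transform(src$coords)
    } else if (k > 1L && roll < 0.45) {     # near-duplicate
      src <- structures[[sample(k - 1L, 1L)]]
      s <- src
      s$coords <- src$coords + matrix(stats::rnorm(length(src$coords), sd = 0.02),
                                      ncol = 3L)
    } else {
      s <- base
      s$coords <- base$coords + matrix(stats::rnorm(length(base$coords),
                                                    sd = jitter_sd), ncol = 3L)
    }
    structures[[k]] <- s
  }
  ts_ensemble(structures, stats::runif(n_members, 0, 10), reference = base)
}

expect_partition_equal <- function(a, b) {
  # same partition up to label renaming
  expect_equal(length(a), length(b))
  ra <- match(a, unique(a)); rb <- match(b, unique(b))
  expect_identical(ra, rb)
}
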