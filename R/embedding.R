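# Constrained distance-geometry embedding.
#
# The constraint specification fixes (a) the Cartesian positions of
# reaction-center atoms and (b) every pairwise distance within the frozen-atom
# set, both measured from the input structure. Conformers are generated by
# classic distance geometry: a distance-bounds matrix is assembled (frozen
# pairs near-exact, bonded/geminal pairs from the input geometry, everything
# else between a van-der-Waals floor and the bond-path length), bounds are
# triangle-smoothed, random distances are drawn, embedded into 3D by
# metric-matrix eigendecomposition, and refined against the bounds. Each
# candidate is superposed onto the input frozen core, checked for frozen-pair
# fidelity, reaction-center placement and core chirality (mirror images are
# rejected -- distance geometry is chirality-blind); failures are skipped and
# counted.

#' Build the constraint specification
#'
#' @param structure the input TS guess (a [ts_structure]).
#' @param frozen integer vector of frozen atom indices (from [frozen_atoms()]);
#'   must contain `reaction_center`.
#' @param reaction_center integer vector of reaction-center indices (may be
#'   empty, in which case only distances are fixed).
#' @param tolerance symmetric slack (Angstrom) on each fixed distance
#'   (default 0.01: near-exact fixing).
#' @return object of class `constraint_spec` with `fixed_positions` (named
#'   matrix), `fixed_distances` (data frame `i`, `j`, `target`), `tolerance`,
#'   `frozen`, `reaction_center`.
#' @export
build_constraints <- function(structure, frozen, reaction_center,
                              tolerance = 0.01) {
  stopifnot(inherits(structure, "ts_structure"), tolerance >= 0)
  frozen <- sort(unique(as.integer(frozen)))
  reaction_center <- validate_reaction_center(reaction_center, structure,
                                              allow_empty = TRUE)
  if (!all(reaction_center %in% frozen)) {
    stop("frozen set must contain every reaction-center atom")
  }
  if (length(frozen) && (min(frozen) < 1L || max(frozen) > n_atoms(structure))) {
    stop("frozen indices out of range")
  }
  fp <- structure$coords[reaction_center, , drop = FALSE]
  rownames(fp) <- as.character(reaction_center)
  fi <- integer(0); fj <- integer(0); ft <- numeric(0)
  if (length(frozen) > 1L) {
    for (a in seq_len(length(frozen) - 1L)) for (b in seq((a + 1L), length(frozen))) {
      i <- frozen[a]; j <- frozen[b]
      d <- sqrt(sum((structure$coords[i, ] - structure$coords[j, ])^2))
      if (d < .MIN_ATOM_DIST) {
        stop("frozen atoms ", i, " and ", j, " are only ",
             sprintf("%.3f", d), " Angstrom apart")
      }
      fi <- c(fi, i); fj <- c(fj, j); ft <- c(ft, d)
    }
  }
  structure(
    list(fixed_positions = fp,
         fixed_distances = data.frame(i = fi, j = fj, target = ft),
         tolerance = tolerance, frozen = frozen,
         reaction_center = reaction_center),
    class = "constraint_spec"
  )
}

#' @export
print.constraint_spec <- function(x, ...) {
  cat("<constraint_spec> ", nrow(x$fixed_positions), " fixed position(s), ",
      nrow(x$fixed_distances), " fixed distance(s), tolerance ",
      x$tolerance, " A\n", sep = "")
  invisible(x)
}

#' Serialise a constraint spec to YAML (debugging aid)
#'
#' @param constraints a `constraint_spec`.
#' @return single YAML string.
#' @export
constraints_as_yaml <- function(constraints) {
  yaml::as.yaml(list(
    tolerance = constraints$tolerance,
    reaction_center = as.integer(constraints$reaction_center),
    frozen = as.integer(constraints$frozen),
    fixed_positions = apply(constraints$fixed_positions, 1L, as.numeric,
                            simplify = FALSE),
    fixed_distances = unname(apply(constraints$fixed_distances, 1L, as.numeric,
                                   simplify = FALSE))
  ))
}

#' Generation configuration
#'
#' @param conf_factor positive integer multiplier on the rotatable-bond count
#'   (default 30); more initially generated conformers discover more rotamer
#'   clusters at higher cost.
#' @param seed integer RNG seed (`NULL` for the session RNG state).
#' @param max_embed_attempts cap on total embedding attempts; default 10x the
#'   requested conformer count (set at generation time when `NULL`).
#' @return object of class `generation_config`.
#' @export
generation_config <- function(conf_factor = 30L, seed = NULL,
                              max_embed_attempts = NULL) {
  conf_factor <- as.integer(conf_factor)
  if (is.na(conf_factor) || conf_factor < 1L) stop("conf_factor must be >= 1")
  structure(list(conf_factor = conf_factor, seed = seed,
                 max_embed_attempts = max_embed_attempts),
            class = "generation_config")
}

#' Number of initial conformers to embed
#'
#' `conf_factor x max(1, number of free rotatable bonds)`: the knob scales
#' with molecular flexibility and never drops below `conf_factor` even for
#' rigid systems.
#'
#' @param config a [generation_config].
#' @param topology a `ts_topology`.
#' @param frozen frozen atom indices (bonds fully inside the frozen core are
#'   not free rotors).
#' @return integer count; deterministic.
#' @export
n_initial_conformers <- function(config, topology, frozen = integer(0)) {
  stopifnot(inherits(config, "generation_config"))
  config$conf_factor * max(1L, n_rotatable_bonds(topology, frozen))
}

# Distance-bounds matrix: lower/upper n x n matrices.
.bounds_matrix <- function(topology, constraints) {
  st <- topology$structure
  n <- n_atoms(st)
  r <- covalent_radius(st$symbols)
  D <- dist_matrix(st$coords)
  g <- topology_graph(topology)
  bd <- topology$bonds
  blen <- sqrt(rowSums((st$coords[bd$i, , drop = FALSE] -
                          st$coords[bd$j, , drop = FALSE])^2))
  gd <- igraph::distances(g, weights = blen)   # bond-path length
  hop <- igraph::distances(g)                  # bond-path hop count

  lower <- outer(r, r, `+`) + 0.5              # vdW-ish floor
  upper <- matrix(0, n, n)
  span <- max(gd[is.finite(gd)], 3) + 6        # disconnected fragments roam
  upper[] <- ifelse(is.finite(gd), pmax(gd, D * 0), span)
  upper[!is.finite(gd)] <- span
  # 1-2 and 1-3 distances are taken from the input geometry (bond lengths and
  # angles are not sampled; torsions are the sampled degrees of freedom)
  b12 <- hop == 1; b13 <- hop == 2
  lower[b12] <- D[b12] - 0.02; upper[b12] <- D[b12] + 0.02
  lower[b13] <- D[b13] - 0.06; upper[b13] <- D[b13] + 0.06
  b14 <- hop == 3
  lower[b14] <- pmax(lower[b14] - 0.3, 1.0)
  # frozen pairs: near-exact
  fd <- constraints$fixed_distances
  tol <- constraints$tolerance
  for (m in seq_len(nrow(fd))) {
    lower[fd$i[m], fd$j[m]] <- lower[fd$j[m], fd$i[m]] <- fd$target[m] - tol
    upper[fd$i[m], fd$j[m]] <- upper[fd$j[m], fd$i[m]] <- fd$target[m] + tol
  }
  diag(lower) <- diag(upper) <- 0
  bad <- lower > upper
  lower[bad] <- upper[bad] - 0.01
  # triangle smoothing (Floyd-Warshall on upper; lower lifted against upper)
  for (k in seq_len(n)) {
    via <- outer(upper[, k], upper[k, ], `+`)
    upper <- pmin(upper, via)
    lift <- pmax(outer(lower[, k], -upper[k, ], `+`),
                 outer(-upper[, k], lower[k, ], `+`))
    lower <- pmax(lower, lift)
  }
  lower <- pmin(lower, upper)
  list(lower = lower, upper = upper)
}

# Embed one random distance matrix into 3D (classical MDS) and polish against
# the bounds by gradient minimisation of the violation function.
.embed_once <- function(bounds, w_frozen_pairs) {
  n <- nrow(bounds$lower)
  Ds <- matrix(stats::runif(n * n, bounds$lower, bounds$upper), n, n)
  Ds <- (Ds + t(Ds)) / 2
  diag(Ds) <- 0
  D2 <- Ds^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  eg <- eigen(B, symmetric = TRUE)
  ev <- pmax(eg$values[1:3], 0)
  X <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(ev), 3L)

  lower <- bounds$lower; upper <- bounds$upper
  W <- matrix(1, n, n); W[w_frozen_pairs] <- 25
  pen <- function(x) {
    coords <- matrix(x, ncol = 3L, byrow = TRUE)
    D <- dist_matrix(coords)
    v <- pmax(lower - D, 0) + pmax(D - upper, 0)
    sum(W * v^2) / 2
  }
  grad <- function(x) {
    coords <- matrix(x, ncol = 3L, byrow = TRUE)
    D <- dist_matrix(coords)
    over <- pmax(D - upper, 0); under <- pmax(lower - D, 0)
    coef <- W * (over - under)          # dE/dd per pair (symmetric)
    Dsafe <- D; diag(Dsafe) <- 1
    coef <- coef / Dsafe
    g <- matrix(0, n, 3L)
    for (d in 1:3) {
      diff <- outer(coords[, d], coords[, d], `-`)
      g[, d] <- rowSums(coef * diff)
    }
    as.numeric(t(g))
  }
  opt <- stats::optim(as.numeric(t(X)), pen, grad, method = "L-BFGS-B",
                      control = list(maxit = 400, factr = 1e3))
  matrix(opt$par, ncol = 3L, byrow = TRUE)
}

# Pick the most non-planar frozen quadruple for the chirality check, or NULL
# for planar/ambiguous cores (which then skip the check).
.chirality_probe <- function(coords, frozen) {
  if (length(frozen) < 4L) return(NULL)
  combos <- utils::combn(frozen, 4L)
  vols <- apply(combos, 2L, function(q) signed_volume(coords[q, , drop = FALSE]))
  best <- which.max(abs(vols))
  if (abs(vols[best]) < 0.1) return(NULL)   # cubic Angstrom; essentially planar
  list(quad = combos[, best], sign = sign(vols[best]))
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample initial TS conformers by constrained embedding
#'
#' Repeatedly samples random distances from the constrained bounds matrix and
#' embeds them into 3D. Every accepted conformer satisfies each fixed distance
#' within `tolerance + 0.1` Angstrom, superposes its reaction-center atoms
#' within 0.2 Angstrom of their fixed positions, and preserves the chirality
#' of the frozen core (mirror-image embeddings are rejected). Failed attempts
#' are skipped and counted; with a fixed seed the output is bit-reproducible.
#'
#' @param topology a `ts_topology`.
#' @param constraints a `constraint_spec` built from the same structure.
#' @param config a [generation_config].
#' @return an unranked [ts_ensemble] (energies `NA`) with attribute
#'   `"embedding_stats"` (requested, attempts, failures). Errors if no
#'   embedding succeeds within `max_embed_attempts`.
#' @export
embed_conformers <- function(topology, constraints, config = generation_config()) {
  stopifnot(inherits(topology, "ts_topology"),
            inherits(constraints, "constraint_spec"),
            inherits(config, "generation_config"))
  st <- topology$structure
  n <- n_atoms(st)
  wanted <- n_initial_conformers(config, topology, constraints$frozen)
  max_attempts <- config$max_embed_attempts
  if (is.null(max_attempts)) max_attempts <- 10L * wanted
  bounds <- .bounds_matrix(topology, constraints)
  fd <- constraints$fixed_distances
  wmask <- matrix(FALSE, n, n)
  if (nrow(fd)) {
    wmask[cbind(fd$i, fd$j)] <- TRUE
    wmask[cbind(fd$j, fd$i)] <- TRUE
  }
  frozen <- constraints$frozen
  rc <- constraints$reaction_center
  probe <- .chirality_probe(st$coords, frozen)
  slack <- constraints$tolerance + 0.1

  .with_seed(config$seed, {
    kept <- list(); attempts <- 0L; failures <- 0L
    while (length(kept) < wanted && attempts < max_attempts) {
      attempts <- attempts + 1L
      X <- .embed_once(bounds, wmask)
      # superpose onto the input frozen core (>=3 atoms) or translate
      if (length(frozen) >= 3L) {
        fit <- kabsch_fit(X[frozen, , drop = FALSE],
                          st$coords[frozen, , drop = FALSE])
        X <- apply_fit(X, fit)
      } else if (length(frozen) > 0L) {
        X <- sweep(X, 2L, colMeans(st$coords[frozen, , drop = FALSE]) -
                     colMeans(X[frozen, , drop = FALSE]), `+`)
      }
      ok <- TRUE
      if (nrow(fd)) {
        d <- sqrt(rowSums((X[fd$i, , drop = FALSE] - X[fd$j, , drop = FALSE])^2))
        if (any(abs(d - fd$target) > slack)) ok <- FALSE
      }
      if (ok && !is.null(probe)) {
        v <- signed_volume(X[probe$quad, , drop = FALSE])
        if (sign(v) != probe$sign) ok <- FALSE   # mirror image: reject
      }
      if (ok && length(rc) > 0L) {
        dev <- sqrt(rowSums((X[rc, , drop = FALSE] -
                               constraints$fixed_positions)^2))
        if (any(dev > 0.2)) ok <- FALSE
      }
      if (ok) {
        s <- st
        s$coords <- X
        s$comment <- ""
        kept <- c(kept, list(s))
      } else failures <- failures + 1L
    }
    if (length(kept) == 0L) {
      stop("no successful embedding in ", attempts, " attempts (",
           failures, " rejected); constraints may be unsatisfiable")
    }
    ens <- ts_ensemble(kept, labels = sprintf("embed_%03d", seq_along(kept)),
                       reference = st)
    attr(ens, "embedding_stats") <- list(requested = wanted,
                                         attempts = attempts,
                                         failures = failures)
    ens
  })
}
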