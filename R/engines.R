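# Energy engines.
#
# An engine is a pure-evaluation object: identical coordinates always give
# identical energies. The built-in classical force field comes in two
# parameter tiers sharing one functional form (harmonic bonds, harmonic-cosine
# angles, 3-fold torsions, Lennard-Jones nonbonded):
#   * the organic tier accepts only elements a typical organic force field is
#     parameterised for (H B C N O F P S Cl Br I) and plays the role of the
#     primary MMFF94-class engine;
#   * the universal tier accepts every element in the radius table and plays
#     the role of the UFF-class fallback, where unrecognised atom types get
#     default parameters.
# A mock engine (fixed smooth pair potential, no topology needed) lets the
# whole pipeline run without any chemistry; an external adapter shows how a
# quantum-chemistry backend (e.g. a tight-binding binary) plugs in.

#' Construct an energy engine
#'
#' Engine adapter contract: `energy(coords, ctx)` maps an n x 3 coordinate
#' matrix (Angstrom) to a single finite energy in kcal/mol and must be a pure
#' function of the coordinates; `setup(topology)` builds the per-system
#' context `ctx` once (bonded terms, charges); `gradient(coords, ctx)` is
#' optional (a central-difference fallback is used when absent);
#' `accepts(symbols)` gates element coverage. Any quantum-chemistry backend
#' can be wrapped this way (convert hartree to kcal/mol inside the adapter).
#'
#' @param name engine identifier.
#' @param energy function(coords, ctx) -> kcal/mol.
#' @param setup function(topology) -> ctx, or `NULL`.
#' @param gradient function(coords, ctx) -> n x 3 matrix, or `NULL`.
#' @param accepts function(symbols) -> logical(1); default accepts all.
#' @param minimizes whether [minimize_conformer()] may optimise with it.
#' @param fixes_atoms_exactly whether frozen atoms are fixed exactly (true for
#'   all built-in engines: frozen coordinates are simply never variables).
#' @return an object of class `energy_engine`.
#' @export
energy_engine <- function(name, energy, setup = NULL, gradient = NULL,
                          accepts = function(symbols) TRUE,
                          minimizes = TRUE, fixes_atoms_exactly = TRUE) {
  structure(
    list(name = name, energy = energy, setup = setup, gradient = gradient,
         accepts = accepts, minimizes = minimizes,
         fixes_atoms_exactly = fixes_atoms_exactly),
    class = "energy_engine"
  )
}

#' @export
print.energy_engine <- function(x, ...) {
  cat("<energy_engine> ", x$name, "\n", sep = ""); invisible(x)
}

engine_setup <- function(engine, topology) {
  if (is.null(engine$setup)) NULL else engine$setup(topology)
}

engine_gradient <- function(engine, coords, ctx, h = 1e-5) {
  if (!is.null(engine$gradient)) return(engine$gradient(coords, ctx))
  g <- matrix(0, nrow(coords), 3L)
  for (a in seq_len(nrow(coords))) for (d in 1:3) {
    cp <- coords; cm <- coords
    cp[a, d] <- cp[a, d] + h; cm[a, d] <- cm[a, d] - h
    g[a, d] <- (engine$energy(cp, ctx) - engine$energy(cm, ctx)) / (2 * h)
  }
  g
}

# ---- generic classical force field ------------------------------------------

.FF <- list(k_bond = 300, k_angle = 60, v_torsion = 2.0,
            lj_eps = 0.05, lj_pad = 1.2, scale_14 = 0.5)

# Precompute bonded terms and the nonbonded pair list from a topology.
# Terms are stored as plain index/parameter vectors so energy and gradient
# evaluate fully vectorised (they sit in the optimiser's inner loop).
build_ff_context <- function(topology) {
  st <- topology$structure
  n <- n_atoms(st)
  r <- covalent_radius(st$symbols)
  bonds <- topology$bonds
  adj <- lapply(seq_len(n), function(a) neighbors_of(topology, a))
  ord <- ifelse(is.na(bonds$order), 1, bonds$order)

  # angle reference: 120 deg at centers carrying a multiple bond, 180 deg at
  # 2-coordinate centers with a triple bond, tetrahedral otherwise
  has_multiple <- rep(FALSE, n); has_triple <- rep(FALSE, n)
  for (b in seq_len(nrow(bonds))) {
    if (ord[b] >= 1.5) has_multiple[c(bonds$i[b], bonds$j[b])] <- TRUE
    if (ord[b] >= 3) has_triple[c(bonds$i[b], bonds$j[b])] <- TRUE
  }
  ai <- integer(0); aj <- integer(0); ak <- integer(0); cos0 <- numeric(0)
  for (center in seq_len(n)) {
    nb <- adj[[center]]
    if (length(nb) < 2L) next
    t0 <- if (has_triple[center] && length(nb) == 2L) 180
          else if (has_multiple[center]) 120 else 109.47
    for (p in seq_len(length(nb) - 1L)) for (q in seq((p + 1L), length(nb))) {
      ai <- c(ai, nb[p]); aj <- c(aj, center); ak <- c(ak, nb[q])
      cos0 <- c(cos0, cos(t0 * pi / 180))
    }
  }

  ti <- integer(0); tj <- integer(0); tk <- integer(0); tl <- integer(0); tv <- numeric(0)
  for (b in seq_len(nrow(bonds))) {
    j <- bonds$i[b]; k <- bonds$j[b]
    nbi <- setdiff(adj[[j]], k); nbl <- setdiff(adj[[k]], j)
    if (length(nbi) == 0L || length(nbl) == 0L) next
    v <- .FF$v_torsion / (length(nbi) * length(nbl))
    for (i in nbi) for (l in nbl) {
      ti <- c(ti, i); tj <- c(tj, j); tk <- c(tk, k); tl <- c(tl, l); tv <- c(tv, v)
    }
  }

  # graph distances decide exclusions: 1-2/1-3 excluded, 1-4 scaled
  gd <- igraph::distances(topology_graph(topology))
  pi_ <- integer(0); pj_ <- integer(0); sc <- numeric(0)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
      d <- gd[a, b]
      if (is.finite(d) && d < 3) next
      pi_ <- c(pi_, a); pj_ <- c(pj_, b)
      sc <- c(sc, if (is.finite(d) && d == 3) .FF$scale_14 else 1)
    }
  }
  list(n = n,
       bi = bonds$i, bj = bonds$j, br0 = r[bonds$i] + r[bonds$j],
       bk = rep(.FF$k_bond, nrow(bonds)),
       ai = ai, aj = aj, ak = ak, acos0 = cos0,
       aka = rep(.FF$k_angle, length(ai)),
       ti = ti, tj = tj, tk = tk, tl = tl, tv = tv,
       pi = pi_, pj = pj_, psc = sc,
       prmin = r[pi_] + r[pj_] + .FF$lj_pad,
       peps = rep(.FF$lj_eps, length(pi_)))
}

# row-wise cross product of two m x 3 matrices
.crossm <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# torsion angles (radians) for index vectors, plus the intermediates the
# gradient reuses
.torsion_geo <- function(coords, ctx) {
  b1 <- coords[ctx$tj, , drop = FALSE] - coords[ctx$ti, , drop = FALSE]
  b2 <- coords[ctx$tk, , drop = FALSE] - coords[ctx$tj, , drop = FALSE]
  b3 <- coords[ctx$tl, , drop = FALSE] - coords[ctx$tk, , drop = FALSE]
  n1 <- .crossm(b1, b2); n2 <- .crossm(b2, b3)
  l2 <- sqrt(rowSums(b2^2))
  phi <- atan2(rowSums(.crossm(n1, n2) * b2) / l2, rowSums(n1 * n2))
  list(b1 = b1, b2 = b2, b3 = b3, n1 = n1, n2 = n2, l2 = l2, phi = phi)
}

.scatter_add <- function(g, idx, mat) {
  s <- rowsum(mat, idx)
  rows <- as.integer(rownames(s))
  g[rows, ] <- g[rows, , drop = FALSE] + s
  g
}

.ff_energy <- function(coords, ctx) {
  e <- 0
  if (length(ctx$bi)) {
    d <- sqrt(rowSums((coords[ctx$bi, , drop = FALSE] -
                         coords[ctx$bj, , drop = FALSE])^2))
    e <- e + sum(ctx$bk * (d - ctx$br0)^2)
  }
  if (length(ctx$ai)) {
    u <- coords[ctx$ai, , drop = FALSE] - coords[ctx$aj, , drop = FALSE]
    v <- coords[ctx$ak, , drop = FALSE] - coords[ctx$aj, , drop = FALSE]
    ct <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    e <- e + sum(ctx$aka * (ct - ctx$acos0)^2)
  }
  if (length(ctx$ti)) {
    phi <- .torsion_geo(coords, ctx)$phi
    e <- e + sum(ctx$tv / 2 * (1 + cos(3 * phi)))
  }
  if (length(ctx$pi)) {
    d <- sqrt(rowSums((coords[ctx$pi, , drop = FALSE] -
                         coords[ctx$pj, , drop = FALSE])^2))
    x6 <- (ctx$prmin / d)^6
    e <- e + sum(ctx$psc * ctx$peps * (x6^2 - 2 * x6))
  }
  e
}

.ff_gradient <- function(coords, ctx) {
  g <- matrix(0, ctx$n, 3L)
  if (length(ctx$bi)) {
    dv <- coords[ctx$bi, , drop = FALSE] - coords[ctx$bj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    contrib <- dv * (2 * ctx$bk * (d - ctx$br0) / d)
    g <- .scatter_add(g, ctx$bi, contrib)
    g <- .scatter_add(g, ctx$bj, -contrib)
  }
  if (length(ctx$ai)) {
    u <- coords[ctx$ai, , drop = FALSE] - coords[ctx$aj, , drop = FALSE]
    v <- coords[ctx$ak, , drop = FALSE] - coords[ctx$aj, , drop = FALSE]
    lu <- sqrt(rowSums(u^2)); lv <- sqrt(rowSums(v^2))
    ct <- rowSums(u * v) / (lu * lv)
    pref <- 2 * ctx$aka * (ct - ctx$acos0)
    gi <- v / (lu * lv) - u * (ct / lu^2)
    gk <- u / (lu * lv) - v * (ct / lv^2)
    g <- .scatter_add(g, ctx$ai, gi * pref)
    g <- .scatter_add(g, ctx$ak, gk * pref)
    g <- .scatter_add(g, ctx$aj, -(gi + gk) * pref)
  }
  if (length(ctx$ti)) {
    geo <- .torsion_geo(coords, ctx)
    n1sq <- rowSums(geo$n1^2); n2sq <- rowSums(geo$n2^2)
    ok <- n1sq > 1e-12 & n2sq > 1e-12
    dEdphi <- ifelse(ok, -1.5 * ctx$tv * sin(3 * geo$phi), 0)
    gi <- -geo$n1 * (geo$l2 / pmax(n1sq, 1e-12))
    gl <- geo$n2 * (geo$l2 / pmax(n2sq, 1e-12))
    s1 <- rowSums(geo$b1 * geo$b2) / geo$l2^2
    s2 <- rowSums(geo$b3 * geo$b2) / geo$l2^2
    gj <- -gi * (1 + s1) + gl * s2
    gk <- -(gi + gj + gl)
    g <- .scatter_add(g, ctx$ti, gi * dEdphi)
    g <- .scatter_add(g, ctx$tj, gj * dEdphi)
    g <- .scatter_add(g, ctx$tk, gk * dEdphi)
    g <- .scatter_add(g, ctx$tl, gl * dEdphi)
  }
  if (length(ctx$pi)) {
    dv <- coords[ctx$pi, , drop = FALSE] - coords[ctx$pj, , drop = FALSE]
    d2 <- rowSums(dv^2); d <- sqrt(d2)
    x6 <- (ctx$prmin / d)^6
    contrib <- dv * (ctx$psc * ctx$peps * 12 * (x6 - x6^2) / d2)
    g <- .scatter_add(g, ctx$pi, contrib)
    g <- .scatter_add(g, ctx$pj, -contrib)
  }
  g
}

#' Built-in engines
#'
#' `ff_organic_engine()` is the primary classical force field, restricted to
#' elements an organic force field is parameterised for. `ff_universal_engine()`
#' shares its functional form but accepts every element in the radius table
#' (unrecognised atom types get default parameters) and serves as the
#' fallback. `mock_engine()` evaluates a fixed smooth pair potential with no
#' topology requirement, so the full pipeline runs with no external binaries
#' and no chemistry. `external_engine()` adapts a command-line backend that
#' reads/writes xyz (e.g. a tight-binding program); it errors at evaluation
#' time if the binary is absent, in which case the pipeline is simply run with
#' the built-in engines instead.
#'
#' @return an [energy_engine].
#' @name engines
NULL

#' @rdname engines
#' @export
ff_organic_engine <- function() {
  energy_engine(
    name = "ff94", energy = .ff_energy, gradient = .ff_gradient,
    setup = build_ff_context,
    accepts = function(symbols) all(symbols %in% .organic_elements)
  )
}

#' @rdname engines
#' @export
ff_universal_engine <- function() {
  energy_engine(
    name = "uff", energy = .ff_energy, gradient = .ff_gradient,
    setup = build_ff_context,
    accepts = function(symbols) all(is_known_element(symbols))
  )
}

#' @rdname engines
#' @export
mock_engine <- function() {
  rm0 <- 2.0; eps <- 1.0
  energy_engine(
    name = "mock",
    energy = function(coords, ctx) {
      if (nrow(coords) < 2L) return(0)
      d <- stats::dist(coords)
      x6 <- (rm0 / d)^6
      sum(eps * (x6^2 - 2 * x6))
    },
    gradient = function(coords, ctx) {
      n <- nrow(coords)
      g <- matrix(0, n, 3L)
      if (n < 2L) return(g)
      for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
        dv <- coords[a, ] - coords[b, ]
        d <- sqrt(sum(dv^2))
        x6 <- (rm0 / d)^6
        f <- eps * 12 * (x6 - x6^2) / d^2
        g[a, ] <- g[a, ] + f * dv
        g[b, ] <- g[b, ] - f * dv
      }
      g
    }
  )
}

#' @rdname engines
#' @param command path to the backend binary (e.g. `"xtb"`).
#' @param args extra command-line arguments.
#' @export
external_engine <- function(command = "xtb", args = character(0)) {
  energy_engine(
    name = paste0("external:", command),
    energy = function(coords, ctx) {
      if (Sys.which(command) == "") {
        stop("external backend '", command, "' not found on PATH; ",
             "run with the built-in force-field engines instead")
      }
      stop("external engine adapter: single-point parsing for '", command,
           "' is intentionally not bundled; wrap the binary with ",
           "energy_engine() for your backend's output format")
    },
    minimizes = FALSE
  )
}

#' Default engine chain
#'
#' Organic force field first, universal fallback second, mock engine last, so
#' the chain accepts any input.
#'
#' @return list of [energy_engine] objects.
#' @export
default_engine_chain <- function() {
  list(ff_organic_engine(), ff_universal_engine(), mock_engine())
}
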