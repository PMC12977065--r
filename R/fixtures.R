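# Toy transition-state fixtures.
#
# These stand in for real benchmark reactions: geometries are deterministic
# functions of their parameters, frozen cores are known by construction, and
# the rotamer inventory of the flexible tail is enumerable by a brute-force
# torsion scan, so every stage of the pipeline can be checked against an
# independent oracle with no external data or binaries.
#
# Construction constants: C-C 1.54 A, C-H 1.09 A, tetrahedral angles
# (109.47 deg), forming/breaking axial bonds at 1.8-2.1 A.

.CC <- 1.54; .CH <- 1.09; .TET <- 109.47

#' SN2-like toy transition state
#'
#' A pentacoordinate central carbon with a fluoride nucleophile and chloride
#' leaving group exactly collinear on the axial axis (C-F 1.8 A, C-Cl 2.1 A,
#' F-C-Cl = 180 degrees), two equatorial hydrogens, and one equatorial
#' n-alkyl tail of `tail_length` carbons contributing `tail_length - 1` free
#' rotatable bonds. Total charge -1; reaction center = {C_central, F, Cl}.
#'
#' @param tail_length number of tail carbons (>= 0; 0 gives a rigid
#'   trihydrogen toy with `expected_rotamer_count` 1).
#' @return object of class `toy_ts`: `structure`, `reaction_center`,
#'   `expected_rotamer_count` (brute-force torsion-scan product over the free
#'   rotors, counted lazily on first access via [torsion_scan_oracle()]),
#'   `free_rotors` (list of 4-atom torsion index vectors), `template_smiles`
#'   (reactant side).
#' @export
make_sn2_toy <- function(tail_length = 0L) {
  tail_length <- as.integer(tail_length)
  if (is.na(tail_length) || tail_length < 0L) stop("tail_length must be >= 0")
  symbols <- c("C", "F", "Cl")
  coords <- rbind(c(0, 0, 0), c(0, 0, 1.80), c(0, 0, -2.10))
  eq <- rbind(c(1, 0, 0),
              c(-0.5, sqrt(3) / 2, 0),
              c(-0.5, -sqrt(3) / 2, 0))
  # two equatorial hydrogens
  symbols <- c(symbols, "H", "H")
  coords <- rbind(coords, .CH * eq[2, ], .CH * eq[3, ])
  tail_carbon <- integer(0)
  if (tail_length >= 1L) {
    symbols <- c(symbols, "C")
    coords <- rbind(coords, .CC * eq[1, ])
    tail_carbon <- nrow(coords)
    chain <- c(2L, 1L, tail_carbon)   # F - Ccentral - C1 reference frame
    for (k in seq_len(max(0L, tail_length - 1L))) {
      # first extension perpendicular to the axial F...Cl axis (a 180-degree
      # dihedral from axial F would fold the chain onto the leaving group);
      # subsequent carbons continue as an anti zig-zag
      dh_next <- if (k == 1L) 90 else 180
      p <- place_atom(coords[chain[1], ], coords[chain[2], ], coords[chain[3], ],
                      .CC, .TET, dh_next)
      symbols <- c(symbols, "C")
      coords <- rbind(coords, p)
      tail_carbon <- c(tail_carbon, nrow(coords))
      chain <- c(chain[2:3], nrow(coords))
    }
    # hydrogens: 2 on inner chain carbons (staggered around the next-carbon
    # direction), 3 on the terminal one
    nc <- length(tail_carbon)
    for (k in seq_len(nc)) {
      this <- tail_carbon[k]
      prev <- if (k == 1L) 1L else tail_carbon[k - 1L]
      pprev <- if (k == 1L) 2L else if (k == 2L) 1L else tail_carbon[k - 2L]
      d0 <- if (k == 1L) 90 else 180
      dihs <- if (k < nc) (d0 + c(120, 240)) %% 360 else c(60, 180, 300)
      for (dh in dihs) {
        p <- place_atom(coords[pprev, ], coords[prev, ], coords[this, ],
                        .CH, .TET, dh)
        symbols <- c(symbols, "H")
        coords <- rbind(coords, p)
      }
    }
  } else {
    symbols <- c(symbols, "H")
    coords <- rbind(coords, .CH * eq[1, ])
  }
  st <- ts_structure(symbols, coords, charge = -1L,
                     comment = sprintf("sn2 toy, tail %d", tail_length))
  rotors <- list()
  if (tail_length >= 2L) {
    for (k in seq_len(tail_length - 1L)) {
      a <- if (k == 1L) 1L else tail_carbon[k - 1L]
      rotors[[k]] <- c(a, tail_carbon[k], tail_carbon[k + 1L],
                       if (k + 1L < tail_length) tail_carbon[k + 2L]
                       else tail_carbon[k + 1L] + 0L)
    }
    # last rotor's 4th atom: first hydrogen on the terminal carbon
    last <- length(rotors)
    if (rotors[[last]][3L] == rotors[[last]][4L]) {
      term <- tail_carbon[tail_length]
      h_on_term <- which(symbols == "H" &
                           sqrt(rowSums(sweep(coords, 2L, coords[term, ])^2)) < 1.2)
      rotors[[last]][4L] <- h_on_term[1L]
    }
  }
  smiles <- if (tail_length == 0L) "CCl.[F-]"
            else paste0(paste(rep("C", tail_length), collapse = ""), "CCl.[F-]")
  toy <- structure(
    list(structure = st, reaction_center = c(1L, 2L, 3L),
         free_rotors = rotors,
         expected_rotamer_count = 1L,
         template_smiles = smiles),
    class = "toy_ts"
  )
  if (tail_length >= 2L) toy$expected_rotamer_count <- count_rotamers(toy)
  toy
}

#' Square-planar organometallic toy
#'
#' A d8-like palladium surrogate with four ligating atoms in a square plane
#' (two amine N at 2.05 A, two Cl at 2.30 A) and one flexible ethyl arm on a
#' nitrogen. Bond-order perception has no valence model for the metal, so
#' this fixture deterministically exercises the connectivity-only fallback
#' and (the organic engine rejecting Pd) the universal force-field fallback.
#'
#' @return a `toy_ts` with reaction center `{Pd}` and charge 0.
#' @export
make_metal_toy <- function() {
  symbols <- c("Pd", "N", "N", "Cl", "Cl")
  coords <- rbind(c(0, 0, 0),
                  c(2.05, 0, 0), c(-2.05, 0, 0),
                  c(0, 2.30, 0), c(0, -2.30, 0))
  # ethyl arm on N2; the cis chloride (atom 4) anchors the dihedral frame
  # because the trans N-Pd-N triple is collinear
  c1 <- place_atom(coords[4, ], coords[1, ], coords[2, ], 1.47, .TET, 90)
  c2 <- place_atom(coords[1, ], coords[2, ], c1, .CC, .TET, 180)
  symbols <- c(symbols, "C", "C")
  coords <- rbind(coords, c1, c2)
  for (dh in c(60, 300)) {
    coords <- rbind(coords, place_atom(coords[1, ], coords[2, ], c1, .CH, .TET, dh))
    symbols <- c(symbols, "H")
  }
  for (dh in c(60, 180, 300)) {
    coords <- rbind(coords, place_atom(coords[2, ], c1, c2, .CH, .TET, dh))
    symbols <- c(symbols, "H")
  }
  # complete the amine coordination: 2 H on the arm nitrogen, 3 on the other
  h1 <- place_atom(coords[4, ], coords[1, ], coords[2, ], 1.02, .TET, 210)
  h2 <- place_atom(coords[4, ], coords[1, ], coords[2, ], 1.02, .TET, 330)
  h3 <- place_atom(coords[4, ], coords[1, ], coords[3, ], 1.02, .TET, 30)
  h4 <- place_atom(coords[4, ], coords[1, ], coords[3, ], 1.02, .TET, 150)
  h5 <- place_atom(coords[4, ], coords[1, ], coords[3, ], 1.02, .TET, 270)
  symbols <- c(symbols, rep("H", 5L))
  coords <- rbind(coords, h1, h2, h3, h4, h5)
  st <- ts_structure(symbols, coords, charge = 0L, comment = "metal toy")
  structure(
    list(structure = st, reaction_center = 1L, free_rotors = list(),
         expected_rotamer_count = NA_integer_, template_smiles = NULL),
    class = "toy_ts"
  )
}

#' Pathological fixture: overlapping atoms
#'
#' Two helium atoms 0.1 Angstrom apart, for exercising geometry-error paths.
#'
#' @return a `toy_ts` whose structure violates the minimum-distance contract.
#' @export
make_overlapping_toy <- function() {
  st <- ts_structure(c("He", "He"), rbind(c(0, 0, 0), c(0.1, 0, 0)),
                     charge = 0L, comment = "pathological overlap")
  structure(list(structure = st, reaction_center = 1L, free_rotors = list(),
                 expected_rotamer_count = NA_integer_, template_smiles = NULL),
            class = "toy_ts")
}

#' @export
print.toy_ts <- function(x, ...) {
  cat("<toy_ts> ", n_atoms(x$structure), " atoms, reaction center {",
      paste(x$reaction_center, collapse = ","), "}, ",
      length(x$free_rotors), " free rotor(s)\n", sep = "")
  invisible(x)
}

#' Brute-force torsion scan oracle
#'
#' Exhaustive rigid scan of one torsion: the atoms on the far side of the
#' central bond are rotated in `step`-degree increments, the engine energy is
#' evaluated at each grid point, and the local minima of the (circular)
#' profile are returned. Deterministic; independent of the embedding path it
#' is used to check.
#'
#' @param toy a `toy_ts`.
#' @param torsion integer vector of 4 bonded-chain atom indices `(i, j, k, l)`;
#'   rotation is about `j-k`.
#' @param step grid step in degrees; must divide 360.
#' @param engine an [energy_engine] (default [ff_universal_engine()]).
#' @param frozen frozen atom indices; scanning a torsion whose four atoms are
#'   all frozen is meaningless and raises a validation error.
#' @return sorted numeric vector of minimum angles (degrees in `[0, 360)`).
#' @export
torsion_scan_oracle <- function(toy, torsion, step = 10,
                                engine = ff_universal_engine(),
                                frozen = integer(0)) {
  stopifnot(inherits(toy, "toy_ts"), length(torsion) == 4L)
  if (360 %% step != 0) stop("step must divide 360")
  if (all(torsion %in% frozen)) {
    stop("torsion lies entirely inside the frozen set; scan is meaningless")
  }
  st <- toy$structure
  topo <- infer_connectivity(st)
  g <- topology_graph(topo)
  j <- torsion[2L]; k <- torsion[3L]
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(j, k)))
  comp <- igraph::components(g2)$membership
  if (comp[j] == comp[k]) stop("torsion bond ", j, "-", k, " is in a ring; rigid scan undefined")
  moving <- which(comp == comp[k])
  ctx <- engine_setup(engine, topo)
  angles <- seq(0, 360 - step, by = step)
  base <- dihedral_angle(st$coords[torsion[1L], ], st$coords[torsion[2L], ],
                         st$coords[torsion[3L], ], st$coords[torsion[4L], ])
  prof <- vapply(angles, function(a) {
    X <- rotate_about_axis(st$coords, moving, st$coords[j, ], st$coords[k, ],
                           a - base)
    engine$energy(X, ctx)
  }, numeric(1))
  n <- length(prof)
  minima <- angles[vapply(seq_len(n), function(m) {
    prof[m] < prof[if (m == 1L) n else m - 1L] &&
      prof[m] < prof[if (m == n) 1L else m + 1L]
  }, logical(1))]
  sort(minima %% 360)
}

#' Count the toy's rotamer inventory by brute force
#'
#' Product over the toy's free rotors of the torsion-scan minima counts.
#'
#' @param toy a `toy_ts`.
#' @param step scan step in degrees (default 10).
#' @param engine engine for the scan.
#' @return integer rotamer count (1 for rigid toys).
#' @export
count_rotamers <- function(toy, step = 10, engine = ff_universal_engine()) {
  if (length(toy$free_rotors) == 0L) return(1L)
  prod(vapply(toy$free_rotors, function(t)
    length(torsion_scan_oracle(toy, t, step = step, engine = engine)),
    integer(1)))
}
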