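#' Bond-graph perception and frozen-atom derivation
#'
#' The TS guess geometry is turned into a bond graph either by full bond-order
#' perception ([perceive_bond_orders()]), by transferring bonding from a
#' reactant/product SMILES template ([apply_smiles_template()]), or by the
#' connectivity-only fallback ([infer_connectivity()]). The frozen-atom set --
#' reaction-center atoms plus their immediate bonded neighbours -- is derived
#' from the graph by [frozen_atoms()].
#'
#' @name topology
NULL

.BOND_TOL_FACTOR <- 1.3   # covalent-radius-sum multiplier
.MIN_ATOM_DIST <- 0.4     # Angstrom; closer atoms are a geometry error

new_topology <- function(structure, bonds, formal_charges, connectivity_only) {
  rownames(bonds) <- NULL
  structure(
    list(structure = structure, bonds = bonds,
         formal_charges = as.integer(formal_charges),
         connectivity_only = isTRUE(connectivity_only)),
    class = "ts_topology"
  )
}

#' @export
print.ts_topology <- function(x, ...) {
  cat("<ts_topology> ", n_atoms(x$structure), " atoms, ", nrow(x$bonds),
      " bonds", if (x$connectivity_only) " (connectivity only)", "\n", sep = "")
  invisible(x)
}

topology_graph <- function(topology) {
  igraph::graph_from_data_frame(
    topology$bonds[, c("i", "j"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(topology$structure)))
  )
}

#' Infer connectivity from geometry
#'
#' Two atoms are bonded iff their distance is at most 1.3 times the sum of
#' their covalent radii. This is the connectivity-only fallback used when
#' bond-order perception fails (common for transition-metal complexes); the
#' resulting topology carries `connectivity_only = TRUE`, unknown bond orders
#' and zero formal charges.
#'
#' @param structure a [ts_structure].
#' @return a `ts_topology`. A disconnected bond graph is allowed (warning).
#' @export
infer_connectivity <- function(structure) {
  stopifnot(inherits(structure, "ts_structure"))
  n <- n_atoms(structure)
  D <- dist_matrix(structure$coords)
  if (n > 1L) {
    too_close <- which(D < .MIN_ATOM_DIST & upper.tri(D), arr.ind = TRUE)
    if (nrow(too_close) > 0L) {
      stop("overlapping atoms ", too_close[1, 1], " and ", too_close[1, 2],
           " at ", sprintf("%.3f", D[too_close[1, , drop = FALSE]]),
           " Angstrom (< ", .MIN_ATOM_DIST, ")")
    }
  }
  r <- covalent_radius(structure$symbols)
  cutoff <- outer(r, r, `+`) * .BOND_TOL_FACTOR
  hit <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
  bonds <- data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
                      order = rep(NA_real_, nrow(hit)))
  topo <- new_topology(structure, bonds, integer(n), connectivity_only = TRUE)
  if (n > 1L) {
    comp <- igraph::components(topology_graph(topo))
    if (comp$no > 1L) {
      warning("bond graph is disconnected (", comp$no, " fragments)")
    }
  }
  topo
}

# Try to assign integer bond orders + formal charges to the non-reaction-center
# part of a connectivity graph. Returns NULL when no acceptable assignment
# exists (unknown valences, metals, residual charge without a reaction center
# to absorb it).
.assign_bond_orders <- function(structure, bonds, reaction_center) {
  n <- n_atoms(structure)
  rc <- reaction_center
  ord <- rep(1, nrow(bonds))
  degree <- tabulate(c(bonds$i, bonds$j), n)
  exempt <- seq_len(n) %in% rc
  # elements with no valence model at all (metals) defeat perception even at
  # the reaction center: there is no internally valid assignment to accept
  if (!all(structure$symbols %in% names(.standard_valences))) return(NULL)
  target <- integer(n)
  for (a in seq_len(n)) {
    if (exempt[a]) next
    vals <- .standard_valences[[structure$symbols[a]]]
    if (is.null(vals)) return(NULL)
    ok <- vals[vals >= degree[a]]
    # degree one above max standard valence is representable as a +/-1 ion
    # (ammonium-like); anything further off is a perception failure
    if (length(ok) == 0L && degree[a] > max(vals) + 1L) return(NULL)
    target[a] <- if (length(ok)) min(ok) else max(vals)
  }
  # greedily promote bonds between two unsaturated non-exempt atoms
  valence <- function() {
    v <- numeric(n)
    for (b in seq_len(nrow(bonds))) {
      v[bonds$i[b]] <- v[bonds$i[b]] + ord[b]
      v[bonds$j[b]] <- v[bonds$j[b]] + ord[b]
    }
    v
  }
  repeat {
    v <- valence()
    deficit <- ifelse(exempt, 0, target - v)
    cand <- which(deficit[bonds$i] > 0 & deficit[bonds$j] > 0 &
                    !exempt[bonds$i] & !exempt[bonds$j])
    if (length(cand) == 0L) break
    ord[cand[1L]] <- ord[cand[1L]] + 1
  }
  v <- valence()
  fc <- integer(n)
  for (a in seq_len(n)) {
    if (exempt[a]) next
    gap <- v[a] - target[a]
    sym <- structure$symbols[a]
    if (gap == 0) next
    if (abs(gap) > 1L) return(NULL)
    # under/over-bonded by one: anion for electronegative atoms with a lone
    # deficit (halide, alkoxide), cation for over-coordinated N/O/S
    fc[a] <- if (gap > 0) 1L else -1L
    if (gap < 0 && sym %in% c("C", "B")) return(NULL)  # carbanion vs cation: ambiguous
  }
  residual <- structure$charge - sum(fc)
  if (residual != 0L) {
    if (length(rc) == 0L) return(NULL)
    fc[min(rc)] <- fc[min(rc)] + residual   # any valid assignment accepted at the RC
  }
  list(order = ord, formal_charges = fc)
}

#' Perceive bond orders and formal charges
#'
#' Attempts a full bond-order/valence assignment consistent with the total
#' charge, on top of geometric connectivity. Reaction-center atoms do not
#' display typical bonds and valences, so any internally consistent assignment
#' is accepted for them (their bonds and distances are constrained throughout
#' generation and refinement anyway; residual charge is parked on the
#' lowest-index reaction-center atom). If no assignment is possible -- as is
#' common for transition-metal complexes -- the operation degrades to
#' [infer_connectivity()] with a message, never an error.
#'
#' @param structure a [ts_structure].
#' @param reaction_center integer vector of 1-based reaction-center atom
#'   indices (may be empty for ground-state molecules).
#' @return a `ts_topology`; `connectivity_only` is `TRUE` when the fallback
#'   path was taken (in which case formal charges are all zero and need not
#'   sum to the total charge).
#' @export
perceive_bond_orders <- function(structure, reaction_center = integer(0)) {
  stopifnot(inherits(structure, "ts_structure"))
  reaction_center <- validate_reaction_center(reaction_center, structure,
                                              allow_empty = TRUE)
  topo <- infer_connectivity(structure)
  res <- .assign_bond_orders(structure, topo$bonds, reaction_center)
  if (is.null(res)) {
    message("bond-order perception failed; falling back to connectivity only")
    return(topo)
  }
  bonds <- topo$bonds
  bonds$order <- res$order
  rc_bond <- bonds$i %in% reaction_center | bonds$j %in% reaction_center
  bonds$order[rc_bond & is.na(bonds$order)] <- 1
  new_topology(structure, bonds, res$formal_charges, connectivity_only = FALSE)
}

validate_reaction_center <- function(reaction_center, structure,
                                     allow_empty = FALSE) {
  reaction_center <- sort(unique(as.integer(reaction_center)))
  if (!allow_empty && length(reaction_center) == 0L) {
    stop("reaction center must contain at least one atom index")
  }
  if (length(reaction_center) &&
      (min(reaction_center) < 1L || max(reaction_center) > n_atoms(structure))) {
    stop("reaction-center indices must be in 1..", n_atoms(structure),
         " (1-based)")
  }
  reaction_center
}

#' Derive the frozen-atom set
#'
#' Frozen atoms are the union of the reaction center and the immediate bonded
#' neighbours of every reaction-center atom (neighbours of neighbours are
#' never frozen). Their positions and mutual distances are held fixed through
#' embedding and refinement.
#'
#' @param topology a `ts_topology`.
#' @param reaction_center integer vector of 1-based atom indices; must be
#'   nonempty.
#' @return sorted integer vector of frozen atom indices (superset of the
#'   reaction center).
#' @export
frozen_atoms <- function(topology, reaction_center) {
  stopifnot(inherits(topology, "ts_topology"))
  rc <- validate_reaction_center(reaction_center, topology$structure)
  nb <- c(topology$bonds$j[topology$bonds$i %in% rc],
          topology$bonds$i[topology$bonds$j %in% rc])
  sort(unique(c(rc, nb)))
}

neighbors_of <- function(topology, atom) {
  sort(unique(c(topology$bonds$j[topology$bonds$i == atom],
                topology$bonds$i[topology$bonds$j == atom])))
}

#' Count rotatable bonds outside the frozen core
#'
#' A bond is counted as a free rotor iff it is not in a ring (bridge edge),
#' both endpoints have graph degree > 1, and not both endpoints are frozen
#' (a bond whose two ends are both frozen is part of the constrained core;
#' torsions around it still relax during refinement but do not add sampled
#' flexibility).
#'
#' @param topology a `ts_topology`.
#' @param frozen integer vector of frozen atom indices (possibly empty).
#' @return integer count.
#' @export
n_rotatable_bonds <- function(topology, frozen = integer(0)) {
  g <- topology_graph(topology)
  if (nrow(topology$bonds) == 0L) return(0L)
  deg <- igraph::degree(g)
  bridges <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(topology$bonds))
  in_ring[as.integer(bridges)] <- FALSE
  i <- topology$bonds$i; j <- topology$bonds$j
  sum(!in_ring & deg[i] > 1 & deg[j] > 1 & !(i %in% frozen & j %in% frozen))
}
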