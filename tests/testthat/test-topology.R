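make_ethane <- function() {
  # standard staggered ethane
  c1 <- c(0, 0, 0); c2 <- c(1.54, 0, 0)
  coords <- rbind(c1, c2)
  symbols <- c("C", "C")
  for (dh in c(60, 180, 300)) {
    coords <- rbind(coords, racerts:::place_atom(c2 + c(0, 1, 0), c2, c1, 1.09, 109.47, dh))
    symbols <- c(symbols, "H")
  }
  for (dh in c(0, 120, 240)) {
    coords <- rbind(coords, racerts:::place_atom(c1 + c(0, 1, 0), c1, c2, 1.09, 109.47, dh))
    symbols <- c(symbols, "H")
  }
  ts_structure(symbols, coords)
}

test_that("infer_connectivity: textbook cases and the covalent-radius oracle", {
  h2 <- ts_structure(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  expect_equal(nrow(infer_connectivity(h2)$bonds), 1L)

  he2 <- ts_structure(c("He", "He"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_warning(topo <- infer_connectivity(he2), "disconnected")
  expect_equal(nrow(topo$bonds), 0L)

  eth <- make_ethane()
  topo <- infer_connectivity(eth)
  expect_equal(nrow(topo$bonds), 7L)
  # oracle: pairwise distances against radius sums with factor 1.3
  D <- as.matrix(dist(eth$coords))
  r <- racerts:::covalent_radius(eth$symbols)
  expected <- sum(D[upper.tri(D)] <= (outer(r, r, `+`) * 1.3)[upper.tri(D)])
  expect_equal(nrow(topo$bonds), expected)
  expect_true(topo$connectivity_only)

  overlap <- make_overlapping_toy()
  expect_error(infer_connectivity(overlap$structure), "overlapping")
})

test_that("perceive_bond_orders assigns orders/charges for organics and never raises", {
  methane <- ts_structure(
    c("C", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
          c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89)))
  topo <- perceive_bond_orders(methane)
  expect_false(topo$connectivity_only)
  expect_equal(nrow(topo$bonds), 4L)
  expect_true(all(topo$bonds$order == 1))
  expect_identical(topo$formal_charges, rep(0L, 5L))

  # pentacoordinate SN2 core: some valid assignment or clean fallback, never an error
  toy <- make_sn2_toy(1L)
  expect_no_error(topo2 <- perceive_bond_orders(toy$structure, toy$reaction_center))
  if (!topo2$connectivity_only) {
    expect_equal(sum(topo2$formal_charges), toy$structure$charge)
  }

  # transition-metal complex: connectivity-only fallback, with a message not an error
  metal <- make_metal_toy()
  expect_message(topo3 <- perceive_bond_orders(metal$structure, metal$reaction_center),
                 "falling back")
  expect_true(topo3$connectivity_only)
})

test_that("non-reaction-center connectivity agrees between perception routes", {
  toy <- make_sn2_toy(2L)
  t_full <- perceive_bond_orders(toy$structure, toy$reaction_center)
  t_conn <- infer_connectivity(toy$structure)
  not_rc <- function(b) !(b$i %in% toy$reaction_center) & !(b$j %in% toy$reaction_center)
  expect_identical(t_full$bonds[not_rc(t_full$bonds), c("i", "j")],
                   t_conn$bonds[not_rc(t_conn$bonds), c("i", "j")])
})

test_that("frozen_atoms returns RC plus immediate neighbours only", {
  toy <- make_sn2_toy(2L)
  topo <- perceive_bond_orders(toy$structure, toy$reaction_center)
  fr <- frozen_atoms(topo, toy$reaction_center)
  # oracle: explicit neighbour enumeration on the bond table
  nb <- unique(unlist(lapply(toy$reaction_center, function(a) {
    c(topo$bonds$j[topo$bonds$i == a], topo$bonds$i[topo$bonds$j == a])
  })))
  expect_setequal(fr, union(toy$reaction_center, nb))
  # neighbours-of-neighbours (tail C2) must not be frozen
  expect_false(7L %in% fr)

  # all atoms as RC -> frozen set is everything
  all_rc <- seq_len(n_atoms(toy$structure))
  expect_setequal(frozen_atoms(topo, all_rc), all_rc)

  # isolated RC atom with no bonds
  iso <- suppressWarnings(infer_connectivity(
    ts_structure(c("He", "He"), rbind(c(0, 0, 0), c(10, 0, 0)))))
  expect_identical(frozen_atoms(iso, 1L), 1L)

  expect_error(frozen_atoms(topo, integer(0)), "at least one")
  expect_error(frozen_atoms(topo, 99L), "1-based")
})

test_that("frozen_atoms is monotone in the reaction center", {
  toy <- make_sn2_toy(3L)
  topo <- perceive_bond_orders(toy$structure, toy$reaction_center)
  rcs <- list(1L, c(1L, 2L), c(1L, 2L, 3L), c(1L, 2L, 3L, 6L))
  prev <- integer(0)
  for (rc in rcs) {
    fr <- frozen_atoms(topo, rc)
    expect_true(all(prev %in% fr))
    prev <- fr
  }
})

test_that("metal toy frozen set is the metal plus its four ligating atoms", {
  metal <- make_metal_toy()
  topo <- suppressMessages(perceive_bond_orders(metal$structure, 1L))
  expect_setequal(frozen_atoms(topo, 1L), 1:5)
})

test_that("rotatable-bond counting excludes rings, terminals and frozen-frozen bonds", {
  toy2 <- make_sn2_toy(2L); toy3 <- make_sn2_toy(3L)
  for (toy in list(toy2, toy3)) {
    topo <- perceive_bond_orders(toy$structure, toy$reaction_center)
    fr <- frozen_atoms(topo, toy$reaction_center)
    expect_equal(n_rotatable_bonds(topo, fr), length(toy$free_rotors))
  }
  # cyclopropane: ring bonds are not rotors
  ring <- ts_structure(rep("C", 3L),
                       rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0)))
  expect_equal(n_rotatable_bonds(suppressWarnings(infer_connectivity(ring))), 0L)
})
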