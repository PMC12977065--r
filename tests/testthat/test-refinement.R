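test_that("force-field analytic gradients match central differences", {
  set.seed(51)
  toy <- make_sn2_toy(2L)
  topo <- perceive_bond_orders(toy$structure, toy$reaction_center)
  eng <- ff_organic_engine()
  ctx <- eng$setup(topo)
  coords <- toy$structure$coords + matrix(rnorm(length(toy$structure$coords),
                                                sd = 0.05), ncol = 3L)
  g_ana <- eng$gradient(coords, ctx)
  g_num <- matrix(0, nrow(coords), 3L)
  h <- 1e-6
  for (a in seq_len(nrow(coords))) for (d in 1:3) {
    cp <- coords; cm <- coords
    cp[a, d] <- cp[a, d] + h; cm[a, d] <- cm[a, d] - h
    g_num[a, d] <- (eng$energy(cp, ctx) - eng$energy(cm, ctx)) / (2 * h)
  }
  expect_equal(g_ana, g_num, tolerance = 1e-4)

  m <- mock_engine()
  gm_ana <- m$gradient(coords, NULL)
  gm_num <- racerts:::engine_gradient(energy_engine("num", m$energy), coords, NULL)
  expect_equal(gm_ana, gm_num, tolerance = 1e-4)
})

test_that("minimize: engine choice, exact frozen fixing, energy descent", {
  toy <- make_sn2_toy(2L)
  topo <- perceive_bond_orders(toy$structure, toy$reaction_center)
  fr <- frozen_atoms(topo, toy$reaction_center)
  conf <- toy$structure
  set.seed(61)
  free <- setdiff(seq_len(n_atoms(conf)), fr)
  conf$coords[free, ] <- conf$coords[free, ] + matrix(rnorm(3 * length(free), sd = 0.1),
                                                      ncol = 3L)
  eng <- ff_organic_engine(); ctx <- eng$setup(topo)
  e0 <- eng$energy(conf$coords, ctx)
  ref <- minimize_conformer(conf, topo, fr)
  expect_s3_class(ref, "refined_conformer")
  expect_identical(ref$engine, "ff94")
  expect_false(ref$fallback_used)
  expect_lte(ref$energy, e0 + 1e-6)
  # frozen atoms exactly fixed (they are not optimisation variables)
  expect_equal(ref$structure$coords[fr, ], conf$coords[fr, ], tolerance = 1e-12)
  # frozen-pair distance matrix untouched
  d0 <- as.matrix(dist(conf$coords[fr, ]))
  d1 <- as.matrix(dist(ref$structure$coords[fr, ]))
  expect_lte(max(abs(d0 - d1)), 1e-6)

  # re-minimising a minimum changes (almost) nothing
  again <- minimize_conformer(ref$structure, topo, fr)
  expect_lte(abs(again$energy - ref$energy), 1e-4)
})

test_that("metal fixture skips the organic tier and uses the universal fallback", {
  metal <- make_metal_toy()
  topo <- suppressMessages(perceive_bond_orders(metal$structure, metal$reaction_center))
  fr <- frozen_atoms(topo, metal$reaction_center)
  ref <- minimize_conformer(metal$structure, topo, fr)
  expect_true(ref$fallback_used)
  expect_identical(ref$engine, "uff")
  expect_equal(ref$structure$coords[fr, ], metal$structure$coords[fr, ],
               tolerance = 1e-12)

  # an element no engine accepts
  only_h <- energy_engine("h-only", function(coords, ctx) 0,
                          accepts = function(s) all(s == "H"))
  expect_error(minimize_conformer(metal$structure, topo, fr,
                                  engines = list(only_h)), "Pd")
})

test_that("engine-chain determinism: same input gives identical results", {
  toy <- make_sn2_toy(2L)
  topo <- perceive_bond_orders(toy$structure, toy$reaction_center)
  fr <- frozen_atoms(topo, toy$reaction_center)
  r1 <- minimize_conformer(toy$structure, topo, fr)
  r2 <- minimize_conformer(toy$structure, topo, fr)
  expect_identical(r1$energy, r2$energy)
  expect_identical(r1$structure$coords, r2$structure$coords)
  expect_identical(r1$fallback_used, r2$fallback_used)
})

test_that("rank_ensemble: stable ties, reversal, failure drops members", {
  s <- make_sn2_toy(0L)$structure
  ens <- ts_ensemble(list(s, s, s), energies = c(1, 2, 3),
                     labels = c("a", "b", "c"))
  const <- energy_engine("const", function(coords, ctx) nrow(coords))
  out <- rank_ensemble(ens, const)
  expect_identical(out$labels, c("a", "b", "c"))     # stable tie
  expect_true(all(out$energies == n_atoms(s)))

  # an engine keyed on a coordinate reverses the order
  marked <- lapply(1:3, function(k) { x <- s; x$coords[1, 1] <- k; x })
  ens2 <- ts_ensemble(marked, energies = c(1, 2, 3), labels = c("a", "b", "c"))
  neg <- energy_engine("neg", function(coords, ctx) -coords[1, 1])
  out2 <- rank_ensemble(ens2, neg)
  expect_identical(out2$labels, c("c", "b", "a"))

  fail_first <- energy_engine("flaky", function(coords, ctx) {
    if (coords[1, 1] == 1) stop("boom") else nrow(coords)
  })
  expect_warning(out3 <- rank_ensemble(ens2, fail_first), "dropped")
  expect_equal(length(out3), 2L)
})

test_that("anti tail rotamer ranks below a gauche-eclipsed perturbation", {
  toy <- make_sn2_toy(2L)
  topo <- perceive_bond_orders(toy$structure, toy$reaction_center)
  eng <- ff_universal_engine(); ctx <- eng$setup(topo)
  st <- toy$structure
  rot <- toy$free_rotors[[1L]]
  g <- racerts:::topology_graph(topo)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, rot[2:3]))
  moving <- which(igraph::components(g2)$membership ==
                    igraph::components(g2)$membership[rot[3L]])
  ecl <- st
  ecl$coords <- racerts:::rotate_about_axis(st$coords, moving,
                                            st$coords[rot[2L], ],
                                            st$coords[rot[3L], ], 60)
  # oracle: direct energy evaluation of both hand-built geometries
  expect_lt(eng$energy(st$coords, ctx), eng$energy(ecl$coords, ctx))
})
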