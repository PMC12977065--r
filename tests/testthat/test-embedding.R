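toy_setup <- function(tail_length) {
  toy <- make_sn2_toy(tail_length)
  topo <- perceive_bond_orders(toy$structure, toy$reaction_center)
  fr <- frozen_atoms(topo, toy$reaction_center)
  cons <- build_constraints(toy$structure, fr, toy$reaction_center)
  list(toy = toy, topo = topo, frozen = fr, constraints = cons)
}

test_that("build_constraints measures every frozen pair from the input", {
  st <- ts_structure(c("C", "N", "O"),
                     rbind(c(0, 0, 0), c(1.8, 0, 0), c(0, 3.1, 0)))
  cons <- build_constraints(st, frozen = 1:3, reaction_center = 1:3)
  expect_equal(nrow(cons$fixed_distances), 3L)
  # oracle: direct distance computation
  expect_setequal(round(cons$fixed_distances$target, 6),
                  round(c(1.8, 3.1, sqrt(1.8^2 + 3.1^2)), 6))
  expect_equal(nrow(cons$fixed_positions), 3L)

  single <- build_constraints(st, frozen = 2L, reaction_center = 2L)
  expect_equal(nrow(single$fixed_distances), 0L)
  expect_equal(nrow(single$fixed_positions), 1L)

  # empty reaction center but nonempty frozen set: distances only
  nofix <- build_constraints(st, frozen = c(1L, 2L), reaction_center = integer(0))
  expect_equal(nrow(nofix$fixed_positions), 0L)
  expect_equal(nrow(nofix$fixed_distances), 1L)

  clash <- ts_structure(c("C", "C"), rbind(c(0, 0, 0), c(0.2, 0, 0)))
  expect_error(build_constraints(clash, 1:2, 1:2), "apart")
  expect_error(build_constraints(st, frozen = 2L, reaction_center = 1L),
               "must contain")
})

test_that("constraint spec serialises to YAML", {
  s <- toy_setup(1L)
  y <- constraints_as_yaml(s$constraints)
  parsed <- yaml::yaml.load(y)
  expect_equal(parsed$tolerance, 0.01)
  expect_equal(length(parsed$fixed_distances), nrow(s$constraints$fixed_distances))
})

test_that("n_initial_conformers scales with free rotors and floors at one", {
  cfg30 <- generation_config(conf_factor = 30L)
  s0 <- toy_setup(0L); s3 <- toy_setup(3L)
  expect_equal(n_initial_conformers(cfg30, s0$topo, s0$frozen), 30L)
  expect_equal(n_initial_conformers(cfg30, s3$topo, s3$frozen), 60L)
  expect_equal(n_initial_conformers(generation_config(conf_factor = 1L),
                                    toy_setup(2L)$topo, toy_setup(2L)$frozen), 1L)
  expect_error(generation_config(conf_factor = 0L), ">= 1")
})

test_that("embedding satisfies constraints, placement and chirality on fixtures", {
  for (tl in c(0L, 2L)) {
    s <- toy_setup(tl)
    ens <- embed_conformers(s$topo, s$constraints,
                            generation_config(conf_factor = 4L, seed = 99L))
    expect_gte(length(ens), 1L)
    fd <- s$constraints$fixed_distances
    slack <- s$constraints$tolerance + 0.1
    probe <- racerts:::.chirality_probe(s$toy$structure$coords, s$frozen)
    for (conf in ens$structures) {
      d <- sqrt(rowSums((conf$coords[fd$i, , drop = FALSE] -
                           conf$coords[fd$j, , drop = FALSE])^2))
      expect_lte(max(abs(d - fd$target)), slack)
      rc <- s$constraints$reaction_center
      dev <- sqrt(rowSums((conf$coords[rc, , drop = FALSE] -
                             s$constraints$fixed_positions)^2))
      expect_lte(max(dev), 0.2)
      if (!is.null(probe)) {
        v <- racerts:::signed_volume(conf$coords[probe$quad, , drop = FALSE])
        expect_identical(sign(v), probe$sign)
      }
    }
  }
})

test_that("fully frozen toy reproduces the input geometry", {
  s <- toy_setup(0L)
  all_atoms <- seq_len(n_atoms(s$toy$structure))
  cons <- build_constraints(s$toy$structure, all_atoms, all_atoms)
  ens <- embed_conformers(s$topo, cons, generation_config(conf_factor = 3L, seed = 5L))
  for (conf in ens$structures) {
    expect_lte(rmsd(conf, s$toy$structure, heavy_only = FALSE), 0.2)
  }
})

test_that("flexible fixture discovers at least two torsional states", {
  s <- toy_setup(2L)
  ens <- embed_conformers(s$topo, s$constraints,
                          generation_config(conf_factor = 30L, seed = 17L))
  rot <- s$toy$free_rotors[[1L]]
  tors <- vapply(ens$structures, function(conf) {
    racerts:::dihedral_angle(conf$coords[rot[1L], ], conf$coords[rot[2L], ],
                             conf$coords[rot[3L], ], conf$coords[rot[4L], ])
  }, numeric(1))
  # bin into the three staggered basins; oracle count comes from the scan
  basins <- unique(floor(((tors %% 360) + 60) %% 360 / 120))
  expect_gte(length(basins), 2L)
})

test_that("embedding is deterministic for a fixed seed and leaves the RNG state alone", {
  s <- toy_setup(2L)
  cfg <- generation_config(conf_factor = 3L, seed = 123L)
  set.seed(777); before <- runif(1)
  set.seed(777)
  e1 <- embed_conformers(s$topo, s$constraints, cfg)
  after <- runif(1)
  e2 <- embed_conformers(s$topo, s$constraints, cfg)
  expect_identical(lapply(e1$structures, `[[`, "coords"),
                   lapply(e2$structures, `[[`, "coords"))
  expect_identical(before, after)   # session RNG restored
})

test_that("unsatisfiable embedding reports a diagnostic error", {
  s <- toy_setup(0L)
  cons <- s$constraints
  # poison a fixed distance so no 3D realisation exists
  cons$fixed_distances$target[1L] <- 50
  cfg <- generation_config(conf_factor = 1L, seed = 3L, max_embed_attempts = 5L)
  expect_error(embed_conformers(s$topo, cons, cfg), "unsatisfiable|no successful")
})
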