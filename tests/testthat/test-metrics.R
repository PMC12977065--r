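test_that("comp_cost: self-normalisation, arithmetic, validation", {
  tm <- data.frame(method = c("a", "a", "b", "b"),
                   reaction = c("r1", "r2", "r1", "r2"),
                   wall_seconds = c(10, 20, 20, 80))
  expect_equal(comp_cost(tm, "b", "b"), 1.0)
  expect_equal(comp_cost(tm, "b", "a"), 3.0)     # ratios 2 and 4
  set.seed(71)
  tm2 <- data.frame(method = rep(c("x", "ref"), each = 6),
                    reaction = rep(paste0("r", 1:6), 2),
                    wall_seconds = runif(12, 1, 100))
  expect_equal(comp_cost(tm2, "x", "ref"),
               mean(tm2$wall_seconds[1:6] / tm2$wall_seconds[7:12]))
  expect_error(comp_cost(tm[1:3, ], "a", "b"), "without a reference")
  tm$wall_seconds[1] <- 0
  expect_error(comp_cost(tm, "a", "b"), "> 0")
})

test_that("combine_ensembles: idempotent on duplicates, unions disjoint sets, matches oracle", {
  set.seed(81)
  base <- make_sn2_toy(1L)$structure
  ens <- random_test_ensemble(8, base)
  ens <- prune_rmsd(prune_energy(ens, 6))
  comb <- combine_ensembles(list(ens, ens))
  expect_equal(length(comb), length(ens))

  # disjoint ensembles within the window: union retained
  e1 <- ts_ensemble(list(base), 0.0)
  far <- base; far$coords <- base$coords + matrix(rnorm(length(base$coords), sd = 1.0), ncol = 3L)
  e2 <- ts_ensemble(list(far), 1.0)
  expect_equal(length(combine_ensembles(list(e1, e2))), 2L)

  # randomized overlapping ensembles against the exhaustive oracle
  for (rep in 1:20) {
    es <- replicate(3, random_test_ensemble(sample(3:8, 1), base), simplify = FALSE)
    comb <- combine_ensembles(es)
    pool_structs <- do.call(c, lapply(es, `[[`, "structures"))
    pool_e <- do.call(c, lapply(es, `[[`, "energies"))
    o <- order(pool_e)
    inwin <- which(pool_e[o] - min(pool_e) <= 6)
    keep <- oracle_prune_rmsd(pool_structs[o][inwin], 0.125)
    expect_equal(comb$energies, pool_e[o][inwin][keep])
  }

  other <- make_sn2_toy(2L)$structure
  expect_error(combine_ensembles(list(e1, ts_ensemble(list(other), 0))), "mixed atom")
})

test_that("butina_cluster: degenerate cases and brute-force oracle equivalence", {
  all_close <- matrix(0.2, 5, 5); diag(all_close) <- 0
  expect_equal(max(butina_cluster(all_close, 1.0)), 1L)
  all_far <- matrix(5, 5, 5); diag(all_far) <- 0
  expect_equal(max(butina_cluster(all_far, 1.0)), 5L)

  set.seed(91)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    pts <- matrix(runif(n * 2, 0, 3), n)
    M <- as.matrix(dist(pts))
    expect_partition_equal(butina_cluster(M, 1.0), oracle_butina(M, 1.0))
  }
  # partition property on structures
  base <- make_sn2_toy(1L)$structure
  structs <- replicate(6, { s <- base
    s$coords <- s$coords + matrix(rnorm(length(s$coords), sd = 0.5), ncol = 3L); s },
    simplify = FALSE)
  cl <- butina_cluster(structs, 1.0)
  expect_equal(length(cl), 6L)
  expect_true(all(cl >= 1L))
})

test_that("space_exploration: self-comparison is perfect, algebra and degenerate cases hold", {
  set.seed(101)
  base <- make_sn2_toy(1L)$structure
  comb <- random_test_ensemble(6, base)
  comb <- prune_rmsd(prune_energy(comb, 6))
  res <- space_exploration(list(self = comb), comb)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  expect_equal(res$f1, 1)

  # method hitting c of C clusters with all members matched: F1 = 2(c/C)/(1 + c/C)
  cl <- butina_cluster(comb)
  C <- max(cl)
  pick <- which(cl == cl[1L])           # members of one cluster only
  sub <- comb[pick]
  res2 <- space_exploration(list(partial = sub), comb)
  cC <- res2$n_clusters / C
  expect_equal(res2$precision, 1)
  expect_equal(res2$f1, 2 * cC / (1 + cC))

  # zero matches -> F1 = 0
  off <- comb
  off$energies <- off$energies + 1000   # identity fails on energy
  res3 <- space_exploration(list(none = off), comb)
  expect_equal(res3$f1, 0)

  expect_error(space_exploration(list(), comb[1][-1]))
})

test_that("js_divergence: identity, disjoint maximum, oracle summation, symmetry", {
  expect_equal(js_divergence(c(0.1, 0.5, 1.1), c(0.1, 0.5, 1.1)), 0)
  expect_equal(js_divergence(rep(0.1, 50), rep(5.1, 50)), 1.0)

  # half-overlapping synthetic histograms vs direct-summation oracle
  p <- c(0.1, 0.1, 0.6, 0.6); q <- c(0.6, 0.6, 1.1, 1.1)
  bw <- 0.25
  hi <- max(p, q, bw)
  breaks <- seq(0, hi + bw, by = bw)
  hp <- tabulate(findInterval(p, breaks, rightmost.closed = TRUE), length(breaks)) / length(p)
  hq <- tabulate(findInterval(q, breaks, rightmost.closed = TRUE), length(breaks)) / length(q)
  m <- (hp + hq) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  expect_equal(js_divergence(p, q), (kl(hp, m) + kl(hq, m)) / 2, tolerance = 1e-12)

  set.seed(111)
  for (rep in 1:20) {
    x <- runif(sample(5:40, 1), 0, 4); y <- runif(sample(5:40, 1), 0, 4)
    expect_equal(js_divergence(x, y), js_divergence(y, x), tolerance = 1e-12)
    expect_gte(js_divergence(x, y), 0)
    expect_lte(js_divergence(x, y), 1)
    expect_equal(js_divergence(x, x), 0)
  }
  expect_error(js_divergence(numeric(0), 1), "empty")
})

test_that("success_rate arithmetic and validation", {
  oc <- data.frame(reaction = c("r1", "r2"), n_successful = c(4L, 2L),
                   n_total = c(4L, 4L))
  res <- success_rate(oc)
  expect_equal(res$rate, 0.75)
  expect_equal(res$n_reactions_with_success, 2L)
  expect_equal(success_rate(data.frame(reaction = "r", n_successful = 3L,
                                       n_total = 3L))$rate, 1.0)
  expect_error(success_rate(data.frame(reaction = "r", n_successful = 1L,
                                       n_total = 0L)), ">= 1")
})

test_that("top_n_accuracy: planted matches against a brute-force check", {
  set.seed(121)
  base <- make_sn2_toy(1L)$structure
  mk <- function(k) { s <- base; s$coords <- base$coords +
    matrix(rnorm(length(base$coords), sd = 0.4 * k), ncol = 3L); s }
  # reaction 1: method A has the best at rank 1, B at rank 4, C never
  distinct <- lapply(1:6, mk)
  best <- list(structure = distinct[[1L]], energy = 2.0)
  ensA <- ts_ensemble(distinct[1:3], c(2.0, 2.5, 3))
  ensB <- ts_ensemble(distinct[c(2, 3, 4, 1, 5)], c(0.5, 1, 1.5, 2.0, 3))
  ensC <- ts_ensemble(distinct[5:6], c(2.0, 2.5))
  rankings <- list(r1 = list(A = ensA, B = ensB, C = ensC))
  top1 <- top_n_accuracy(rankings, list(best), n = 1L)
  top5 <- top_n_accuracy(rankings, list(best), n = 5L)
  expect_equal(unname(top1), c(1, 0, 0))
  expect_equal(unname(top5), c(1, 1, 0))

  # brute-force cross-check over the same rankings
  brute <- vapply(rankings$r1, function(e) {
    hits <- vapply(seq_along(e$structures), function(k)
      conformers_identical(e$structures[[k]], best$structure,
                           e$energies[k], best$energy), logical(1))
    if (any(hits)) which(hits)[1L] else Inf
  }, numeric(1))
  expect_equal(unname(top1), as.numeric(brute <= 1))
  expect_equal(unname(top5), as.numeric(brute <= 5))
})

test_that("boltzmann_average: closed forms and temperature limits", {
  expect_equal(boltzmann_average(3.7), 3.7)
  expect_equal(boltzmann_average(c(0, 0)), 0)
  # two-state closed form at 298.15 K
  R <- 0.0019872041; T_ <- 298.15
  w <- exp(-100 / (R * T_))
  expect_equal(boltzmann_average(c(0, 100), T_), 100 * w / (1 + w), tolerance = 1e-10)
  expect_lt(boltzmann_average(c(0, 100), T_), 1e-10)

  set.seed(131)
  e <- runif(8, -3, 12)
  expect_equal(boltzmann_average(e, 1e-3), min(e), tolerance = 1e-6)
  expect_equal(boltzmann_average(e / 20, 1e9), mean(e / 20), tolerance = 1e-6)
  expect_gte(boltzmann_average(e), min(e))
  expect_lte(boltzmann_average(e), max(e))
  expect_error(boltzmann_average(numeric(0)), "at least one")
  expect_error(boltzmann_average(1, temperature = 0), "> 0")
})

test_that("delta_e_lowe: medians match direct computation, exclusions logged as NA", {
  lows <- list(c(a = 1.0, b = 3.2), c(a = 2.0, b = 2.0), c(b = 5.0))
  overall <- c(1.0, 1.5, 4.0)
  res <- delta_e_lowe(lows, overall)
  expect_equal(unname(res$per_reaction[1, "a"]), 0)
  expect_equal(unname(res$per_reaction[1, "b"]), 2.2)
  expect_true(is.na(res$per_reaction[3, "a"]))
  expect_equal(unname(res$median["a"]), stats::median(c(0, 0.5)))
  expect_equal(unname(res$median["b"]), stats::median(c(2.2, 0.5, 1.0)))
  expect_true(all(res$per_reaction >= 0, na.rm = TRUE))
})

test_that("delta_e_marc composes Boltzmann averages; single-member subsets reduce to raw differences", {
  subsets <- list(list(m1 = c(1, 2), m2 = c(4)))
  union <- list(c(1, 2, 4))
  res <- delta_e_marc(subsets, union, temperature = 298.15)
  eb <- boltzmann_average(c(1, 2, 4))
  expect_equal(unname(res$per_reaction[1, "m1"]), boltzmann_average(c(1, 2)) - eb)
  expect_equal(unname(res$per_reaction[1, "m2"]), 4 - eb)
  # method subset == union -> 0
  res2 <- delta_e_marc(list(list(m = c(0.3, 1.7))), list(c(0.3, 1.7)))
  expect_equal(unname(res2$per_reaction[1, "m"]), 0)
  expect_error(delta_e_marc(list(list(m = 1)), list(numeric(0))), "empty union")
})
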