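# Benchmark metrics for comparing conformer generators: cost normalisation,
# combined reference-ensemble construction, Butina clustering, space
# exploration (precision/recall/F1), space distribution (Jensen-Shannon
# divergence of RMSD distributions), success rate, top-N accuracy, and
# Boltzmann-averaged activation-energy errors.

.GAS_R <- 0.0019872041  # kcal/(mol K)

#' Normalised computational cost
#'
#' Mean over reactions of the wall-time ratio `t_r^i / t_r^ref`.
#'
#' @param timings data frame with columns `method`, `reaction`, `wall_seconds`
#'   (all > 0).
#' @param method method identifier to score.
#' @param reference reference method identifier (cost 1 by construction when
#'   `method == reference`).
#' @return single numeric cost factor.
#' @export
comp_cost <- function(timings, method, reference) {
  stopifnot(is.data.frame(timings),
            all(c("method", "reaction", "wall_seconds") %in% names(timings)))
  if (any(timings$wall_seconds <= 0)) stop("wall times must be > 0")
  ti <- timings[timings$method == method, ]
  tr <- timings[timings$method == reference, ]
  if (nrow(ti) == 0L) stop("no timings for method '", method, "'")
  m <- match(ti$reaction, tr$reaction)
  if (anyNA(m)) {
    stop("reaction(s) without a reference timing: ",
         paste(ti$reaction[is.na(m)], collapse = ", "))
  }
  mean(ti$wall_seconds / tr$wall_seconds[m])
}

#' Combined reference ensemble
#'
#' Concatenates the per-method ensembles of one reaction, energy-sorts,
#' prunes to a 6 kcal/mol window and deduplicates at 0.125 Angstrom
#' heavy-atom RMSD. The result approximates the complete reference TS
#' conformer ensemble for that reaction.
#'
#' @param ensembles list of [ts_ensemble]s sharing one atom list.
#' @param window energy window in kcal/mol (default 6).
#' @param rmsd_threshold duplicate threshold in Angstrom (default 0.125).
#' @return a [ts_ensemble].
#' @export
combine_ensembles <- function(ensembles, window = 6,
                              rmsd_threshold = .RMSD_THRESHOLD) {
  stopifnot(length(ensembles) >= 1L,
            all(vapply(ensembles, inherits, logical(1), "ts_ensemble")))
  sy <- ensembles[[1L]]$structures[[1L]]$symbols
  for (e in ensembles) {
    if (!identical(e$structures[[1L]]$symbols, sy)) {
      stop("ensembles have mixed atom lists; cannot combine")
    }
  }
  all_structs <- do.call(c, lapply(ensembles, `[[`, "structures"))
  all_e <- do.call(c, lapply(ensembles, `[[`, "energies"))
  all_l <- do.call(c, lapply(ensembles, `[[`, "labels"))
  if (anyNA(all_e)) stop("all member energies must be defined")
  combined <- ts_ensemble(all_structs, all_e, make.unique(all_l),
                          reference = ensembles[[1L]]$reference)
  prune_rmsd(prune_energy(combined, window),
             prune_config(rmsd_threshold = rmsd_threshold,
                          energy_window = window))
}

#' Butina sphere-exclusion clustering
#'
#' Repeatedly selects the member with the most unassigned neighbours within
#' the RMSD threshold as a centroid, assigns its whole neighbourhood to a new
#' cluster, removes it, and repeats; singletons are allowed. Ties in
#' neighbour count are broken by the lowest member index, making the
#' partition deterministic.
#'
#' @param x either a list of [ts_structure]s (pairwise heavy-atom RMSD is
#'   computed), a [ts_ensemble], or a precomputed symmetric distance matrix.
#' @param threshold neighbourhood radius (default 1.0 Angstrom).
#' @return integer vector of 1-based cluster ids, one per member (a partition:
#'   disjoint and covering); cluster 1 is the first-extracted centroid's.
#' @export
butina_cluster <- function(x, threshold = 1.0) {
  if (inherits(x, "ts_ensemble")) x <- x$structures
  if (is.list(x)) {
    n <- length(x)
    M <- matrix(0, n, n)
    if (n > 1L) {
      for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
        M[a, b] <- M[b, a] <- rmsd(x[[a]], x[[b]])
      }
    }
  } else {
    M <- as.matrix(x)
    n <- nrow(M)
    if (n != ncol(M)) stop("distance matrix must be square")
  }
  if (n < 1L) stop("butina_cluster needs at least one member")
  cluster <- integer(n)
  unassigned <- rep(TRUE, n)
  next_id <- 0L
  while (any(unassigned)) {
    idx <- which(unassigned)
    counts <- vapply(idx, function(a) sum(M[a, idx] < threshold) - 1L, integer(1))
    centroid <- idx[which.max(counts)]   # which.max: lowest index wins ties
    members <- idx[M[centroid, idx] < threshold]
    members <- union(centroid, members)
    next_id <- next_id + 1L
    cluster[members] <- next_id
    unassigned[members] <- FALSE
  }
  cluster
}

# Match every member of `ensemble` to the first identical member of `combined`
# (identity = RMSD < 0.125 A and dE < 0.05 kcal/mol); returns the combined
# index or NA.
.match_members <- function(ensemble, combined) {
  vapply(seq_along(ensemble$structures), function(k) {
    for (m in seq_along(combined$structures)) {
      if (conformers_identical(ensemble$structures[[k]], combined$structures[[m]],
                               ensemble$energies[k], combined$energies[m])) {
        return(m)
      }
    }
    NA_integer_
  }, integer(1))
}

#' Space exploration (precision / recall / F1)
#'
#' The combined ensemble is Butina-clustered; a method conformer "is in a
#' cluster" iff it is identical (RMSD < 0.125 Angstrom, dE < 0.05 kcal/mol)
#' to some combined-ensemble member, inheriting that member's cluster.
#' Precision is the matched fraction of the method's conformers, recall the
#' fraction of combined clusters hit, and F1 their harmonic mean (0 when
#' PRE + REC = 0).
#'
#' @param method_ensembles named list: method -> [ts_ensemble] (one reaction).
#' @param combined the combined reference ensemble from [combine_ensembles()].
#' @param cluster_threshold Butina radius (default 1.0 Angstrom).
#' @return data frame with one row per method: `method`, `n_in_cluster`,
#'   `n_total`, `n_clusters`, `n_total_clusters`, `precision`, `recall`, `f1`.
#' @export
space_exploration <- function(method_ensembles, combined,
                              cluster_threshold = 1.0) {
  stopifnot(inherits(combined, "ts_ensemble"))
  if (length(combined) == 0L) stop("combined ensemble is empty")
  cl <- butina_cluster(combined, cluster_threshold)
  n_total_clusters <- max(cl)
  rows <- lapply(names(method_ensembles), function(method) {
    ens <- method_ensembles[[method]]
    hit <- .match_members(ens, combined)
    n_in <- sum(!is.na(hit))
    n_cl <- length(unique(cl[hit[!is.na(hit)]]))
    pre <- n_in / length(ens)
    rec <- n_cl / n_total_clusters
    f1 <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
    data.frame(method = method, n_in_cluster = n_in, n_total = length(ens),
               n_clusters = n_cl, n_total_clusters = n_total_clusters,
               precision = pre, recall = rec, f1 = f1)
  })
  do.call(rbind, rows)
}

#' RMSD-to-reference distribution
#'
#' Heavy-atom RMSD of every ensemble member to the reference input structure.
#'
#' @param ensemble a [ts_ensemble].
#' @param reference a [ts_structure] (defaults to `ensemble$reference`).
#' @return numeric vector of RMSD samples (Angstrom).
#' @export
rmsd_to_reference <- function(ensemble, reference = ensemble$reference) {
  stopifnot(inherits(ensemble, "ts_ensemble"))
  if (is.null(reference)) stop("no reference structure available")
  vapply(ensemble$structures, rmsd, numeric(1), b = reference)
}

#' Jensen-Shannon divergence of two RMSD sample sets
#'
#' Samples are histogrammed on shared fixed-width bins spanning `[0, max)` of
#' both sample sets, normalised, and compared with base-2 logarithms (so the
#' value lies in `[0, 1]`, reaching 1 for fully disjoint supports). Empty
#' bins contribute nothing via the `0 log 0 = 0` convention.
#'
#' @param p_samples,q_samples nonnegative numeric sample vectors (nonempty).
#' @param bin_width histogram bin width in Angstrom (default 0.25).
#' @return JS divergence in `[0, 1]`.
#' @export
js_divergence <- function(p_samples, q_samples, bin_width = 0.25) {
  if (length(p_samples) == 0L || length(q_samples) == 0L) {
    stop("empty sample set")
  }
  if (any(p_samples < 0) || any(q_samples < 0)) stop("RMSD samples must be >= 0")
  hi <- max(p_samples, q_samples, bin_width)
  breaks <- seq(0, hi + bin_width, by = bin_width)
  p <- tabulate(findInterval(p_samples, breaks, rightmost.closed = TRUE),
                length(breaks)) / length(p_samples)
  q <- tabulate(findInterval(q_samples, breaks, rightmost.closed = TRUE),
                length(breaks)) / length(q_samples)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Validity success rate
#'
#' Mean over reactions of the fraction of filtered conformers that passed the
#' downstream validation pipeline (labels are inputs; the pipeline itself is
#' external).
#'
#' @param outcomes data frame with columns `reaction`, `n_successful`,
#'   `n_total` (`n_total >= 1`, `n_successful <= n_total`).
#' @return list with `rate` (mean fraction) and `n_reactions_with_success`.
#' @export
success_rate <- function(outcomes) {
  stopifnot(is.data.frame(outcomes),
            all(c("reaction", "n_successful", "n_total") %in% names(outcomes)))
  if (any(outcomes$n_total < 1L)) stop("n_total must be >= 1 for every reaction")
  if (any(outcomes$n_successful > outcomes$n_total) ||
      any(outcomes$n_successful < 0L)) {
    stop("need 0 <= n_successful <= n_total")
  }
  frac <- outcomes$n_successful / outcomes$n_total
  list(rate = mean(frac), n_reactions_with_success = sum(outcomes$n_successful > 0L))
}

#' Top-N accuracy
#'
#' For each reaction, a method scores a hit iff one of its first `n`
#' conformers -- in the *generator's own* energy order, neglecting downstream
#' reordering -- is identical to the overall lowest-energy conformer. The
#' rank of the first identical match is also reported (`Inf` when absent;
#' an empty ranking counts as a miss).
#'
#' @param rankings list over reactions; each element is a named list
#'   method -> [ts_ensemble] (the method's ranked conformers, with energies).
#' @param overall_lowest list over reactions of `list(structure =, energy =)`
#'   for the overall lowest-energy conformer.
#' @param n integer cutoff (1 and 5 are the conventional choices).
#' @return named numeric vector: per-method mean hit fraction over reactions.
#' @export
top_n_accuracy <- function(rankings, overall_lowest, n = 1L) {
  stopifnot(length(rankings) == length(overall_lowest), length(rankings) >= 1L)
  methods <- names(rankings[[1L]])
  hits <- sapply(methods, function(method) {
    mean(vapply(seq_along(rankings), function(r) {
      ens <- rankings[[r]][[method]]
      best <- overall_lowest[[r]]
      if (is.null(ens) || length(ens) == 0L) return(0)
      rank_of_match <- Inf
      for (k in seq_along(ens$structures)) {
        if (conformers_identical(ens$structures[[k]], best$structure,
                                 ens$energies[k], best$energy)) {
          rank_of_match <- k; break
        }
      }
      as.numeric(rank_of_match <= n)
    }, numeric(1)))
  })
  stats::setNames(as.numeric(hits), methods)
}

#' Boltzmann-averaged ensemble energy
#'
#' `sum(E_k w_k)` with `w_k = exp(-(E_k - E_min)/RT) / sum(...)`; the minimum
#' shift makes the exponentials numerically safe. The result always lies in
#' `[min(E), max(E)]`, tends to `min(E)` as `T -> 0+` and to the arithmetic
#' mean as `T -> Inf`.
#'
#' @param energies nonempty numeric vector (kcal/mol).
#' @param temperature Kelvin (> 0, default 298.15).
#' @return kcal/mol.
#' @export
boltzmann_average <- function(energies, temperature = 298.15) {
  if (length(energies) == 0L) stop("boltzmann_average needs at least one energy")
  if (!all(is.finite(energies))) stop("energies must be finite")
  if (temperature <= 0) stop("temperature must be > 0")
  w <- exp(-(energies - min(energies)) / (.GAS_R * temperature))
  sum(energies * w) / sum(w)
}

#' Lowest-conformer activation-energy error
#'
#' Per reaction and method: `E(lowest valid conformer of the method) -
#' E(overall lowest valid conformer)`, nonnegative whenever the overall
#' lowest is drawn from the union of methods. Methods with zero valid
#' conformers for a reaction are excluded for that reaction.
#'
#' @param method_lowest list over reactions; each element a named numeric
#'   vector method -> lowest valid conformer energy (kcal/mol), `NA` or
#'   missing methods allowed.
#' @param overall_lowest numeric vector: per-reaction overall lowest energy.
#' @return list with `per_reaction` (matrix reactions x methods of delta E),
#'   `median` and `boxplot` (per-method Tukey five-number statistics over the
#'   pooled per-reaction values).
#' @export
delta_e_lowe <- function(method_lowest, overall_lowest) {
  stopifnot(length(method_lowest) == length(overall_lowest))
  methods <- unique(unlist(lapply(method_lowest, names)))
  per <- matrix(NA_real_, length(method_lowest), length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_along(method_lowest)) {
    e <- method_lowest[[r]]
    per[r, names(e)] <- e - overall_lowest[r]
  }
  med <- apply(per, 2L, stats::median, na.rm = TRUE)
  box <- lapply(methods, function(m) {
    v <- per[, m]; v <- v[!is.na(v)]
    if (length(v) == 0L) return(rep(NA_real_, 5L))
    as.numeric(grDevices::boxplot.stats(v)$stats)
  })
  names(box) <- methods
  list(per_reaction = per, median = med, boxplot = box)
}

#' Boltzmann-averaged representative-conformer error
#'
#' Per reaction and method: difference between the Boltzmann average of the
#' method's representative-conformer energies and the Boltzmann average of
#' the deduplicated union of all methods' representatives. Representative
#' selection itself is external; arbitrary pre-selected subsets are accepted.
#'
#' @param method_subsets list over reactions; each element a named list
#'   method -> numeric energy vector (kcal/mol, nonempty).
#' @param all_subsets list over reactions of the pruned union energy vector.
#' @param temperature Kelvin (default 298.15).
#' @return list with `per_reaction` matrix, per-method `mean` and `median`.
#' @export
delta_e_marc <- function(method_subsets, all_subsets, temperature = 298.15) {
  stopifnot(length(method_subsets) == length(all_subsets))
  methods <- unique(unlist(lapply(method_subsets, names)))
  per <- matrix(NA_real_, length(method_subsets), length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_along(method_subsets)) {
    if (length(all_subsets[[r]]) == 0L) stop("empty union subset for reaction ", r)
    eb_all <- boltzmann_average(all_subsets[[r]], temperature)
    for (m in names(method_subsets[[r]])) {
      per[r, m] <- boltzmann_average(method_subsets[[r]][[m]], temperature) - eb_all
    }
  }
  list(per_reaction = per,
       mean = apply(per, 2L, mean, na.rm = TRUE),
       median = apply(per, 2L, stats::median, na.rm = TRUE))
}
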