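# Ensemble pruning: energy window, heavy-atom RMSD deduplication, and the
# conformer-identity predicate shared with the metrics module.

.RMSD_THRESHOLD <- 0.125   # Angstrom, duplicate criterion
.IDENTITY_DE <- 0.05       # kcal/mol, identity criterion

#' Pruning configuration
#'
#' @param rmsd_threshold duplicate threshold in Angstrom (default 0.125): a
#'   conformer with a smaller heavy-atom RMSD to a retained lower-energy
#'   conformer is removed.
#' @param energy_window kcal/mol above the ensemble minimum (default 20,
#'   deliberately conservative for force-field energies; 6 is used after
#'   tight-binding post-optimisation and when building combined reference
#'   ensembles).
#' @param heavy_only use heavy atoms only in RMSD (default `TRUE`).
#' @return object of class `prune_config`.
#' @export
prune_config <- function(rmsd_threshold = .RMSD_THRESHOLD, energy_window = 20,
                         heavy_only = TRUE) {
  if (rmsd_threshold <= 0 || energy_window <= 0) stop("thresholds must be > 0")
  structure(list(rmsd_threshold = rmsd_threshold, energy_window = energy_window,
                 heavy_only = isTRUE(heavy_only)),
            class = "prune_config")
}

#' Energy-window pruning
#'
#' Retains exactly the members with `E - min(E) <= window`, preserving order.
#'
#' @param ensemble a [ts_ensemble] with all energies defined.
#' @param window energy window in kcal/mol.
#' @return the pruned [ts_ensemble].
#' @export
prune_energy <- function(ensemble, window = 20) {
  stopifnot(inherits(ensemble, "ts_ensemble"))
  if (anyNA(ensemble$energies)) {
    stop("prune_energy requires defined energies for every member")
  }
  keep <- ensemble$energies - min(ensemble$energies) <= window
  ensemble[which(keep)]
}

#' RMSD duplicate pruning
#'
#' Greedy sweep in ascending energy: the lowest-energy member is always
#' retained and each subsequent member is retained iff its RMSD to *every*
#' already-retained member is at least the threshold. The input must already
#' be energy-sorted (sorting is the caller's responsibility, keeping this
#' operation pure); ties in energy are resolved by input order.
#'
#' @param ensemble an energy-sorted [ts_ensemble].
#' @param config a [prune_config] (or a bare numeric RMSD threshold).
#' @return the pruned [ts_ensemble]; the minimum pairwise RMSD among retained
#'   members is >= the threshold, and the operation is idempotent.
#' @export
prune_rmsd <- function(ensemble, config = prune_config()) {
  stopifnot(inherits(ensemble, "ts_ensemble"))
  if (is.numeric(config)) config <- prune_config(rmsd_threshold = config)
  if (anyNA(ensemble$energies) || is.unsorted(ensemble$energies)) {
    stop("prune_rmsd requires an ascending energy-sorted ensemble")
  }
  retained <- integer(0)
  for (k in seq_along(ensemble$structures)) {
    dup <- FALSE
    for (m in retained) {
      if (rmsd(ensemble$structures[[k]], ensemble$structures[[m]],
               heavy_only = config$heavy_only) < config$rmsd_threshold) {
        dup <- TRUE; break
      }
    }
    if (!dup) retained <- c(retained, k)
  }
  ensemble[retained]
}

#' Conformer identity predicate
#'
#' Two conformers are identical iff their heavy-atom RMSD is below 0.125
#' Angstrom *and* their energies differ by less than 0.05 kcal/mol.
#'
#' @param a,b [ts_structure] objects with identical symbol sequences.
#' @param energy_a,energy_b energies in kcal/mol.
#' @param rmsd_threshold,energy_threshold the identity thresholds.
#' @param heavy_only use heavy atoms only (default `TRUE`).
#' @return logical(1).
#' @export
conformers_identical <- function(a, b, energy_a, energy_b,
                                 rmsd_threshold = .RMSD_THRESHOLD,
                                 energy_threshold = .IDENTITY_DE,
                                 heavy_only = TRUE) {
  abs(energy_a - energy_b) < energy_threshold &&
    rmsd(a, b, heavy_only = heavy_only) < rmsd_threshold
}
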