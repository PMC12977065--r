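#' Generate a TS conformer ensemble
#'
#' End-to-end pipeline: bond perception (optionally from a SMILES template),
#' frozen-atom derivation, constrained distance-geometry embedding,
#' frozen-core force-field refinement, single-point re-ranking, energy-window
#' pruning and RMSD deduplication.
#'
#' @param structure the TS guess (a [ts_structure]; its `charge` field is the
#'   total molecular charge).
#' @param reaction_center integer vector of 1-based reaction-center atom
#'   indices (nonempty).
#' @param smiles optional reactant- or product-side SMILES bonding template.
#' @param conf_factor multiplier on the rotatable-bond count (default 30).
#' @param energy_window pruning window in kcal/mol (default 20, matched to
#'   force-field energy inaccuracy).
#' @param rmsd_threshold duplicate threshold in Angstrom (default 0.125).
#' @param seed integer RNG seed for reproducible generation.
#' @param engine `"forcefield"` (organic tier with universal fallback),
#'   `"mock"`, `"external"`, or a list of [energy_engine]s.
#' @param tolerance slack on fixed distances in Angstrom (default 0.01).
#' @return list of class `racerts_result`: `ensemble` (pruned, energy-sorted
#'   [ts_ensemble]), `topology`, `frozen`, `constraints`, `diagnostics`
#'   (embedding stats, fallback/convergence flags, counts per stage).
#' @examples
#' toy <- make_sn2_toy(tail_length = 2)
#' res <- generate_ts_conformers(toy$structure, toy$reaction_center,
#'                               conf_factor = 5, seed = 1)
#' res$ensemble
#' @export
generate_ts_conformers <- function(structure, reaction_center, smiles = NULL,
                                   conf_factor = 30L, energy_window = 20,
                                   rmsd_threshold = 0.125, seed = NULL,
                                   engine = "forcefield", tolerance = 0.01) {
  stopifnot(inherits(structure, "ts_structure"))
  reaction_center <- validate_reaction_center(reaction_center, structure)
  topology <- perceive_bond_orders(structure, reaction_center)
  if (!is.null(smiles)) topology <- apply_smiles_template(topology, smiles)
  frozen <- frozen_atoms(topology, reaction_center)
  constraints <- build_constraints(structure, frozen, reaction_center,
                                   tolerance = tolerance)
  config <- generation_config(conf_factor = conf_factor, seed = seed)
  embedded <- embed_conformers(topology, constraints, config)

  engines <- if (is.character(engine)) {
    switch(engine,
           forcefield = default_engine_chain(),
           mock = list(mock_engine()),
           external = c(list(external_engine()), default_engine_chain()),
           stop("unknown engine '", engine, "'"))
  } else if (inherits(engine, "energy_engine")) list(engine) else engine

  refined <- lapply(embedded$structures, minimize_conformer,
                    topology = topology, frozen = frozen, engines = engines)
  ens <- ts_ensemble(lapply(refined, `[[`, "structure"),
                     vapply(refined, `[[`, numeric(1), "energy"),
                     labels = embedded$labels,
                     reference = structure)
  # single-point re-ranking with the engine actually used for refinement
  used <- refined[[1L]]$engine
  rank_engine <- engines[[match(used, vapply(engines, `[[`, character(1), "name"))]]
  ens <- rank_ensemble(ens, rank_engine, topology)
  n_refined <- length(ens)
  ens <- prune_energy(ens, energy_window)
  n_window <- length(ens)
  ens <- prune_rmsd(ens, prune_config(rmsd_threshold = rmsd_threshold,
                                      energy_window = energy_window))
  structure(
    list(ensemble = ens, topology = topology, frozen = frozen,
         constraints = constraints,
         diagnostics = list(
           embedding = attr(embedded, "embedding_stats"),
           engine = used,
           fallback_used = any(vapply(refined, `[[`, logical(1), "fallback_used")),
           all_converged = all(vapply(refined, `[[`, logical(1), "converged")),
           n_embedded = length(embedded), n_refined = n_refined,
           n_after_window = n_window, n_final = length(ens))),
    class = "racerts_result"
  )
}

#' @export
print.racerts_result <- function(x, ...) {
  d <- x$diagnostics
  cat("<racerts_result> engine ", d$engine,
      if (d$fallback_used) " (fallback)", ": ",
      d$n_embedded, " embedded -> ", d$n_after_window,
      " in window -> ", d$n_final, " unique conformer(s)\n", sep = "")
  print(x$ensemble)
  invisible(x)
}
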