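#' Frozen-core force-field refinement
#'
#' Minimises one conformer with the first engine in the chain that accepts all
#' of its atom types; engines that reject (e.g. the organic tier on a
#' transition metal) are skipped and `fallback_used` records the skip. Frozen
#' atoms are never part of the optimisation variables, so they are fixed
#' exactly (zero drift), and the frozen-pair distance matrix is untouched by
#' construction. The optimiser is L-BFGS-B with at most `maxit` steps and
#' projected-gradient tolerance `gtol`; non-converged conformers are kept but
#' flagged.
#'
#' @param conformer a [ts_structure].
#' @param topology the shared `ts_topology` (bonded terms are built from it).
#' @param frozen integer vector of frozen atom indices (may be empty).
#' @param engines ordered list of [energy_engine]s; default
#'   [default_engine_chain()].
#' @param maxit maximum optimiser iterations (default 2000).
#' @param gtol projected-gradient tolerance in kcal/mol/Angstrom (default 1e-4).
#' @return list of class `refined_conformer`: `structure`, `energy` (kcal/mol),
#'   `engine`, `fallback_used`, `converged`.
#' @export
minimize_conformer <- function(conformer, topology, frozen = integer(0),
                               engines = default_engine_chain(),
                               maxit = 2000L, gtol = 1e-4) {
  stopifnot(inherits(conformer, "ts_structure"), inherits(topology, "ts_topology"))
  if (inherits(engines, "energy_engine")) engines <- list(engines)
  picked <- NULL; fallback_used <- FALSE
  for (k in seq_along(engines)) {
    if (isTRUE(engines[[k]]$accepts(conformer$symbols))) { picked <- engines[[k]]; break }
    fallback_used <- TRUE
  }
  if (is.null(picked)) {
    bad <- unique(conformer$symbols[
      !vapply(conformer$symbols,
              function(s) any(vapply(engines, function(e) isTRUE(e$accepts(s)),
                                     logical(1))), logical(1))])
    stop("no engine in the chain accepts atom type(s): ",
         paste(bad, collapse = ", "))
  }
  ctx <- engine_setup(picked, topology)
  coords <- conformer$coords
  n <- nrow(coords)
  free <- setdiff(seq_len(n), as.integer(frozen))
  e_start <- picked$energy(coords, ctx)
  converged <- TRUE
  if (length(free) > 0L && isTRUE(picked$minimizes)) {
    x0 <- as.numeric(t(coords[free, , drop = FALSE]))
    unpack <- function(x) {
      cc <- coords
      cc[free, ] <- matrix(x, ncol = 3L, byrow = TRUE)
      cc
    }
    fn <- function(x) picked$energy(unpack(x), ctx)
    gr <- function(x) {
      g <- engine_gradient(picked, unpack(x), ctx)
      as.numeric(t(g[free, , drop = FALSE]))
    }
    opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, pgtol = gtol, factr = 1e4))
    if (opt$value <= e_start + 1e-6) {
      coords <- unpack(opt$par)
      converged <- opt$convergence == 0L
    } else {
      converged <- FALSE  # pathological line-search blow-up: keep input
    }
  }
  e_final <- picked$energy(coords, ctx)
  out <- conformer
  out$coords <- coords
  structure(
    list(structure = out, energy = e_final, engine = picked$name,
         fallback_used = fallback_used, converged = converged),
    class = "refined_conformer"
  )
}

#' Re-rank an ensemble by single-point energies
#'
#' Attaches single-point energies from `engine` to every member and re-sorts
#' ascending (stable: ties keep their prior order). A member on which the
#' engine fails is dropped with a warning rather than silently reordered.
#'
#' @param ensemble a [ts_ensemble].
#' @param engine an [energy_engine].
#' @param topology `ts_topology` for the engine's context (required by the
#'   force-field engines, ignored by context-free engines).
#' @return a [ts_ensemble] with the new energies.
#' @export
rank_ensemble <- function(ensemble, engine, topology = NULL) {
  stopifnot(inherits(ensemble, "ts_ensemble"), inherits(engine, "energy_engine"))
  ctx <- if (is.null(engine$setup)) NULL else engine$setup(topology)
  energies <- rep(NA_real_, length(ensemble))
  ok <- rep(TRUE, length(ensemble))
  for (k in seq_along(ensemble$structures)) {
    e <- tryCatch(engine$energy(ensemble$structures[[k]]$coords, ctx),
                  error = function(err) NA_real_)
    if (is.na(e) || !is.finite(e)) {
      ok[k] <- FALSE
      warning("engine '", engine$name, "' failed on member ", k, " ('",
              ensemble$labels[k], "'); member dropped")
    } else energies[k] <- e
  }
  if (!any(ok)) stop("engine '", engine$name, "' failed on every member")
  ts_ensemble(ensemble$structures[ok], energies[ok], ensemble$labels[ok],
              reference = ensemble$reference)
}
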