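#' Molecular structure container
#'
#' A `ts_structure` holds one molecular geometry: ordered element symbols,
#' Cartesian coordinates in Angstrom, the total molecular charge, and a
#' free-text comment. All atom indices in this package are 1-based, following
#' xyz body line order.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix with one row per atom and 3 columns (Angstrom).
#' @param charge integer total molecular charge.
#' @param comment free-text metadata line (single line).
#' @return an object of class `ts_structure`.
#' @examples
#' water <- ts_structure(c("O", "H", "H"),
#'                       rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' n_atoms(water)
#' @export
ts_structure <- function(symbols, coords, charge = 0L, comment = "") {
  symbols <- as.character(symbols)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(symbols) == 0L) stop("structure must contain at least one atom")
  if (nrow(coords) != length(symbols) || ncol(coords) != 3L) {
    stop("coords must be a ", length(symbols), "x3 matrix (got ",
         nrow(coords), "x", ncol(coords), ")")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!all(is_known_element(symbols))) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[!is_known_element(symbols)]), collapse = ", "))
  }
  if (length(charge) != 1L || !is.finite(charge) || charge != round(charge)) {
    stop("charge must be a single integer")
  }
  dimnames(coords) <- NULL
  structure(
    list(symbols = symbols, coords = coords, charge = as.integer(charge),
         comment = as.character(comment)[1L]),
    class = "ts_structure"
  )
}

#' @rdname ts_structure
#' @param x a `ts_structure`.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "ts_structure"))
  length(x$symbols)
}

#' @export
print.ts_structure <- function(x, ...) {
  cat("<ts_structure> ", n_atoms(x), " atoms, charge ", x$charge, "\n", sep = "")
  cat("  formula:", paste0(names(table(x$symbols)), table(x$symbols), collapse = " "), "\n")
  invisible(x)
}

same_symbols <- function(a, b) identical(a$symbols, b$symbols)

#' Conformer ensemble container
#'
#' An energy-sorted collection of conformers of one bonded structure. Members
#' with defined energies are sorted ascending (stable sort); if any energy is
#' missing the ensemble is flagged unranked and kept in input order.
#'
#' @param structures list of [ts_structure] objects with identical symbol
#'   sequences.
#' @param energies numeric vector of energies in kcal/mol (`NA` allowed, which
#'   flags the ensemble unranked).
#' @param labels optional character labels, one per member.
#' @param reference optional [ts_structure]: the generator's input geometry.
#' @return an object of class `ts_ensemble` with fields `structures`,
#'   `energies`, `labels`, `reference` and logical `ranked`.
#' @export
ts_ensemble <- function(structures, energies = rep(NA_real_, length(structures)),
                        labels = NULL, reference = NULL) {
  if (length(structures) == 0L) stop("ensemble must be nonempty")
  if (!all(vapply(structures, inherits, logical(1), "ts_structure"))) {
    stop("all members must be ts_structure objects")
  }
  sy <- structures[[1L]]$symbols
  for (s in structures) {
    if (!identical(s$symbols, sy)) {
      stop("all ensemble members must share an identical symbol sequence")
    }
  }
  energies <- as.numeric(energies)
  if (length(energies) != length(structures)) {
    stop("energies must have one entry per structure")
  }
  if (any(is.infinite(energies))) stop("energies must be finite or NA")
  if (is.null(labels)) labels <- sprintf("conf_%03d", seq_along(structures))
  ranked <- !anyNA(energies)
  if (ranked) {
    o <- order(energies)  # stable
    structures <- structures[o]
    energies <- energies[o]
    labels <- labels[o]
  }
  structure(
    list(structures = structures, energies = energies, labels = labels,
         reference = reference, ranked = ranked),
    class = "ts_ensemble"
  )
}

#' @export
length.ts_ensemble <- function(x) length(x$structures)

#' @export
`[.ts_ensemble` <- function(x, i) {
  ts_ensemble(x$structures[i], x$energies[i], x$labels[i], reference = x$reference)
}

#' @export
print.ts_ensemble <- function(x, ...) {
  cat("<ts_ensemble> ", length(x), " conformer(s), ",
      if (x$ranked) "energy-ranked" else "unranked", "\n", sep = "")
  if (x$ranked) {
    rel <- x$energies - min(x$energies)
    cat("  relative energies (kcal/mol): ",
        paste(sprintf("%.2f", utils::head(rel, 8L)), collapse = ", "),
        if (length(x) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}
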