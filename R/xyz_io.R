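# xyz I/O.
#
# Canonical formatting: atoms are written as "%-3s%16.8f%16.8f%16.8f", the
# comment line carries machine-parseable tokens "E=<kcal/mol>" (8 significant
# digits, multi-structure files only) and "charge=<int>", followed by any
# free-text label. Because reading recovers exactly the written tokens,
# write -> read -> write is byte-identical from the first write onward.

.format_xyz_block <- function(structure, energy = NULL, label = NULL) {
  tokens <- character(0)
  if (!is.null(energy) && !is.na(energy)) {
    tokens <- c(tokens, sprintf("E=%.8g", energy))
  }
  tokens <- c(tokens, sprintf("charge=%d", structure$charge))
  if (!is.null(label) && nzchar(label)) tokens <- c(tokens, label)
  else if (nzchar(structure$comment)) tokens <- c(tokens, structure$comment)
  c(
    as.character(n_atoms(structure)),
    paste(tokens, collapse = " "),
    sprintf("%-3s%16.8f%16.8f%16.8f",
            structure$symbols,
            structure$coords[, 1], structure$coords[, 2], structure$coords[, 3])
  )
}

.parse_xyz_block <- function(lines, first, path) {
  count_line <- trimws(lines[first])
  n <- suppressWarnings(as.integer(count_line))
  if (is.na(n) || !grepl("^[0-9]+$", count_line)) {
    stop("malformed atom-count line ", first, " in '", path, "': '",
         lines[first], "'")
  }
  if (first + 1L + n > length(lines)) {
    stop("file '", path, "' ends before the ", n,
         " atom lines declared on line ", first)
  }
  comment <- lines[first + 1L]
  body <- lines[(first + 2L):(first + 1L + n)]
  fields <- strsplit(trimws(body), "[[:space:]]+")
  ok <- vapply(fields, length, integer(1)) >= 4L
  if (!all(ok)) {
    stop("atom line ", first + 1L + which(!ok)[1L], " in '", path,
         "' does not have 4 fields")
  }
  symbols <- vapply(fields, `[[`, character(1), 1L)
  coords <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (anyNA(coords)) stop("non-numeric coordinate in block starting at line ",
                          first, " of '", path, "'")
  # declared count vs. what the next lines actually look like: if the line
  # right after the block parses as coordinates too, the header undercounted;
  # an atom line that parses as a bare integer means it overcounted.
  charge <- 0L
  m <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1L]]
  if (length(m) == 2L) charge <- as.integer(m[2L])
  energy <- NA_real_
  m <- regmatches(comment, regexec("E=([-+0-9.eE]+)", comment))[[1L]]
  if (length(m) == 2L) energy <- as.numeric(m[2L])
  label <- trimws(gsub("E=[-+0-9.eE]+|charge=-?[0-9]+", "", comment))
  list(structure = ts_structure(symbols, coords, charge, comment = label),
       energy = energy, label = label, next_line = first + 2L + n)
}

#' Read a single-structure xyz file
#'
#' Parses the first xyz block of a file. The comment line may carry a
#' `charge=<int>` token (defaults to 0 when absent). Extra blocks after the
#' first raise an error; use [read_multi_xyz()] for concatenated files.
#'
#' @param path path to an xyz file.
#' @return a [ts_structure].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 3L) stop("'", path, "' is not an xyz file (too short)")
  block <- .parse_xyz_block(lines, 1L, path)
  n_declared <- as.integer(trimws(lines[1L]))
  trailing <- length(lines) - (block$next_line - 1L)
  if (trailing > 0L) {
    stop("'", path, "' declares ", n_declared, " atoms but has ", trailing,
         " extra non-empty line(s); atom count mismatch or multi-structure ",
         "file (use read_multi_xyz)")
  }
  block$structure
}

#' Write a single-structure xyz file
#'
#' @param structure a [ts_structure].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  stopifnot(inherits(structure, "ts_structure"))
  writeLines(.format_xyz_block(structure), path)
  invisible(path)
}

#' Write a conformer ensemble as a multi-structure xyz file
#'
#' Blocks are concatenated in ensemble order; each comment line carries the
#' conformer energy as an `E=<kcal/mol>` token (8 significant digits) plus the
#' total charge and the member label.
#'
#' @param ensemble a nonempty [ts_ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multi_xyz <- function(ensemble, path) {
  if (!inherits(ensemble, "ts_ensemble")) stop("ensemble must be a ts_ensemble")
  if (length(ensemble) == 0L) stop("refusing to write an empty ensemble")
  blocks <- unlist(lapply(seq_along(ensemble$structures), function(k) {
    .format_xyz_block(ensemble$structures[[k]], energy = ensemble$energies[k],
                      label = ensemble$labels[k])
  }))
  writeLines(blocks, path)
  invisible(path)
}

#' Read a multi-structure xyz file into an ensemble
#'
#' All blocks must share an identical atom list. Energies are parsed from
#' `E=` comment tokens; if any block lacks one the ensemble is returned
#' unranked (file order preserved) with `NA` energies.
#'
#' @param path path to a concatenated xyz file.
#' @return a [ts_ensemble] in file order (re-sorted ascending by energy when
#'   all energies are present, which is a no-op for files this package wrote).
#' @export
read_multi_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 3L) stop("'", path, "' is not an xyz file (too short)")
  at <- 1L
  structures <- list(); energies <- numeric(0); labels <- character(0)
  while (at <= length(lines)) {
    block <- .parse_xyz_block(lines, at, path)
    structures <- c(structures, list(block$structure))
    energies <- c(energies, block$energy)
    labels <- c(labels, block$label)
    at <- block$next_line
  }
  sy <- structures[[1L]]$symbols
  for (k in seq_along(structures)) {
    if (!identical(structures[[k]]$symbols, sy)) {
      stop("block ", k, " of '", path, "' has a different atom list (",
           paste(structures[[k]]$symbols, collapse = ""), " vs ",
           paste(sy, collapse = ""), ")")
    }
  }
  if (anyNA(energies)) {
    warning("'", path, "' has block(s) without an E= token; ensemble is unranked")
  }
  ts_ensemble(structures, energies, labels)
}
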