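# Minimal SMILES reader and template mapping.
#
# Scope: enough of the grammar to express reactant/product bonding templates
# for TS work -- organic-subset atoms (B C N O P S F Cl Br I), bracket atoms
# with charges and explicit H counts, single/double/triple/aromatic bonds,
# branches, ring closures (including %nn), dot-disconnected components.
# Stereo markers (/ \ @) are accepted and ignored; isotopes are ignored.
# Aromatic (lowercase) atoms get bond order 1.5 on aromatic-aromatic bonds.

parse_smiles <- function(smiles) {
  chars <- strsplit(smiles, "")[[1L]]
  n <- length(chars)
  atoms <- data.frame(symbol = character(0), charge = integer(0),
                      aromatic = logical(0), explicit_h = integer(0))
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  stack <- integer(0)      # branch stack of "previous atom"
  prev <- 0L
  pending_order <- NA_real_
  ring_open <- list()      # ring digit -> c(atom, order)
  pos <- 1L
  add_atom <- function(symbol, charge = 0L, aromatic = FALSE, explicit_h = NA_integer_) {
    atoms[nrow(atoms) + 1L, ] <<- list(symbol, charge, aromatic, explicit_h)
    idx <- nrow(atoms)
    if (prev > 0L) {
      ord <- pending_order
      if (is.na(ord)) {
        ord <- if (aromatic && atoms$aromatic[prev]) 1.5 else 1
      }
      bonds[nrow(bonds) + 1L, ] <<- list(prev, idx, ord)
    }
    prev <<- idx
    pending_order <<- NA_real_
    invisible(idx)
  }
  two_letter <- c("Cl", "Br")
  while (pos <= n) {
    ch <- chars[pos]
    nxt2 <- if (pos < n) paste0(ch, chars[pos + 1L]) else ""
    if (ch == "(") { stack <- c(stack, prev); pos <- pos + 1L }
    else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES '", smiles, "'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    }
    else if (ch == ".") { prev <- 0L; pending_order <- NA_real_; pos <- pos + 1L }
    else if (ch %in% c("-", "/", "\\")) { pending_order <- 1; pos <- pos + 1L }
    else if (ch == "=") { pending_order <- 2; pos <- pos + 1L }
    else if (ch == "#") { pending_order <- 3; pos <- pos + 1L }
    else if (ch == ":") { pending_order <- 1.5; pos <- pos + 1L }
    else if (ch == "%" || grepl("[0-9]", ch)) {
      if (ch == "%") {
        if (pos + 2L > n) stop("truncated %nn ring closure in '", smiles, "'")
        key <- paste0(chars[pos + 1L], chars[pos + 2L]); pos <- pos + 3L
      } else { key <- ch; pos <- pos + 1L }
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- c(prev, if (is.na(pending_order)) -1 else pending_order)
      } else {
        open <- ring_open[[key]]; ring_open[[key]] <- NULL
        ord <- pending_order
        if (is.na(ord)) ord <- if (open[2L] >= 0) open[2L] else {
          if (atoms$aromatic[open[1L]] && atoms$aromatic[prev]) 1.5 else 1
        }
        bonds[nrow(bonds) + 1L, ] <- list(open[1L], prev, ord)
      }
      pending_order <- NA_real_
    }
    else if (ch == "[") {
      close <- pos
      while (close <= n && chars[close] != "]") close <- close + 1L
      if (close > n) stop("unbalanced '[' in SMILES '", smiles, "'")
      body <- paste(chars[(pos + 1L):(close - 1L)], collapse = "")
      m <- regexec("^[0-9]*([A-Za-z][a-z]?)(@{0,2})(H([0-9]?))?(([+-])([0-9]?)|((\\+\\+)|(--))?)?$",
                   body)
      g <- regmatches(body, m)[[1L]]
      if (length(g) == 0L) stop("cannot parse bracket atom [", body, "]")
      sym <- g[2L]
      aromatic <- sym == tolower(sym) && sym %in% c("b", "c", "n", "o", "p", "s")
      if (aromatic) sym <- toupper(sym)
      hcount <- if (nzchar(g[4L])) { if (nzchar(g[5L])) as.integer(g[5L]) else 1L } else 0L
      charge <- 0L
      if (nzchar(g[7L])) {
        mag <- if (nzchar(g[8L])) as.integer(g[8L]) else 1L
        charge <- if (g[7L] == "+") mag else -mag
      } else if (nzchar(g[10L])) charge <- 2L
      else if (nzchar(g[11L])) charge <- -2L
      if (!is_known_element(sym)) stop("unknown element '", sym, "' in SMILES")
      add_atom(sym, charge, aromatic, hcount)
      pos <- close + 1L
    }
    else if (nxt2 %in% two_letter) { add_atom(nxt2); pos <- pos + 2L }
    else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch); pos <- pos + 1L
    }
    else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), aromatic = TRUE); pos <- pos + 1L
    }
    else stop("unsupported SMILES character '", ch, "' at position ", pos,
              " of '", smiles, "'")
  }
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES '", smiles, "'")
  if (length(ring_open) > 0L) stop("unclosed ring bond in SMILES '", smiles, "'")
  list(atoms = atoms, bonds = bonds)
}

# Backtracking maximum-common-bond mapping of template heavy atoms onto the
# 3D structure's heavy atoms. Element labels must match; the mapping
# maximises the number of template bonds realised as 3D-connectivity bonds.
# Ties are broken deterministically by lowest-index depth-first order.
.map_template <- function(tpl_symbols, tpl_bonds, str_symbols, str_adj) {
  nt <- length(tpl_symbols)
  tpl_adj <- lapply(seq_len(nt), function(a) {
    c(tpl_bonds$j[tpl_bonds$i == a], tpl_bonds$i[tpl_bonds$j == a])
  })
  # visit template atoms in BFS order over components for early pruning
  order <- integer(0); seen <- rep(FALSE, nt)
  for (root in seq_len(nt)) {
    if (seen[root]) next
    queue <- root; seen[root] <- TRUE
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      order <- c(order, a)
      for (b in tpl_adj[[a]]) if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
    }
  }
  best <- list(score = -1L, map = NULL)
  n_bonds_total <- nrow(tpl_bonds)
  recurse <- function(k, map, used, score) {
    if (best$score == n_bonds_total) return()
    if (k > nt) {
      if (score > best$score) best <<- list(score = score, map = map)
      return()
    }
    a <- order[k]
    remaining_bonds <- sum(tpl_bonds$i %in% order[k:nt] | tpl_bonds$j %in% order[k:nt])
    if (score + remaining_bonds <= best$score) return()
    for (cand in which(str_symbols == tpl_symbols[a] & !used)) {
      gain <- 0L; ok <- TRUE
      for (b in tpl_adj[[a]]) {
        if (!is.na(map[b])) {
          if (cand %in% str_adj[[map[b]]]) gain <- gain + 1L
        }
      }
      if (ok) {
        map[a] <- cand; used[cand] <- TRUE
        recurse(k + 1L, map, used, score + gain)
        map[a] <- NA_integer_; used[cand] <- FALSE
      }
    }
  }
  recurse(1L, rep(NA_integer_, nt), rep(FALSE, length(str_symbols)), 0L)
  best
}

#' Transfer bonding from a SMILES template
#'
#' Copies bond orders and formal charges from a user-supplied reactant- or
#' product-side SMILES onto the 3D topology via a maximum-common-substructure
#' atom mapping on heavy atoms (element labels must match; hydrogens follow
#' their parent heavy atom). Bonds present in the 3D connectivity but absent
#' from the template -- the forming/breaking bonds of the reaction center --
#' are retained with unknown bond order. Template bonds with no 3D
#' counterpart (e.g. a reactant bond already broken in the TS geometry beyond
#' the distance cutoff) are ignored with a warning. Atom order of the 3D
#' structure is always preserved.
#'
#' @param topology a `ts_topology` (its bond set defines the 3D connectivity).
#' @param smiles template SMILES; dot-disconnected components allowed.
#' @param fallback_on_mapping_failure if `TRUE`, an unmappable template falls
#'   back to [perceive_bond_orders()] instead of erroring (explicit opt-in).
#' @return a `ts_topology` with template-derived bond orders/charges.
#' @export
apply_smiles_template <- function(topology, smiles,
                                  fallback_on_mapping_failure = FALSE) {
  stopifnot(inherits(topology, "ts_topology"))
  tpl <- parse_smiles(smiles)
  str_symbols <- topology$structure$symbols
  heavy_idx <- which(is_heavy(str_symbols))
  tpl_comp <- sort(tpl$atoms$symbol[tpl$atoms$symbol != "H"])
  str_comp <- sort(str_symbols[heavy_idx])
  if (!identical(tpl_comp, str_comp)) {
    stop("template heavy-atom composition (", paste(tpl_comp, collapse = ""),
         ") does not match the structure's (", paste(str_comp, collapse = ""), ")")
  }
  keep <- which(tpl$atoms$symbol != "H")
  remap <- match(seq_len(nrow(tpl$atoms)), keep)
  tpl_bonds <- tpl$bonds[tpl$bonds$i %in% keep & tpl$bonds$j %in% keep, , drop = FALSE]
  tpl_bonds$i <- remap[tpl_bonds$i]; tpl_bonds$j <- remap[tpl_bonds$j]
  hb <- topology$bonds[topology$bonds$i %in% heavy_idx &
                         topology$bonds$j %in% heavy_idx, , drop = FALSE]
  sub_of <- match(seq_along(str_symbols), heavy_idx)
  str_adj <- lapply(heavy_idx, function(a) {
    sub_of[c(hb$j[hb$i == a], hb$i[hb$j == a])]
  })
  res <- .map_template(tpl$atoms$symbol[keep], tpl_bonds,
                       str_symbols[heavy_idx], str_adj)
  if (is.null(res$map) || res$score < nrow(tpl_bonds) * 0.5) {
    if (fallback_on_mapping_failure) {
      warning("no consistent template atom mapping; falling back to direct perception")
      return(perceive_bond_orders(topology$structure))
    }
    stop("no consistent atom mapping between template '", smiles,
         "' and the 3D connectivity (matched ", max(0L, res$score), "/",
         nrow(tpl_bonds), " template bonds)")
  }
  map_full <- heavy_idx[res$map]   # template heavy atom -> structure atom
  bonds <- topology$bonds
  bonds$order <- NA_real_
  matched <- 0L
  for (b in seq_len(nrow(tpl_bonds))) {
    si <- map_full[tpl_bonds$i[b]]; sj <- map_full[tpl_bonds$j[b]]
    row <- which((bonds$i == min(si, sj)) & (bonds$j == max(si, sj)))
    if (length(row) == 1L) {
      bonds$order[row] <- tpl_bonds$order[b]; matched <- matched + 1L
    }
  }
  if (matched < nrow(tpl_bonds)) {
    warning(nrow(tpl_bonds) - matched,
            " template bond(s) have no 3D-connectivity counterpart; ignored")
  }
  # H-X bonds and forming/breaking bonds keep order 1 / NA respectively
  h_bond <- !is_heavy(str_symbols[bonds$i]) | !is_heavy(str_symbols[bonds$j])
  bonds$order[h_bond] <- 1
  fc <- integer(length(str_symbols))
  fc[map_full] <- tpl$atoms$charge[keep]
  ok_charge <- sum(fc) == topology$structure$charge
  if (!ok_charge) {
    warning("template formal charges sum to ", sum(fc), " but total charge is ",
            topology$structure$charge, "; topology kept connectivity-only")
  }
  new_topology(topology$structure, bonds, fc, connectivity_only = !ok_charge)
}
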