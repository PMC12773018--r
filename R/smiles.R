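# Minimal SMILES reader (Daylight dialect, isomeric accepted) producing a
# molecular graph: atoms (element, aromatic flag, formal charge, hydrogen
# count, chirality tag) and bonds (order; aromatic = 1.5). Covers the organic
# subset, bracket atoms, branches, ring closures (including %nn), and the
# bond symbols - = # : / \ (directional bonds are read as single bonds).
# No tautomer or aromaticity perception is attempted: lowercase atoms are
# taken as aromatic as written, which is all the framework needs for
# fingerprints and atom-level features.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
DEFAULT_VALENCE <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5),
                        S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles A SMILES string.
#' @return A `mol_graph` with `atoms` (data.frame: symbol, aromatic, charge,
#'   h_explicit, chiral, bracket) and `bonds` (data.frame: from, to, order),
#'   plus implicit hydrogen counts filled in by organic-subset valence rules.
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles))
    stop("unparseable SMILES: empty input")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  prev_stack <- integer(0)  # branch stack
  prev <- NA_integer_       # atom awaiting the next bond
  pending_order <- NA_real_ # bond symbol seen since last atom
  ring_open <- list()       # ring digit -> list(atom, order)
  i <- 1
  add_atom <- function(symbol, aromatic, charge = 0, h_explicit = NA_integer_,
                       chiral = 0L, bracket = FALSE) {
    atoms[[length(atoms) + 1]] <<- list(
      symbol = symbol, aromatic = aromatic, charge = charge,
      h_explicit = h_explicit, chiral = chiral, bracket = bracket)
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending_order
      if (is.na(ord)) ord <- if (aromatic && atoms[[prev]]$aromatic) 1.5 else 1
      bonds[[length(bonds) + 1]] <<- list(from = prev, to = idx, order = ord)
    }
    pending_order <<- NA_real_
    prev <<- idx
    idx
  }
  close_ring <- function(digit) {
    key <- as.character(digit)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, order = pending_order)
      pending_order <<- NA_real_
    } else {
      other <- ring_open[[key]]
      ord <- pending_order
      if (is.na(ord)) ord <- other$order
      if (is.na(ord)) {
        ord <- if (atoms[[prev]]$aromatic && atoms[[other$atom]]$aromatic)
          1.5 else 1
      }
      bonds[[length(bonds) + 1]] <<- list(from = other$atom, to = prev,
                                          order = ord)
      ring_open[[key]] <<- NULL
      pending_order <<- NA_real_
    }
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      prev_stack <- c(prev_stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (length(prev_stack) == 0)
        stop("unparseable SMILES: unbalanced ')' in '", smiles, "'")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1
    } else if (ch %in% c("-", "/", "\\")) {
      pending_order <- 1; i <- i + 1
    } else if (ch == "=") {
      pending_order <- 2; i <- i + 1
    } else if (ch == "#") {
      pending_order <- 3; i <- i + 1
    } else if (ch == ":") {
      pending_order <- 1.5; i <- i + 1
    } else if (ch == ".") {
      prev <- NA_integer_; pending_order <- NA_real_; i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n) stop("unparseable SMILES: truncated % ring closure")
      close_ring(paste0(chars[i + 1], chars[i + 2])); i <- i + 3
    } else if (ch == "[") {
      j <- i + 1
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop("unparseable SMILES: unclosed bracket atom")
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$",
        body))[[1]]
      if (length(m) == 0)
        stop("unparseable SMILES: bad bracket atom [", body, "]")
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      if (aromatic) sym <- paste0(toupper(substr(sym, 1, 1)),
                                  substring(sym, 2))
      chiral <- if (m[4] == "@") 1L else if (m[4] == "@@") 2L else 0L
      hexp <- if (m[5] == "") 0L
              else if (m[5] == "H") 1L
              else as.integer(substring(m[5], 2))
      chg <- 0
      if (m[6] != "") {
        cc <- m[6]
        if (grepl("^[+-][0-9]+$", cc)) {
          chg <- as.integer(substring(cc, 2)) *
            (if (substr(cc, 1, 1) == "+") 1 else -1)
        } else {
          chg <- nchar(cc) * (if (substr(cc, 1, 1) == "+") 1 else -1)
        }
      }
      add_atom(sym, aromatic, charge = chg, h_explicit = hexp,
               chiral = chiral, bracket = TRUE)
      i <- j + 1
    } else if (grepl("[A-Za-z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE); i <- i + 2
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE); i <- i + 1
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE); i <- i + 1
      } else {
        stop("unparseable SMILES: unexpected atom '", ch, "' in '",
             smiles, "'")
      }
    } else {
      stop("unparseable SMILES: unexpected character '", ch, "' in '",
           smiles, "'")
    }
  }
  if (length(prev_stack) > 0)
    stop("unparseable SMILES: unbalanced '(' in '", smiles, "'")
  if (length(ring_open) > 0)
    stop("unparseable SMILES: unclosed ring bond in '", smiles, "'")
  if (length(atoms) == 0) stop("unparseable SMILES: no atoms in '",
                               smiles, "'")
  at <- data.frame(
    symbol = vapply(atoms, `[[`, character(1), "symbol"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, `[[`, numeric(1), "charge"),
    h_explicit = vapply(atoms, `[[`, integer(1), "h_explicit"),
    chiral = vapply(atoms, `[[`, integer(1), "chiral"),
    bracket = vapply(atoms, `[[`, logical(1), "bracket"),
    stringsAsFactors = FALSE)
  bd <- if (length(bonds) == 0) {
    data.frame(from = integer(0), to = integer(0), order = numeric(0))
  } else {
    data.frame(from = vapply(bonds, `[[`, numeric(1), "from"),
               to = vapply(bonds, `[[`, numeric(1), "to"),
               order = vapply(bonds, `[[`, numeric(1), "order"))
  }
  mol <- structure(list(atoms = at, bonds = bd, smiles = smiles),
                   class = "mol_graph")
  mol$atoms$h_count <- .implicit_h(mol)
  mol
}

# hydrogen count per atom: explicit for bracket atoms, smallest standard
# valence covering the bond-order sum for organic-subset atoms
.implicit_h <- function(mol) {
  at <- mol$atoms; bd <- mol$bonds
  deg_order <- numeric(nrow(at))
  if (nrow(bd) > 0) {
    for (k in seq_len(nrow(bd))) {
      deg_order[bd$from[k]] <- deg_order[bd$from[k]] + bd$order[k]
      deg_order[bd$to[k]] <- deg_order[bd$to[k]] + bd$order[k]
    }
  }
  h <- integer(nrow(at))
  for (i in seq_len(nrow(at))) {
    if (at$bracket[i]) { h[i] <- at$h_explicit[i]; next }
    val <- DEFAULT_VALENCE[[at$symbol[i]]]
    if (is.null(val)) { h[i] <- 0L; next }
    # aromatic bond sums are half-integers; round up (benzene C: 3 -> 1 H)
    need <- ceiling(deg_order[i] - 1e-9)
    ok <- val[val >= need]
    h[i] <- if (length(ok) == 0) 0L else as.integer(ok[1] - need)
  }
  h
}

#' Molecular formula of a parsed molecule
#'
#' Hill-order formula (C first, H second, then alphabetical) counting
#' implicit and explicit hydrogens.
#'
#' @param mol A `mol_graph` (or SMILES string).
#' @return A string such as `"C2H5NO2"`.
#' @export
mol_formula <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  counts <- table(mol$atoms$symbol)
  nh <- sum(mol$atoms$h_count)
  els <- names(counts)
  out <- ""
  fmt <- function(el, k) if (k == 1) el else paste0(el, k)
  if ("C" %in% els) out <- paste0(out, fmt("C", counts[["C"]]))
  if (nh > 0) out <- paste0(out, fmt("H", nh))
  for (el in sort(setdiff(els, "C")))
    out <- paste0(out, fmt(el, counts[[el]]))
  out
}

n_heavy_atoms <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  nrow(mol$atoms)
}

# adjacency as a list of (neighbor index, bond order) pairs
.mol_adjacency <- function(mol) {
  adj <- vector("list", nrow(mol$atoms))
  bd <- mol$bonds
  if (nrow(bd) > 0) {
    for (k in seq_len(nrow(bd))) {
      adj[[bd$from[k]]] <- rbind(adj[[bd$from[k]]], c(bd$to[k], bd$order[k]))
      adj[[bd$to[k]]] <- rbind(adj[[bd$to[k]]], c(bd$from[k], bd$order[k]))
    }
  }
  adj
}
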