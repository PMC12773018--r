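# Chemistry and physicochemistry: sequence -> SMILES assembly, circular
# (Morgan/ECFP-style) fingerprints, Tanimoto similarity, physicochemical
# profiles with tunable pH, and the low-complexity flag.

# Kekulized side-chain templates; backbone unit is N[C@@H](<side>)C(=O),
# glycine and proline are special-cased. Templates verified against the
# known molecular formulas of the free amino acids.
AA_SIDECHAIN <- c(
  A = "C", R = "CCCNC(=N)N", N = "CC(=O)N", D = "CC(=O)O", C = "CS",
  E = "CCC(=O)O", Q = "CCC(=O)N", H = "CC1=CN=CN1", I = "C(C)CC",
  L = "CC(C)C", K = "CCCCN", M = "CCSC", F = "CC1=CC=CC=C1", S = "CO",
  T = "C(O)C", W = "CC1=C[NH]C2=CC=CC=C21", V = "C(C)C",
  Y = "CC1=CC=C(O)C=C1")

# known formulas of the free amino acids; the peptide-formula oracle is
# sum(residues) - (n-1) x H2O
AA_FORMULA <- list(
  G = c(C = 2, H = 5, N = 1, O = 2),           A = c(C = 3, H = 7, N = 1, O = 2),
  R = c(C = 6, H = 14, N = 4, O = 2),          N = c(C = 4, H = 8, N = 2, O = 3),
  D = c(C = 4, H = 7, N = 1, O = 4),           C = c(C = 3, H = 7, N = 1, O = 2, S = 1),
  E = c(C = 5, H = 9, N = 1, O = 4),           Q = c(C = 5, H = 10, N = 2, O = 3),
  H = c(C = 6, H = 9, N = 3, O = 2),           I = c(C = 6, H = 13, N = 1, O = 2),
  L = c(C = 6, H = 13, N = 1, O = 2),          K = c(C = 6, H = 14, N = 2, O = 2),
  M = c(C = 5, H = 11, N = 1, O = 2, S = 1),   F = c(C = 9, H = 11, N = 1, O = 2),
  P = c(C = 5, H = 9, N = 1, O = 2),           S = c(C = 3, H = 7, N = 1, O = 3),
  T = c(C = 4, H = 9, N = 1, O = 3),           W = c(C = 11, H = 12, N = 2, O = 2),
  Y = c(C = 9, H = 11, N = 1, O = 3),          V = c(C = 5, H = 11, N = 1, O = 2))

.check_canonical <- function(seq, min_len = 1) {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0)
    stop("non-canonical letter(s): ", paste(bad, collapse = ", "))
  if (length(chars) < min_len)
    stop("sequence shorter than ", min_len, " residues")
  chars
}

#' Convert an amino-acid sequence to a peptide SMILES
#'
#' Assembles a linear, uncharged peptide: free amine N-terminus, free
#' carboxylic-acid C-terminus, amide bonds between consecutive residues.
#' L-stereocenters are written for all residues except glycine; no
#' cyclization and no D-residues (those enter the framework as SMILES
#' directly).
#'
#' @param seq Canonical amino-acid string (length >= 1 for this operation).
#' @return A SMILES string that reparses to a molecule whose formula equals
#'   the residue-composition oracle (sum of amino-acid formulas minus one
#'   water per peptide bond).
#' @export
sequence_to_smiles <- function(seq) {
  chars <- .check_canonical(seq, min_len = 1)
  unit <- function(a) {
    if (a == "G") return("NCC(=O)")
    if (a == "P") return("N1CCC[C@H]1C(=O)")
    paste0("N[C@@H](", AA_SIDECHAIN[[a]], ")C(=O)")
  }
  paste0(paste(vapply(chars, unit, character(1)), collapse = ""), "O")
}

# expected molecular formula from residue composition (independent of the
# SMILES path): sum of free amino-acid formulas minus (n-1) waters
peptide_formula_oracle <- function(seq) {
  chars <- .check_canonical(seq, min_len = 1)
  tot <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (a in chars) {
    f <- AA_FORMULA[[a]]
    tot[names(f)] <- tot[names(f)] + f
  }
  nb <- length(chars) - 1
  tot["H"] <- tot["H"] - 2 * nb
  tot["O"] <- tot["O"] - nb
  tot <- tot[tot > 0]
  out <- ""
  fmt <- function(el) {
    if (!el %in% names(tot)) return("")
    if (tot[[el]] == 1) el else paste0(el, tot[[el]])
  }
  paste0(fmt("C"), fmt("H"),
         paste(vapply(sort(setdiff(names(tot), c("C", "H"))), fmt,
                      character(1)), collapse = ""))
}

# deterministic integer hash of a numeric tuple, folded into [0, 2^31-1)
.tuple_hash <- function(x) {
  h <- 17
  for (v in x) h <- (h * 33 + (v %% 2147483647)) %% 2147483647
  h
}

#' Circular (Morgan-style) fingerprint of a molecule
#'
#' ECFP-flavored hashed fingerprint: each atom starts from an invariant
#' tuple (element, heavy degree, hydrogen count, formal charge, aromatic
#' flag, and - when `chirality = TRUE` - the chirality tag as written);
#' neighborhoods are iteratively rehashed out to `radius`, and every
#' environment identifier is folded modulo `nbits` into a binary bit
#' vector. Collisions are accepted (standard ECFP behavior). The hash is
#' documented and deterministic but not bit-compatible with other toolkits.
#'
#' @param smiles SMILES string (or a parsed `mol_graph`).
#' @param radius Neighborhood radius (default 2).
#' @param nbits Folded length (default 2048).
#' @param chirality Include chirality tags in atom invariants (default TRUE).
#' @return A `fingerprint`: sorted 0-based positions of set bits with
#'   parameters and `n_on` attached.
#' @export
circular_fingerprint <- function(smiles, radius = 2, nbits = 2048,
                                 chirality = TRUE) {
  mol <- if (inherits(smiles, "mol_graph")) smiles else parse_smiles(smiles)
  at <- mol$atoms
  n <- nrow(at)
  elem_code <- as.integer(factor(at$symbol, levels = c(
    "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")))
  elem_code[is.na(elem_code)] <- 99L
  adj <- .mol_adjacency(mol)
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  inv <- numeric(n)
  for (i in seq_len(n)) {
    tup <- c(elem_code[i], deg[i], at$h_count[i], at$charge[i],
             as.integer(at$aromatic[i]))
    if (chirality) tup <- c(tup, at$chiral[i])
    inv[i] <- .tuple_hash(tup)
  }
  feats <- inv
  for (r in seq_len(radius)) {
    new_inv <- numeric(n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (is.null(nb)) {
        new_inv[i] <- .tuple_hash(c(r, inv[i]))
      } else {
        pairs <- cbind(round(nb[, 2] * 10), inv[nb[, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        new_inv[i] <- .tuple_hash(c(r, inv[i], t(pairs[ord, , drop = FALSE])))
      }
    }
    inv <- new_inv
    feats <- c(feats, inv)
  }
  bits <- sort(unique(floor(feats %% nbits)))
  structure(bits, class = "fingerprint", nbits = nbits, radius = radius,
            chirality = chirality, n_on = length(bits))
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint>", attr(x, "n_on"), "of", attr(x, "nbits"),
      "bits set (radius", attr(x, "radius"), ")\n")
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 1 when both fingerprints are
#' all-zero (identical objects).
#'
#' @param a,b `fingerprint`s with identical parameters.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  for (p in c("nbits", "radius", "chirality"))
    if (!identical(attr(a, p), attr(b, p)))
      stop("fingerprint parameter mismatch: ", p)
  na <- length(a); nb <- length(b)
  if (na == 0 && nb == 0) return(1)
  ni <- length(intersect(as.integer(a), as.integer(b)))
  ni / (na + nb - ni)
}

.charge_at_ph <- function(counts, pH, pka = PKA_EMBOSS) {
  # counts: named residue counts incl. termini handled by caller
  pos <- 1 / (1 + 10^(pH - pka$nterm))
  neg <- -1 / (1 + 10^(pka$cterm - pH))
  for (a in names(pka$positive))
    pos <- pos + (counts[[a]] %||% 0) / (1 + 10^(pH - pka$positive[[a]]))
  for (a in names(pka$negative))
    neg <- neg - (counts[[a]] %||% 0) / (1 + 10^(pka$negative[[a]] - pH))
  unname(pos + neg)
}

#' Physicochemical profile of a peptide
#'
#' Molecular weight (average residue masses plus one water), isoelectric
#' point, GRAVY (mean Kyte-Doolittle hydropathy), net charge at a stated pH
#' (Henderson-Hasselbalch over termini and ionizable side chains), sequence
#' length, number of distinct residues and the complexity ratio
#' length / n_unique. The pKa scale defaults to an EMBOSS-style table and is
#' configurable; published scales differ by a few tenths of a pH unit.
#'
#' @param seq Canonical amino-acid sequence (length >= 2).
#' @param pH pH for the net-charge calculation, in (0, 14).
#' @param pka pKa scale: list with `nterm`, `cterm`, `positive`, `negative`.
#' @return A `physchem_profile` list.
#' @export
physchem_profile <- function(seq, pH = 7.0, pka = PKA_EMBOSS) {
  if (pH <= 0 || pH >= 14) stop("pH outside (0, 14)")
  chars <- .check_canonical(seq, min_len = 2)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  counts <- as.list(as.numeric(counts))
  names(counts) <- AA_ALPHABET
  mw <- sum(RESIDUE_MASS[chars]) + WATER_MASS
  gravy <- mean(KD_HYDROPATHY[chars])
  net_charge <- .charge_at_ph(counts, pH, pka)
  # pI by bisection: charge is monotone decreasing in pH
  lo <- 1e-6; hi <- 14 - 1e-6
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    q <- .charge_at_ph(counts, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  pI <- mid
  n_unique <- length(unique(chars))
  structure(list(mw = mw, pI = pI, gravy = gravy, net_charge = net_charge,
                 length = length(chars), n_unique = n_unique,
                 complexity_ratio = length(chars) / n_unique, ph = pH),
            class = "physchem_profile")
}

#' Low-complexity flag
#'
#' TRUE iff length / n_unique exceeds 5 (strict inequality).
#'
#' @param seq Canonical amino-acid sequence.
#' @return Logical.
#' @export
low_complexity_flag <- function(seq) {
  chars <- .check_canonical(seq, min_len = 1)
  length(chars) / length(unique(chars)) > 5
}
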