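# Pluggable featurization: deterministic baseline featurizers stand in for
# frozen language-model embeddings so every downstream stage is testable
# without pretrained weights; external models plug in through an adapter
# contract only (no weights are shipped).

# per-residue side-chain charge at pH 7 (Henderson-Hasselbalch, EMBOSS pKa)
.residue_charge7 <- local({
  q <- stats::setNames(rep(0, 20), AA_ALPHABET)
  for (a in names(PKA_EMBOSS$positive))
    q[a] <- 1 / (1 + 10^(7 - PKA_EMBOSS$positive[[a]]))
  for (a in names(PKA_EMBOSS$negative))
    q[a] <- -1 / (1 + 10^(PKA_EMBOSS$negative[[a]] - 7))
  q
})

BASELINE_SEQ_DIM <- 24L    # one-hot(20) + hydropathy + charge + sin + cos
SMILES_ATOM_PALETTE <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                         "other")
BASELINE_SMILES_DIM <- length(SMILES_ATOM_PALETTE) + 3L  # + degree, arom, charge

.embedding_matrix <- function(values, pooled, featurizer_id,
                              source_id = NA_character_) {
  structure(values, class = c("embedding_matrix", "matrix"),
            pooled = pooled, featurizer_id = featurizer_id,
            source_id = source_id)
}

#' Declare an embedder
#'
#' @param name Embedder name. Built-ins: `"baseline_seq"` (AA and protein
#'   sequences) and `"baseline_smiles"` (SMILES); anything of kind
#'   `"external_adapter"` must be registered at run time and declares its
#'   expected dimension (e.g. 1280 for a large protein language model).
#' @param modality `"AA"`, `"SMILES"` or `"protein"`.
#' @param dim Embedding dimension (> 0).
#' @param kind `"baseline_seq"`, `"baseline_smiles"` or
#'   `"external_adapter"`.
#' @return An `embedder_spec`.
#' @export
embedder_spec <- function(name = "baseline_seq",
                          modality = c("AA", "SMILES", "protein"),
                          dim = NULL,
                          kind = c("baseline_seq", "baseline_smiles",
                                   "external_adapter")) {
  modality <- match.arg(modality)
  kind <- match.arg(kind)
  if (is.null(dim))
    dim <- switch(kind, baseline_seq = BASELINE_SEQ_DIM,
                  baseline_smiles = BASELINE_SMILES_DIM,
                  stop("external adapters must declare their dimension"))
  stopifnot(dim > 0)
  structure(list(name = name, modality = modality, dim = as.integer(dim),
                 kind = kind),
            class = "embedder_spec")
}

#' Baseline sequence featurizer
#'
#' Per-position concatenation of a 20-way one-hot residue encoding, scaled
#' Kyte-Doolittle hydropathy, side-chain charge at pH 7, and a two-channel
#' sinusoidal position encoding. Deterministic and injective over distinct
#' sequences (the one-hot block preserves identity).
#'
#' @param seq Canonical amino-acid sequence.
#' @return An unpooled `embedding_matrix` (length x 24).
#' @export
baseline_sequence_featurizer <- function(seq) {
  chars <- .check_canonical(seq, min_len = 1)
  L <- length(chars)
  idx <- match(chars, AA_ALPHABET)
  onehot <- matrix(0, L, 20)
  onehot[cbind(seq_len(L), idx)] <- 1
  pos <- seq_len(L)
  m <- cbind(onehot,
             KD_HYDROPATHY[chars] / 4.5,
             .residue_charge7[chars],
             sin(pos / 10), cos(pos / 10))
  dimnames(m) <- NULL
  .embedding_matrix(m, pooled = FALSE, featurizer_id = "baseline_seq")
}

#' Baseline SMILES featurizer
#'
#' Per-atom invariant features: element one-hot over a fixed palette,
#' heavy-atom degree, aromaticity flag and formal charge. With
#' `pooled_fp = TRUE` a pooled variant is returned instead: the column
#' means with the circular fingerprint folded to `fp_block` bits appended
#' as a fixed-length block (this variant is pooled-only by construction).
#'
#' @param smiles SMILES string.
#' @param pooled_fp Append a folded-fingerprint block and pool.
#' @param fp_block Folded fingerprint block length (default 64).
#' @return An `embedding_matrix` (heavy atoms x 14, or 1 x (14+fp_block)).
#' @export
baseline_smiles_featurizer <- function(smiles, pooled_fp = FALSE,
                                       fp_block = 64) {
  mol <- parse_smiles(smiles)
  at <- mol$atoms
  n <- nrow(at)
  pal <- match(at$symbol, SMILES_ATOM_PALETTE)
  pal[is.na(pal)] <- length(SMILES_ATOM_PALETTE)
  onehot <- matrix(0, n, length(SMILES_ATOM_PALETTE))
  onehot[cbind(seq_len(n), pal)] <- 1
  adj <- .mol_adjacency(mol)
  deg <- vapply(adj, function(a) if (is.null(a)) 0 else nrow(a), numeric(1))
  m <- cbind(onehot, deg / 4, as.numeric(at$aromatic), at$charge)
  dimnames(m) <- NULL
  if (!pooled_fp)
    return(.embedding_matrix(m, pooled = FALSE,
                             featurizer_id = "baseline_smiles"))
  fp <- circular_fingerprint(mol, nbits = fp_block)
  block <- numeric(fp_block)
  block[as.integer(fp) + 1] <- 1
  .embedding_matrix(matrix(c(colMeans(m), block), nrow = 1),
                    pooled = TRUE, featurizer_id = "baseline_smiles_fp")
}

# run-time registry for external adapters (no weights shipped)
.adapter_registry <- new.env(parent = emptyenv())

#' Register an external embedding adapter
#'
#' The adapter contract: `fn(payload)` returns an unpooled numeric matrix
#' (positions x dim) with any special tokens already stripped.
#'
#' @param name Adapter name (used as `featurizer_id`).
#' @param fn Featurizing function.
#' @export
register_adapter <- function(name, fn) {
  assign(name, fn, envir = .adapter_registry)
  invisible(name)
}

#' Embed a record or raw sequence
#'
#' @param x A `peptide_record`, or a raw character payload.
#' @param spec An `embedder_spec`.
#' @param pooled Return the pooled (mean over positions) representation.
#'   Pooled output equals the column means of the unpooled output exactly.
#' @return An `embedding_matrix`.
#' @export
embed_record <- function(x, spec = embedder_spec(), pooled = FALSE) {
  stopifnot(inherits(spec, "embedder_spec"))
  if (inherits(x, "peptide_record")) {
    rec_modality <- x$modality
    if (spec$modality == "protein" && rec_modality == "AA")
      rec_modality <- "protein"
    if (rec_modality != spec$modality)
      stop("modality mismatch: record is ", x$modality,
           ", embedder expects ", spec$modality)
    payload <- x$payload
    source_id <- x$id
  } else {
    payload <- as.character(x)
    source_id <- NA_character_
  }
  m <- switch(spec$kind,
    baseline_seq = baseline_sequence_featurizer(payload),
    baseline_smiles = baseline_smiles_featurizer(payload),
    external_adapter = {
      fn <- tryCatch(get(spec$name, envir = .adapter_registry),
                     error = function(e)
                       stop("adapter unavailable: ", spec$name))
      v <- fn(payload)
      if (!is.matrix(v) || ncol(v) != spec$dim)
        stop("adapter '", spec$name, "' returned wrong dimension")
      .embedding_matrix(v, pooled = FALSE, featurizer_id = spec$name)
    })
  attr(m, "source_id") <- source_id
  if (pooled) mean_pool(m) else m
}

#' Mean-pool an embedding matrix over positions
#'
#' @param m An unpooled `embedding_matrix`. Pooling a pooled matrix is
#'   idempotent and emits a warning.
#' @return A 1 x D pooled `embedding_matrix` equal to the column means.
#' @export
mean_pool <- function(m) {
  stopifnot(inherits(m, "embedding_matrix"))
  if (isTRUE(attr(m, "pooled"))) {
    warning("input is already pooled; returning unchanged")
    return(m)
  }
  .embedding_matrix(matrix(colMeans(m), nrow = 1), pooled = TRUE,
                    featurizer_id = attr(m, "featurizer_id"),
                    source_id = attr(m, "source_id"))
}

#' Featurize a whole dataset
#'
#' @param ds A `property_dataset` (or character payload vector).
#' @param spec An `embedder_spec`.
#' @param pooled Pool each record's embedding.
#' @return Pooled: an n x D matrix. Unpooled: a list of L_i x D matrices.
#'   Both carry `featurizer_id`.
#' @export
featurize_dataset <- function(ds, spec = embedder_spec(), pooled = TRUE) {
  payloads <- if (is.character(ds)) ds else dataset_payloads(ds)
  ms <- lapply(payloads, function(p) embed_record(p, spec, pooled = pooled))
  if (pooled) {
    out <- do.call(rbind, ms)
    attr(out, "featurizer_id") <- attr(ms[[1]], "featurizer_id")
    out
  } else {
    attr(ms, "featurizer_id") <- attr(ms[[1]], "featurizer_id")
    ms
  }
}
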