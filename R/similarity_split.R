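# Leakage-aware clustering and splitting in both modalities, plus split
# propagation and audit.
#
# The sequence path replaces an MMseqs2 run with a documented greedy
# representative clustering over explicit identity/coverage definitions
# (global alignment with free end gaps, match +1, mismatch 0, affine
# interior gaps). Parameters (min identity 0.3, bidirectional coverage 0.8)
# are preserved, but cluster memberships are NOT bit-identical to MMseqs2.

#' Pairwise sequence identity and coverage
#'
#' Global alignment with free end gaps (overlap alignment) scored match +1,
#' mismatch 0, affine interior gaps. Identity is matches divided by the
#' number of alignment columns between the first and last aligned pair;
#' coverage of each sequence is the span of its residues inside that window
#' divided by its length.
#'
#' Co-optimal alignments can carry different match counts, so the result
#' is made orientation-independent by always aligning the longer sequence
#' first (ties broken lexicographically); `cov_a`/`cov_b` still refer to
#' the arguments as given. The greedy clustering scan uses the same
#' canonical orientation, so identity is symmetric everywhere.
#'
#' @param a,b Canonical amino-acid sequences.
#' @param gap_open,gap_ext Affine gap penalties (positive numbers).
#' @return Named vector: `identity`, `cov_a`, `cov_b`, `matches`, `columns`.
#' @export
pairwise_identity <- function(a, b, gap_open = 1, gap_ext = 0.5) {
  swap <- nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)
  x <- if (swap) b else a
  y <- if (swap) a else b
  xi <- match(strsplit(x, "")[[1]], AA_ALPHABET)
  yi <- match(strsplit(y, "")[[1]], AA_ALPHABET)
  if (anyNA(xi) || anyNA(yi)) stop("non-canonical letters in input")
  st <- .pairwise_identity_cpp(xi, yi, gap_open, gap_ext)
  if (swap) st[c("cov_a", "cov_b")] <- st[c("cov_b", "cov_a")]
  st
}

.as_sequences <- function(records) {
  if (is.character(records)) {
    ids <- names(records) %||% as.character(seq_along(records))
    return(list(ids = ids, seqs = unname(records)))
  }
  list(ids = vapply(records, function(r) r$id, character(1)),
       seqs = vapply(records, function(r) r$payload, character(1)))
}

.cluster_assignment <- function(member_of, method, params) {
  structure(list(member_of = member_of, method = method, params = params,
                 n_clusters = length(unique(member_of))),
            class = "cluster_assignment")
}

#' Greedy identity clustering of amino-acid sequences
#'
#' Records are sorted by descending length (ties broken lexicographically);
#' each record joins the first existing representative with identity
#' `>= min_id` and both coverages `>= min_cov`, else founds a new cluster.
#' Cluster ids are contiguous from 0 in founding order.
#'
#' @param records List of AA `peptide_record`s, or a named character vector
#'   of sequences.
#' @param min_id Minimum pairwise identity (default 0.3).
#' @param min_cov Minimum bidirectional coverage (default 0.8).
#' @param gap_open,gap_ext Alignment gap penalties.
#' @return A `cluster_assignment` with `member_of` mapping id -> cluster id.
#' @export
cluster_sequences_by_identity <- function(records, min_id = 0.3,
                                          min_cov = 0.8, gap_open = 1,
                                          gap_ext = 0.5) {
  x <- .as_sequences(records)
  params <- list(min_id = min_id, min_cov = min_cov,
                 gap_open = gap_open, gap_ext = gap_ext)
  if (length(x$seqs) == 0)
    return(.cluster_assignment(structure(integer(0), names = character(0)),
                               "identity_greedy", params))
  ord <- order(-nchar(x$seqs), x$seqs)
  enc <- lapply(x$seqs[ord], function(s) {
    v <- match(strsplit(s, "")[[1]], AA_ALPHABET)
    if (anyNA(v)) stop("non-canonical letters in sequence")
    v
  })
  cl <- .cluster_identity_cpp(enc, min_id, min_cov, gap_open, gap_ext)
  member_of <- integer(length(cl))
  member_of[ord] <- cl
  names(member_of) <- x$ids
  .cluster_assignment(member_of, "identity_greedy", params)
}

# dense pairwise Tanimoto matrix from a list of fingerprints
.tanimoto_matrix <- function(fps) {
  n <- length(fps)
  nbits <- attr(fps[[1]], "nbits")
  for (f in fps)
    for (p in c("nbits", "radius", "chirality"))
      if (!identical(attr(f, p), attr(fps[[1]], p)))
        stop("fingerprint parameter mismatch: ", p)
  M <- matrix(0, n, nbits)
  for (i in seq_len(n)) if (length(fps[[i]]) > 0)
    M[i, as.integer(fps[[i]]) + 1] <- 1
  inter <- M %*% t(M)
  non <- rowSums(M)
  uni <- outer(non, non, "+") - inter
  S <- ifelse(uni == 0, 1, inter / pmax(uni, 1e-300))
  S
}

#' Taylor-Butina clustering of fingerprints
#'
#' Neighbor lists are formed at Tanimoto similarity `>= sim_threshold`;
#' the unassigned molecule with the most unassigned neighbors (ties: lowest
#' input index) becomes a centroid and absorbs its unassigned neighbors;
#' the process repeats until everything is assigned. Singletons form their
#' own clusters. Cluster ids are contiguous from 0 in centroid-picking
#' order.
#'
#' @param fps List of `fingerprint`s sharing parameters; names are record
#'   ids (defaults to the input index).
#' @param sim_threshold Tanimoto similarity threshold (default 0.6).
#' @return A `cluster_assignment`.
#' @export
cluster_smiles_butina <- function(fps, sim_threshold = 0.6) {
  params <- list(sim_threshold = sim_threshold)
  n <- length(fps)
  ids <- names(fps) %||% as.character(seq_len(n))
  if (n == 0)
    return(.cluster_assignment(structure(integer(0), names = character(0)),
                               "butina", params))
  S <- .tanimoto_matrix(fps)
  nbr <- lapply(seq_len(n), function(i)
    setdiff(which(S[i, ] >= sim_threshold), i))
  assigned <- rep(FALSE, n)
  member_of <- integer(n)
  cid <- 0L
  while (!all(assigned)) {
    cnt <- vapply(seq_len(n), function(i) {
      if (assigned[i]) -1L else length(nbr[[i]][!assigned[nbr[[i]]]])
    }, integer(1))
    centroid <- which.max(cnt) # ties -> lowest index
    members <- c(centroid, nbr[[centroid]][!assigned[nbr[[centroid]]]])
    member_of[members] <- cid
    assigned[members] <- TRUE
    cid <- cid + 1L
  }
  names(member_of) <- ids
  .cluster_assignment(member_of, "butina", params)
}

.split_assignment <- function(partition_of, member_of, train_frac, seed,
                              method, params = list(), ks = NULL) {
  record_partition <- partition_of[as.character(member_of)]
  names(record_partition) <- names(member_of)
  structure(list(partition_of = partition_of, member_of = member_of,
                 record_partition = record_partition,
                 train_frac = train_frac, seed = seed, method = method,
                 params = params, ks = ks),
            class = "split_assignment")
}

#' Cluster-level train/validation split
#'
#' Clusters are shuffled with the seed and assigned to train until
#' `ceiling(train_frac * n_clusters)` clusters are reached; the remainder
#' goes to validation. All members of one cluster share one partition by
#' construction (the leakage-control guarantee).
#'
#' @param ca A `cluster_assignment`.
#' @param train_frac Fraction of clusters assigned to train (default 0.8).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A `split_assignment`.
#' @export
cluster_split <- function(ca, train_frac = 0.8, seed = 1) {
  stopifnot(inherits(ca, "cluster_assignment"))
  if (ca$n_clusters < 2) stop("need at least 2 clusters to split")
  cl_ids <- sort(unique(ca$member_of))
  set.seed(seed)
  shuffled <- sample(cl_ids)
  n_train <- ceiling(train_frac * length(cl_ids))
  partition_of <- stats::setNames(
    ifelse(seq_along(shuffled) <= n_train, "train", "val"),
    as.character(shuffled))
  .split_assignment(partition_of, ca$member_of, train_frac, seed,
                    paste0(ca$method, "+cluster_split"), ca$params)
}

#' Propagate a split from one modality to a converted dataset
#'
#' After AA records are converted to SMILES, each converted record inherits
#' the partition of its source record by id, preserving the original
#' cluster-based assignments across modalities.
#'
#' @param split A `split_assignment` over the source records.
#' @param converted A `property_dataset` (or character vector of ids).
#' @return A `split_assignment` restricted to the converted ids.
#' @export
propagate_split <- function(split, converted) {
  stopifnot(inherits(split, "split_assignment"))
  ids <- if (is.character(converted)) converted else dataset_ids(converted)
  if (length(ids) == 0)
    return(.split_assignment(character(0),
                             structure(integer(0), names = character(0)),
                             split$train_frac, split$seed,
                             split$method, split$params))
  missing <- setdiff(ids, names(split$record_partition))
  if (length(missing) > 0)
    stop("id(s) missing from source split: ", paste(missing, collapse = ", "))
  member_of <- split$member_of[ids]
  .split_assignment(split$partition_of, member_of, split$train_frac,
                    split$seed, split$method, split$params)
}

# two-sample Kolmogorov-Smirnov distance (sup of ECDF differences)
ks_distance <- function(x, y) {
  xs <- sort(x); ys <- sort(y)
  grid <- sort(unique(c(xs, ys)))
  Fx <- findInterval(grid, xs) / length(xs)
  Fy <- findInterval(grid, ys) / length(ys)
  max(abs(Fx - Fy))
}

#' Distribution-matched train/validation split for continuous labels
#'
#' Labels are binned into quantile bins; within each bin, records are
#' shuffled and assigned to train at `train_frac`, so both partitions carry
#' similar label distributions. Each record forms its own (singleton)
#' cluster. The Kolmogorov-Smirnov distance between the partitions' label
#' distributions is attached for auditing.
#'
#' @param values Named numeric vector of labels (names are record ids).
#' @param train_frac Train fraction (default 0.8).
#' @param n_bins Number of quantile bins (default 10).
#' @param seed Integer seed.
#' @return A `split_assignment` with a `ks` field.
#' @export
distribution_matched_split <- function(values, train_frac = 0.8,
                                       n_bins = 10, seed = 1) {
  n <- length(values)
  if (n < 5) stop("need at least 5 records for a matched split")
  ids <- names(values) %||% as.character(seq_len(n))
  qs <- unique(quantile(values, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(qs) <= 2) rep(1L, n) else
    as.integer(cut(values, breaks = qs, include.lowest = TRUE))
  part <- character(n)
  set.seed(seed)
  for (b in unique(bins)) {
    idx <- which(bins == b)
    idx <- idx[sample.int(length(idx))]
    k <- round(train_frac * length(idx))
    part[idx] <- c(rep("train", k), rep("val", length(idx) - k))
  }
  # guarantee both partitions are non-empty
  if (!any(part == "val")) part[length(part)] <- "val"
  if (!any(part == "train")) part[1] <- "train"
  member_of <- stats::setNames(seq_len(n) - 1L, ids)
  partition_of <- stats::setNames(part, as.character(member_of))
  ks <- ks_distance(values[part == "train"], values[part == "val"])
  .split_assignment(partition_of, member_of, train_frac, seed,
                    "distribution_matched", list(n_bins = n_bins), ks = ks)
}

#' Audit a split for cross-partition similarity leakage
#'
#' Counts cross-partition record pairs whose similarity reaches the
#' threshold. Exhaustive for n <= `exhaustive_limit`; above that a seeded
#' sample of pairs is scored and the sample size reported.
#'
#' @param split A `split_assignment`.
#' @param records List of records (or named character payload vector).
#' @param similarity_fn `function(payload_a, payload_b) -> similarity`.
#' @param threshold Similarity at or above which a pair is a violation.
#' @param exhaustive_limit Max n for the exhaustive scan (default 5000).
#' @param sample_pairs Number of pairs sampled above the limit.
#' @param seed Seed for pair sampling.
#' @return List: `n_violations`, `worst_pairs` (data.frame), `n_pairs`,
#'   `exhaustive`.
#' @export
audit_leakage <- function(split, records, similarity_fn, threshold,
                          exhaustive_limit = 5000, sample_pairs = 100000,
                          seed = 1) {
  x <- .as_sequences(records)
  part <- split$record_partition[x$ids]
  if (anyNA(part)) stop("split does not cover all records")
  tr <- which(part == "train"); va <- which(part == "val")
  if (length(tr) == 0 || length(va) == 0)
    return(list(n_violations = 0L, worst_pairs = NULL,
                n_pairs = 0L, exhaustive = TRUE))
  n_cross <- length(tr) * length(va)
  exhaustive <- length(x$ids) <= exhaustive_limit
  if (exhaustive) {
    pairs <- expand.grid(a = tr, b = va)
  } else {
    set.seed(seed)
    pairs <- data.frame(a = sample(tr, sample_pairs, replace = TRUE),
                        b = sample(va, sample_pairs, replace = TRUE))
  }
  sims <- mapply(function(i, j) similarity_fn(x$seqs[i], x$seqs[j]),
                 pairs$a, pairs$b)
  viol <- which(sims >= threshold)
  ord <- viol[order(-sims[viol])]
  worst <- if (length(ord) == 0) NULL else
    data.frame(id_a = x$ids[pairs$a[head(ord, 10)]],
               id_b = x$ids[pairs$b[head(ord, 10)]],
               similarity = sims[head(ord, 10)])
  list(n_violations = length(viol), worst_pairs = worst,
       n_pairs = nrow(pairs), exhaustive = exhaustive)
}
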