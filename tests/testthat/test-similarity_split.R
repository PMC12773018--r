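test_that("pairwise identity matches the plain-R alignment oracle", {
  r <- pairwise_identity("PEPTIDE", "PEPTIDE")
  expect_equal(unname(r["identity"]), 1)
  expect_equal(unname(r[c("cov_a", "cov_b")]), c(1, 1))
  expect_equal(unname(pairwise_identity("AAAA", "CCCC")["identity"]), 0)

  expect_equal(unname(pairwise_identity("PEPTIDE", "PEPT")),
               unname(oracle_align("PEPTIDE", "PEPT")))

  set.seed(23)
  for (k in 1:60) {
    a <- rand_seqs(1, 3, 18); b <- rand_seqs(1, 3, 18)
    expect_equal(unname(pairwise_identity(a, b)),
                 unname(oracle_pairwise(a, b)), info = paste(a, b))
    # symmetry under the canonical-orientation rule
    expect_equal(pairwise_identity(a, b)[["identity"]],
                 pairwise_identity(b, a)[["identity"]])
  }
})

test_that("greedy identity clustering equals its brute-force oracle", {
  # duplicated set collapses to one cluster
  seqs <- stats::setNames(rep("ACDEFGHIKL", 4), paste0("d", 1:4))
  expect_equal(cluster_sequences_by_identity(seqs)$n_clusters, 1)

  # shared block with low coverage stays separate
  set.seed(29)
  block <- "ILKMNPQRST"
  a <- paste0(rand_seqs(1, 15, 15), block, rand_seqs(1, 15, 15))
  b <- paste0(rand_seqs(1, 2, 2), block, rand_seqs(1, 28, 28))
  ca <- cluster_sequences_by_identity(c(x = a, y = b))
  expect_equal(ca$n_clusters, 2)

  # oracle equivalence on randomized corpora
  set.seed(31)
  for (trial in 1:50) {
    n <- sample(8:30, 1)
    seqs <- stats::setNames(rand_seqs(n, 5, 15), paste0("s", seq_len(n)))
    got <- cluster_sequences_by_identity(seqs)
    want <- oracle_identity_cluster(seqs)
    expect_equal(got$member_of[names(want)], want, info = trial)
    expect_equal(got$n_clusters, length(unique(want)))
    expect_equal(sort(unique(unname(got$member_of))),
                 0:(got$n_clusters - 1))
  }
})

test_that("Butina clustering equals its brute-force oracle", {
  # all-identical -> one cluster; all-dissimilar -> all singletons
  same <- lapply(1:5, function(i) make_fp(c(1, 2, 3)))
  names(same) <- paste0("m", 1:5)
  expect_equal(cluster_smiles_butina(same)$n_clusters, 1)
  disj <- lapply(1:5, function(i) make_fp((i * 10):(i * 10 + 2)))
  names(disj) <- paste0("m", 1:5)
  expect_equal(cluster_smiles_butina(disj)$n_clusters, 5)

  set.seed(37)
  for (trial in 1:50) {
    n <- sample(6:30, 1)
    fps <- lapply(seq_len(n), function(i)
      make_fp(sample(0:40, sample(3:10, 1))))
    names(fps) <- paste0("m", seq_len(n))
    got <- cluster_smiles_butina(fps, sim_threshold = 0.6)
    S <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      tanimoto(fps[[i]], fps[[j]])))
    want <- oracle_butina(S, 0.6)
    expect_equal(unname(got$member_of), want, info = trial)
  }
})

test_that("cluster splits follow the ceiling rule and are deterministic", {
  member_of <- stats::setNames(rep(0:99, each = 3),
                               paste0("r", 1:300))
  ca <- structure(list(member_of = member_of, method = "identity_greedy",
                       params = list(), n_clusters = 100),
                  class = "cluster_assignment")
  sp <- cluster_split(ca, 0.8, seed = 3)
  expect_equal(sum(sp$partition_of == "train"), 80)
  expect_equal(sum(sp$partition_of == "val"), 20)

  # 5 clusters -> ceiling(0.8 * 5) = 4 train
  ca5 <- structure(list(member_of = stats::setNames(0:4, paste0("c", 1:5)),
                        method = "x", params = list(), n_clusters = 5),
                   class = "cluster_assignment")
  sp5 <- cluster_split(ca5, 0.8, seed = 1)
  expect_equal(sum(sp5$partition_of == "train"), 4)

  expect_identical(cluster_split(ca, 0.8, seed = 17)$record_partition,
                   cluster_split(ca, 0.8, seed = 17)$record_partition)
  ca1 <- structure(list(member_of = c(a = 0L), method = "x",
                        params = list(), n_clusters = 1),
                   class = "cluster_assignment")
  expect_error(cluster_split(ca1, 0.8, 1), "at least 2")
})

test_that("cluster-then-split never separates cluster members", {
  set.seed(41)
  for (trial in 1:10) {
    base <- rand_seqs(12, 8, 16)
    # plant near-duplicates so clusters are non-trivial
    seqs <- c(base, vapply(base[1:6], function(s) {
      v <- strsplit(s, "")[[1]]
      v[1] <- "A"
      paste(v, collapse = "")
    }, character(1)))
    names(seqs) <- paste0("s", seq_along(seqs))
    ca <- cluster_sequences_by_identity(seqs)
    if (ca$n_clusters < 2) next
    sp <- cluster_split(ca, 0.8, seed = trial)
    agg <- tapply(sp$record_partition, ca$member_of[names(seqs)],
                  function(x) length(unique(x)))
    expect_true(all(agg == 1))
    got <- sum(sp$partition_of == "train")
    expect_equal(got, ceiling(0.8 * ca$n_clusters))
  }
})

test_that("split propagation preserves assignments across modalities", {
  sp <- local({
    member_of <- stats::setNames(c(0L, 1L), c("p1", "p2"))
    ca <- structure(list(member_of = member_of, method = "x",
                         params = list(), n_clusters = 2),
                    class = "cluster_assignment")
    cluster_split(ca, 0.5, seed = 2)
  })
  out <- propagate_split(sp, c("p1", "p2"))
  expect_equal(out$record_partition[c("p1", "p2")],
               sp$record_partition[c("p1", "p2")])
  expect_error(propagate_split(sp, c("p1", "zz")), "zz")
  empty <- propagate_split(sp, character(0))
  expect_length(empty$record_partition, 0)
})

test_that("distribution-matched splits balance the label distribution", {
  set.seed(43)
  vals <- stats::setNames(runif(1000), paste0("v", 1:1000))
  sp <- distribution_matched_split(vals, n_bins = 10, seed = 7)
  expect_lt(sp$ks, 0.1)
  tr <- vals[sp$record_partition[names(vals)] == "train"]
  va <- vals[sp$record_partition[names(vals)] == "val"]
  expect_lt(abs(mean(tr) - mean(va)) / abs(mean(vals)), 0.05)
  expect_lt(abs(var(tr) - var(va)) / var(vals), 0.05)
  expect_equal(length(tr) / 1000, 0.8, tolerance = 0.02)

  # identical values: KS 0 by construction
  same <- stats::setNames(rep(2.5, 40), paste0("w", 1:40))
  expect_equal(distribution_matched_split(same, seed = 1)$ks, 0)
  expect_error(distribution_matched_split(stats::setNames(1:4,
                                                          letters[1:4])),
               "at least 5")
})

test_that("leakage audit finds planted duplicates and clears clean splits", {
  # similarity under the clustering rule: identity gated by coverage
  # (a high-identity 2-residue overlap window is not leakage)
  simfn <- function(a, b) {
    st <- pairwise_identity(a, b)
    if (st[["cov_a"]] >= 0.8 && st[["cov_b"]] >= 0.8)
      st[["identity"]] else 0
  }
  set.seed(47)
  # split produced by clustering: no cross-partition near-identity
  seqs <- stats::setNames(rand_seqs(60, 8, 14), paste0("s", 1:60))
  seqs[31:60] <- seqs[1:30] # exact duplicates share clusters
  names(seqs) <- paste0("s", 1:60)
  ca <- cluster_sequences_by_identity(seqs)
  sp <- cluster_split(ca, 0.8, seed = 3)
  rep_audit <- audit_leakage(sp, seqs, simfn, threshold = 0.95)
  expect_equal(rep_audit$n_violations, 0)
  expect_true(rep_audit$exhaustive)

  # a random (non-cluster) split of duplicated sequences leaks
  part <- rep(c("train", "val"), each = 30) # each duplicate pair crosses
  bad <- structure(list(record_partition = stats::setNames(part,
                                                           names(seqs))),
                   class = "split_assignment")
  expect_gt(audit_leakage(bad, seqs, simfn, threshold = 0.999)$n_violations,
            0)

  # single-partition corpus has no cross pairs
  solo <- structure(list(record_partition = stats::setNames(
    rep("train", 60), names(seqs))), class = "split_assignment")
  expect_equal(audit_leakage(solo, seqs, simfn, 0.5)$n_violations, 0)
})
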