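test_that("generators are reproducible and emit valid records", {
  cfg <- synth_config(n = 200, seed = 77)
  d1 <- gen_binary_corpus(cfg, "charge")
  d2 <- gen_binary_corpus(cfg, "charge")
  expect_identical(dataset_payloads(d1), dataset_payloads(d2))
  expect_identical(dataset_labels(d1), dataset_labels(d2))
  # validity is enforced at construction; re-validate explicitly
  for (r in d1$records[1:20]) expect_identical(validate_record(r), r)

  hl1 <- gen_halflife(synth_config(n = 50, seed = 78), n_pretrain = 100)
  hl2 <- gen_halflife(synth_config(n = 50, seed = 78), n_pretrain = 100)
  expect_identical(vapply(hl1$halflife, `[[`, numeric(1), "hours"),
                   vapply(hl2$halflife, `[[`, numeric(1), "hours"))
  expect_error(synth_config(n = 10, class_balance = 0), "class_balance")
})

test_that("achieved class balance tracks the requested balance", {
  for (bal in c(0.22, 0.5, 0.78)) {
    cfg <- synth_config(n = 2000, class_balance = bal, seed = 79)
    for (rule in c("charge", "hydropathy", "motif")) {
      y <- dataset_labels(gen_binary_corpus(cfg, rule))
      expect_lt(abs(mean(y) - bal), 0.03)
    }
  }
})

test_that("SMILES conversion preserves ids and labels for propagation", {
  cfg <- synth_config(n = 30, seed = 81)
  ds <- gen_binary_corpus(cfg, "hydropathy")
  smi <- convert_dataset_to_smiles(ds)
  expect_identical(dataset_ids(smi), dataset_ids(ds))
  expect_identical(dataset_labels(smi), dataset_labels(ds))
  expect_true(all(vapply(smi$records, function(r)
    r$modality == "SMILES", logical(1))))
  # payloads reparse as molecules
  expect_silent(lapply(dataset_payloads(smi)[1:5], parse_smiles))

  # propagation: converted records inherit the AA partition
  ca <- cluster_sequences_by_identity(
    stats::setNames(dataset_payloads(ds), dataset_ids(ds)))
  sp <- cluster_split(ca, 0.8, seed = 4)
  sp2 <- propagate_split(sp, smi)
  expect_identical(sp2$record_partition[dataset_ids(smi)],
                   sp$record_partition[dataset_ids(ds)])
})

test_that("permeability mixture matches the labeling rule and tail mass", {
  cfg <- synth_config(n = 10000, class_balance = 0.5, seed = 83)
  out <- gen_permeability_corpus(cfg, means = c(-8, -5),
                                 sds = c(0.8, 0.8))
  logp <- dataset_labels(out$continuous)
  y <- dataset_labels(out$binary)
  # threshold rule: >= -6.0 is high (boundary value included)
  expect_identical(y, as.numeric(logp >= -6.0))
  # closed-form high fraction: equal-weight Gaussian tails above -6
  want <- 0.5 * (1 - pnorm((-6 + 8) / 0.8)) +
    0.5 * (1 - pnorm((-6 + 5) / 0.8))
  expect_lt(abs(mean(y) - want), 0.02)
})

test_that("the affinity generator is self-consistent and class-coherent", {
  cfg0 <- synth_config(n = 100, length_range = c(8, 15), noise_sd = 0,
                       seed = 87)
  pairs <- gen_affinity_pairs(cfg0, offset = 3)
  # independent re-evaluation of the planted compatibility formula
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  for (p in pairs[1:25]) {
    hp <- kd[strsplit(p$peptide$payload, "")[[1]]] / 4.5
    hq <- kd[strsplit(p$protein_seq, "")[[1]]] / 4.5
    i <- seq_along(hp); j <- i + 3; keep <- j <= length(hq)
    raw <- sum(hp[keep] * hq[j[keep]]) / sqrt(sum(keep))
    want <- 8 + 3 * min(max(raw * 2, -4 / 3), 4 / 3)
    expect_equal(p$score, unname(want), tolerance = 1e-12)
  }
  # classes are always the image of the score
  noisy <- gen_affinity_pairs(synth_config(n = 200, noise_sd = 0.5,
                                           seed = 88))
  expect_identical(vapply(noisy, `[[`, character(1), "class"),
                   affinity_class(vapply(noisy, `[[`, numeric(1),
                                         "score")))
  expect_true(all(vapply(pairs, `[[`, numeric(1), "score") >= 4 - 1e-9))
  expect_true(all(vapply(pairs, `[[`, numeric(1), "score") <= 12 + 1e-9))
})

test_that("half-life hours are positive and track the latent stability", {
  hl <- gen_halflife(synth_config(n = 300, noise_sd = 0.6, seed = 91),
                     n_pretrain = 600)
  hours <- vapply(hl$halflife, `[[`, numeric(1), "hours")
  expect_true(all(hours > 0))
  ids <- vapply(hl$halflife, function(r) r$peptide$id, character(1))
  stab <- stats::setNames(dataset_labels(hl$stability),
                          dataset_ids(hl$stability))
  expect_true(all(ids %in% names(stab)))
  # log1p(hours) correlates with the (noisy) stability signal
  expect_gte(cor(log1p(hours), stab[ids]), 0.6)
  expect_error(gen_halflife(synth_config(n = 600, seed = 1)), "capped")
})

test_that("stronger planted effects never hurt the gbt head", {
  med_f1 <- function(effect) {
    f1s <- vapply(1:5, function(seed) {
      cfg <- synth_config(n = 600, effect_size = effect, noise_sd = 1,
                          seed = 100 + seed)
      ds <- gen_binary_corpus(cfg, "hydropathy")
      y <- dataset_labels(ds)
      X <- featurize_dataset(ds, embedder_spec("baseline_seq", "AA"),
                             pooled = TRUE)
      tr <- 1:480; va <- 481:600
      fit <- train_head(head_spec("gbt", "binary", seed = seed),
                        X[tr, , drop = FALSE], y[tr])
      classification_metrics(y[va], predict_head(
        fit, X[va, , drop = FALSE]))$f1
    }, numeric(1))
    median(f1s)
  }
  f <- vapply(c(0.5, 2, 5), med_f1, numeric(1))
  expect_true(all(diff(f) >= -1e-9))
})
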