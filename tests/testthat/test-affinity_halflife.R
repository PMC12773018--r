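test_that("affinity unification follows the -log10 molar scale", {
  expect_equal(as.numeric(unify_affinity(1, "nM")), 9)
  expect_equal(as.numeric(unify_affinity(1, "M")), 0)
  expect_equal(as.numeric(unify_affinity(100, "nM")), 7)
  expect_equal(as.numeric(unify_affinity(1, "pM")) -
                 as.numeric(unify_affinity(1, "nM")), 3)
  # strictly decreasing in molar value
  v <- sort(10^runif(20, -12, 0))
  s <- vapply(v, function(x) as.numeric(unify_affinity(x, "M")),
              numeric(1))
  expect_true(all(diff(s) < 0))
  expect_error(unify_affinity(-1, "nM"), "> 0")
  expect_equal(attr(unify_affinity(5, "uM", "IC50"), "kind"), "IC50")
})

test_that("affinity classes use the documented boundary convention", {
  expect_equal(affinity_class(9.5), "strong")
  expect_equal(affinity_class(8.0), "medium")
  expect_equal(affinity_class(6.5), "weak")
  eps <- 1e-9
  expect_equal(affinity_class(9), "strong")
  expect_equal(affinity_class(7), "medium")
  expect_equal(affinity_class(7 - eps), "weak")
  expect_equal(affinity_class(9 - eps), "medium")
})

test_that("cross-attention forward is deterministic and mask-invariant", {
  spec <- affinity_model_spec(seed = 13)
  pep <- baseline_sequence_featurizer("ACDEFGHIKL")
  prot <- baseline_sequence_featurizer(rand_seqs(1, 40, 40))
  o1 <- cross_attention_forward(pep, prot, spec)
  o2 <- cross_attention_forward(pep, prot, spec)
  expect_true(all(is.finite(c(o1$score_pred, o1$class_logits))))
  expect_identical(o1, o2)
  expect_length(o1$class_logits, 3)
  expect_error(cross_attention_forward(pep, mean_pool(prot), spec),
               "unpooled")

  # batching with a longer protein (extra masked padding) leaves the
  # first pair's outputs unchanged
  pd <- asNamespace("peptidev")
  set.seed(13)
  params <- pd$.affinity_init_params(spec, 24, 24)
  model <- structure(list(spec = spec, parameters = params,
                          pe = pd$posenc(90, spec$embed_dim),
                          ymu = 0, ysd = 1), class = "affinity_model")
  rec <- peptide_record("q1", "AA", "ACDEFGHIKL",
                        labels = list(binding_affinity = 8))
  rec2 <- peptide_record("q2", "AA", "KLWWYPSTVM",
                         labels = list(binding_affinity = 6))
  p1 <- affinity_pair(rec, rand_seqs(1, 40, 40), 8)
  p2 <- affinity_pair(rec2, rand_seqs(1, 75, 75), 6)
  alone <- predict_affinity(model, list(p1))$score
  batched <- predict_affinity(model, list(p1, p2))$score[1]
  expect_lt(abs(alone - batched), 1e-6)
})

test_that("class head stays untouched when the multitask weight is zero", {
  cfg <- synth_config(n = 60, length_range = c(8, 12), noise_sd = 0.2,
                      seed = 71)
  pairs <- gen_affinity_pairs(cfg)
  vals <- stats::setNames(vapply(pairs, `[[`, numeric(1), "score"),
                          vapply(pairs, function(p) p$peptide$id,
                                 character(1)))
  split <- distribution_matched_split(vals, seed = 2)
  spec0 <- affinity_model_spec(class_loss_weight = 0, epochs = 2, seed = 3)
  pd <- asNamespace("peptidev")
  set.seed(3)
  init <- pd$.affinity_init_params(spec0, 24, 24)
  m <- train_affinity(pairs, spec0, split)
  expect_identical(m$parameters$Wc, init$Wc)
  expect_identical(m$parameters$bc3, init$bc3)
  expect_false(identical(m$parameters$Ws, init$Ws))
})

test_that("half-life unit conversion and record invariants hold", {
  expect_equal(halflife_normalize(90, "min"), 1.5)
  expect_equal(halflife_normalize(2, "d"), 48)
  expect_equal(halflife_normalize(3.5, "h"), 3.5)
  expect_error(halflife_normalize(-1, "h"), "> 0")

  rec <- peptide_record("h1", "AA", "ACDEFG",
                        labels = list(half_life = 12))
  hr <- halflife_record(rec, 12)
  expect_identical(hr$target, log1p(12))
  expect_error(halflife_record(rec, -2))
})

test_that("the four half-life configurations all produce CV reports", {
  hl <- gen_halflife(synth_config(n = 60, length_range = c(8, 14),
                                  noise_sd = 0.5, seed = 97),
                     n_pretrain = 120)
  out <- run_halflife_protocol(hl$stability, hl$halflife, n_folds = 3,
                               seed = 4,
                               hyperparams = list(epochs = 5,
                                                  nrounds = 30))
  expect_setequal(names(out), c("gbt_hours", "gbt_log1p",
                                "transformer_hours",
                                "transformer_log1p"))
  for (nm in names(out)) {
    expect_equal(nrow(out[[nm]]$per_fold), 3, info = nm)
    expect_true(is.finite(out[[nm]]$mean$spearman_rho), info = nm)
  }
  expect_true(out$transformer_log1p$warm_started)
  expect_false(out$gbt_log1p$warm_started)
})

test_that("half-life protocol validates fold counts and inverts log1p", {
  hl <- gen_halflife(synth_config(n = 30, noise_sd = 0.6, seed = 73),
                     n_pretrain = 60)
  expect_error(pretrain_finetune_halflife(hl$stability, hl$halflife[1:4],
                                          family = "gbt", n_folds = 5),
               "smaller than fold")
  res <- pretrain_finetune_halflife(hl$stability, hl$halflife,
                                    family = "gbt", target = "log1p",
                                    n_folds = 3, seed = 2)
  expect_equal(nrow(res$per_fold), 3)
  expect_false(res$warm_started) # trees have no warm start
  expect_true(all(c("pearson_r", "spearman_rho", "r2") %in%
                    names(res$mean)))
  # log1p target round trip: expm1 of predictions gives positive hours
  X <- peptidev:::.featurize_seqs(
    vapply(hl$halflife, function(r) r$peptide$payload, character(1)),
    "gbt")
  y <- vapply(hl$halflife, function(r) r$target, numeric(1))
  fit <- train_head(head_spec("gbt", "regression", seed = 1), X, y)
  hours <- expm1(predict_head(fit, X))
  expect_true(all(hours > -1e-12))
})
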