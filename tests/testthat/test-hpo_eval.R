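test_that("log-uniform sampling is uniform in log space", {
  expect_error(p_loguniform(-1, 1), "0 < a < b")
  sp <- search_space(lr = p_loguniform(1e-4, 1e-1))
  set.seed(61)
  draws <- replicate(10000, sample_params(sp)$lr)
  expect_true(all(draws >= 1e-4 & draws <= 1e-1))
  # each decade holds ~1/3 of the mass
  expect_equal(mean(draws < 1e-3), 1 / 3, tolerance = 0.02 * 3)
  expect_equal(mean(draws >= 1e-2), 1 / 3, tolerance = 0.02 * 3)

  sp2 <- search_space(k = p_categorical(list("a")))
  expect_equal(sample_params(sp2)$k, "a")
  sp3 <- search_space(n = p_int(2, 5), u = p_uniform(0, 1))
  d3 <- sample_params(sp3)
  expect_true(d3$n %in% 2:5)
  expect_true(d3$u >= 0 && d3$u <= 1)
})

test_that("random search finds smooth optima and is reproducible", {
  sp <- search_space(x = p_loguniform(0.1, 10))
  obj <- function(p) -(p$x - 2)^2
  for (seed in 1:5) {
    res <- run_search(sp, obj, n_trials = 200, seed = seed)
    expect_lt(abs(res$best$params$x - 2) / 2, 0.1)
  }
  r1 <- run_search(sp, obj, n_trials = 25, seed = 9)
  r2 <- run_search(sp, obj, n_trials = 25, seed = 9)
  expect_identical(r1$history$objective, r2$history$objective)
  expect_identical(r1$best$params, r2$best$params)

  one <- run_search(sp, obj, n_trials = 1, seed = 3)
  expect_equal(one$best$trial_id, 1)
  expect_error(run_search(sp, function(p) stop("boom"), 5, 1),
               "all trials failed")
  # failures are recorded, not fatal, when some trials succeed
  flaky <- function(p) if (p$x > 1) stop("bad region") else p$x
  res <- run_search(sp, flaky, n_trials = 50, seed = 2)
  expect_true(any(res$history$status == "failed"))
  expect_true(res$best$params$x <= 1)
})

test_that("larger budgets dominate smaller ones on a smooth objective", {
  sp <- search_space(x = p_loguniform(0.01, 100))
  obj <- function(p) -abs(log(p$x / 3))
  best_at <- function(n, seed) run_search(sp, obj, n, seed)$best$objective
  b200 <- vapply(1:20, function(s) best_at(200, s), numeric(1))
  b20 <- vapply(1:20, function(s) best_at(20, s + 100), numeric(1))
  expect_gt(median(b200), median(b20))
})

test_that("classification metrics match their oracles", {
  m <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(m$auc, 0.75)

  perfect <- classification_metrics(c(1, 0, 1), c(0.9, 0.1, 0.8))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$accuracy, 1)

  # all-negative predictions on mixed labels: f1 = 0, mcc = 0 (0/0 rule)
  deg <- classification_metrics(c(1, 0, 1, 0), c(0.1, 0.2, 0.05, 0.3))
  expect_equal(deg$f1, 0)
  expect_equal(classification_metrics(c(1, 0), c(0.2, 0.1),
                                      threshold = 0.9)$mcc, 0)

  # single-class truth: AUC is missing, not zero
  expect_true(is.na(classification_metrics(c(1, 1), c(0.2, 0.4))$auc))

  set.seed(67)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2) # duplicates exercise tie averaging
    s[s == 0.5] <- 0.52     # a score exactly at threshold breaks the
                            # flip symmetry below; exclude that case
    m <- classification_metrics(y, s)
    expect_equal(m$auc, oracle_auc(y, s), info = k)
    expect_gte(m$best_f1, m$f1)
    # mcc invariant under simultaneous label and prediction flip
    expect_equal(classification_metrics(1 - y, 1 - s, threshold = 0.5)$mcc,
                 classification_metrics(y, s, threshold = 0.5)$mcc,
                 tolerance = 1e-12)
  }
})

test_that("regression metrics match the rank-formula oracle", {
  y <- c(1.5, 2.2, 3.9)
  m <- regression_metrics(y, y)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$spearman_rho, 1)
  expect_equal(m$r2, 1)
  m2 <- regression_metrics(y, -y)
  expect_equal(m2$pearson_r, -1)
  expect_equal(m2$spearman_rho, -1)
  expect_equal(regression_metrics(c(1, 2, 3), c(3, 1, 2))$spearman_rho,
               -0.5)
  expect_true(is.na(regression_metrics(rep(1, 5), rnorm(5))$pearson_r))
})

test_that("best-model selection follows the documented tie rules", {
  mk <- function(best_f1 = NA, mcc = NA, rho = NA, r2 = NA)
    structure(list(best_f1 = best_f1, mcc = mcc, spearman_rho = rho,
                   r2 = r2), class = "metric_report")
  res <- list(gbt = mk(best_f1 = 0.9, mcc = 0.5),
              mlp = mk(best_f1 = 0.8, mcc = 0.9))
  expect_equal(select_best(res, "binary")$family, "gbt")
  res2 <- list(b = mk(rho = 0.7, r2 = 0.5), a = mk(rho = 0.7, r2 = 0.4))
  expect_equal(select_best(res2, "regression")$family, "b")
  res3 <- list(b = mk(rho = 0.7, r2 = 0.5), a = mk(rho = 0.7, r2 = 0.5))
  expect_equal(select_best(res3, "regression")$family, "a") # lexicographic
  expect_error(select_best(list(), "binary"), "empty")
})
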