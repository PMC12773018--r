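# The cross-attention multitask binding-affinity model, the unified
# affinity scale, and the stability-pretrain -> half-life fine-tune
# regression protocol.

#' Unify an affinity measurement onto the -log10 molar scale
#'
#' Kd/Ki/IC50 readouts are pooled onto one scale by a single negative log
#' transform of the molar value; the readout kind is recorded as metadata
#' but not numerically corrected (no Cheng-Prusoff adjustment).
#'
#' @param value Measured value (> 0).
#' @param unit One of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @param kind `"Kd"`, `"Ki"` or `"IC50"` (metadata only).
#' @return Unified score: 1 nM -> 9, 1 uM -> 6, 1 M -> 0.
#' @export
unify_affinity <- function(value, unit = c("M", "mM", "uM", "nM", "pM"),
                           kind = c("Kd", "Ki", "IC50")) {
  unit <- match.arg(unit)
  kind <- match.arg(kind)
  if (any(value <= 0)) stop("affinity value must be > 0")
  factor <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[unit]]
  score <- -log10(value * factor)
  attr(score, "kind") <- kind
  score
}

#' Discrete affinity class of a unified score
#'
#' `strong` iff score >= 9 (nM-pM binders), `medium` iff 7 <= score < 9,
#' `weak` iff score < 7 (uM and weaker). Ties at 9 are strong, at 7 medium.
#'
#' @param score Unified affinity score(s).
#' @return Character vector in `{weak, medium, strong}`.
#' @export
affinity_class <- function(score) {
  stopifnot(all(is.finite(score)))
  ifelse(score >= 9, "strong", ifelse(score >= 7, "medium", "weak"))
}

AFFINITY_CLASSES <- c("weak", "medium", "strong")

#' Create an affinity pair
#'
#' @param peptide A `peptide_record` (AA or SMILES modality).
#' @param protein_seq Canonical protein sequence (non-empty).
#' @param score Unified affinity score (finite).
#' @param kind Readout kind metadata.
#' @return An `affinity_pair`; `class` is derived from the score.
#' @export
affinity_pair <- function(peptide, protein_seq, score, kind = "Kd") {
  stopifnot(inherits(peptide, "peptide_record"), is.finite(score))
  .check_canonical(protein_seq, min_len = 1)
  structure(list(peptide = peptide, protein_seq = protein_seq,
                 score = score, class = affinity_class(score), kind = kind),
            class = "affinity_pair")
}

#' Specify the cross-attention affinity model
#'
#' Peptide tokens attend to protein tokens through `n_layers` cross-
#' attention blocks (one-directional peptide -> protein) with sinusoidal
#' position channels added to both streams; the final peptide state is
#' mean-pooled and split into a scalar regression head and a 3-logit
#' classification head (multitask). Protein embeddings are always
#' unpooled; peptide pooling is the experimental variable.
#'
#' @param embed_dim Model width D (divisible by `n_heads`).
#' @param n_heads Attention heads.
#' @param n_layers Cross-attention blocks.
#' @param ff Feed-forward width.
#' @param dropout Dropout probability (training only; default 0).
#' @param peptide_embedding `"unpooled"` or `"pooled"`.
#' @param class_loss_weight Multitask weight lambda (>= 0) on the class
#'   cross-entropy.
#' @param loss Regression loss: `"huber"` (default) or `"mse"`.
#' @param huber_delta Huber delta.
#' @param epochs,lr,batch Training protocol.
#' @param seed Integer seed.
#' @return An `affinity_model_spec`.
#' @export
affinity_model_spec <- function(embed_dim = 32, n_heads = 4, n_layers = 1,
                                ff = 64, dropout = 0,
                                peptide_embedding = c("unpooled", "pooled"),
                                class_loss_weight = 0.3, loss = "huber",
                                huber_delta = 1, epochs = 35, lr = 4e-3,
                                batch = 96, seed = 1) {
  peptide_embedding <- match.arg(peptide_embedding)
  if (embed_dim %% n_heads != 0)
    stop("embed_dim must be divisible by n_heads")
  if (class_loss_weight < 0) stop("class_loss_weight must be >= 0")
  structure(list(embed_dim = embed_dim, n_heads = n_heads,
                 n_layers = n_layers, ff = ff, dropout = dropout,
                 peptide_embedding = peptide_embedding,
                 class_loss_weight = class_loss_weight, loss = loss,
                 huber_delta = huber_delta, epochs = epochs, lr = lr,
                 batch = batch, seed = as.integer(seed)),
            class = "affinity_model_spec")
}

.affinity_init_params <- function(spec, d_pep, d_prot) {
  D <- spec$embed_dim
  params <- list(Wp = nn_init_param(d_pep, D), bp = nn_init_param(D),
                 Wr = nn_init_param(d_prot, D), br = nn_init_param(D))
  for (l in seq_len(spec$n_layers)) {
    blk <- mha_init(D, spec$ff)
    names(blk) <- paste0("L", l, "_", names(blk))
    params <- c(params, blk)
  }
  c(params,
    list(Wt = nn_init_param(D, D), bt = nn_init_param(D),
         Ws = nn_init_param(D, 1), bs = nn_init_param(1),
         Wc = nn_init_param(D, 3), bc3 = nn_init_param(3)))
}

.affinity_forward <- function(pn, spec, pepb, protb, pe) {
  Xp <- ag_add_posenc(
    ag_add_bias(ag_cube_mm(ag_var(pepb$X), pn$Wp), pn$bp), pe)
  Xr <- ag_add_posenc(
    ag_add_bias(ag_cube_mm(ag_var(protb$X), pn$Wr), pn$br), pe)
  Z <- Xp
  for (l in seq_len(spec$n_layers)) {
    blk <- pn[paste0("L", l, "_",
                     c("Wq", "Wk", "Wv", "Wo", "bo",
                       "W1", "b1", "W2", "b2"))]
    names(blk) <- sub("^L[0-9]+_", "", names(blk))
    Z <- mha_forward(blk, Z, Xr, protb$mask, spec$n_heads)
  }
  pooled <- ag_masked_meanpool(Z, pepb$mask)
  h <- ag_relu(ag_add_bias(ag_mm(pooled, pn$Wt), pn$bt))
  list(score = ag_add_bias(ag_mm(h, pn$Ws), pn$bs),
       logits = ag_add_bias(ag_mm(h, pn$Wc), pn$bc3))
}

#' Forward pass of the cross-attention affinity model
#'
#' Deterministic at inference for fixed parameters; appending masked
#' padding to the protein stream leaves outputs unchanged.
#'
#' @param pep Peptide `embedding_matrix` (pooled or unpooled per `spec`).
#' @param prot Protein `embedding_matrix` (must be unpooled).
#' @param spec An `affinity_model_spec`.
#' @param params Optional fitted parameters; when NULL a fresh
#'   seed-initialized parameter set is used.
#' @return List: `score_pred` (scalar), `class_logits` (length 3).
#' @export
cross_attention_forward <- function(pep, prot, spec = affinity_model_spec(),
                                    params = NULL) {
  if (isTRUE(attr(prot, "pooled"))) stop("protein stream must be unpooled")
  if (nrow(pep) == 0 || nrow(prot) == 0) stop("empty sequence")
  if (is.null(params)) {
    set.seed(spec$seed)
    params <- .affinity_init_params(spec, ncol(pep), ncol(prot))
  }
  pepb <- pad_batch(list(unclass(pep)))
  protb <- pad_batch(list(unclass(prot)))
  pe <- posenc(max(nrow(pep), nrow(prot)) + 8, spec$embed_dim)
  ag_tape_begin()
  pn <- params_as_nodes(params)
  out <- .affinity_forward(pn, spec, pepb, protb, pe)
  list(score_pred = as.numeric(out$score$value),
       class_logits = as.numeric(out$logits$value))
}

.embed_pairs <- function(pairs, spec) {
  pep_spec <- embedder_spec("baseline_seq", "AA", kind = "baseline_seq")
  prot_spec <- embedder_spec("baseline_seq", "protein",
                             kind = "baseline_seq")
  pep <- lapply(pairs, function(p) {
    m <- embed_record(p$peptide$payload, pep_spec, pooled = FALSE)
    if (spec$peptide_embedding == "pooled") mean_pool(m) else m
  })
  prot <- lapply(pairs, function(p)
    embed_record(p$protein_seq, prot_spec, pooled = FALSE))
  list(pep = lapply(pep, unclass), prot = lapply(prot, unclass))
}

#' Train the cross-attention affinity model
#'
#' Loss = regression loss (Huber by default) on the unified score plus
#' `class_loss_weight` times the cross-entropy over classes derived from
#' the true scores; with weight 0 this reduces to pure regression. The
#' validation selection metric is Spearman rho.
#'
#' @param pairs List of `affinity_pair`s (AA peptides; baseline
#'   featurizers are used for both streams).
#' @param spec An `affinity_model_spec`.
#' @param split A `split_assignment` over the pair ids (normally from
#'   [distribution_matched_split()]).
#' @return An `affinity_model`: fitted parameters, spec, and train/val
#'   `metrics` (regression report + class agreement).
#' @export
train_affinity <- function(pairs, spec = affinity_model_spec(), split) {
  ids <- vapply(pairs, function(p) p$peptide$id, character(1))
  part <- split$record_partition[ids]
  if (anyNA(part)) stop("split does not cover all pairs")
  if (!any(part == "val") || !any(part == "train"))
    stop("degenerate split: both partitions must be non-empty")
  y <- vapply(pairs, function(p) p$score, numeric(1))
  ycl <- match(affinity_class(y), AFFINITY_CLASSES)
  # the regression head trains on standardized scores (stored and undone
  # at prediction time); the class head sees the raw-scale classes
  ymu <- mean(y); ysd <- max(sd(y), 1e-12)
  ys <- (y - ymu) / ysd
  emb <- .embed_pairs(pairs, spec)
  set.seed(spec$seed)
  params <- .affinity_init_params(spec, ncol(emb$pep[[1]]),
                                  ncol(emb$prot[[1]]))
  pe <- posenc(max(vapply(emb$prot, nrow, numeric(1)),
                   vapply(emb$pep, nrow, numeric(1))) + 8, spec$embed_dim)
  tr <- which(part == "train")
  regloss <- if (spec$loss == "huber")
    function(z, yy) loss_huber(z, yy, spec$huber_delta) else loss_mse
  opt <- adam_new(params, lr = spec$lr)
  for (ep in seq_len(spec$epochs)) {
    for (mb in .nn_minibatches(length(tr), spec$batch)) {
      idx <- tr[mb]
      pepb <- pad_batch(emb$pep[idx])
      protb <- pad_batch(emb$prot[idx])
      ag_tape_begin()
      pn <- params_as_nodes(params)
      out <- .affinity_forward(pn, spec, pepb, protb, pe)
      lr_ <- regloss(out$score$value, ys[idx])
      if (spec$class_loss_weight > 0) {
        lc <- loss_softmax_ce(out$logits$value, ycl[idx])
        ag_backward(list(out$score, out$logits),
                    list(lr_$grad, spec$class_loss_weight * lc$grad))
      } else {
        ag_backward(out$score, lr_$grad)
      }
      up <- adam_step(params, collect_grads(pn), opt)
      params <- up$params; opt <- up$state
    }
  }
  model <- structure(list(spec = spec, parameters = params, pe = pe,
                          ymu = ymu, ysd = ysd),
                     class = "affinity_model")
  pred <- predict_affinity(model, pairs, emb = emb)
  va <- which(part == "val")
  model$metrics <- list(
    train = regression_metrics(y[tr], pred$score[tr]),
    val = regression_metrics(y[va], pred$score[va]),
    val_class_agreement = mean(
      pred$class[va] == affinity_class(pred$score[va])))
  model
}

#' Predict with a trained affinity model
#'
#' @param model An `affinity_model`.
#' @param pairs List of `affinity_pair`s.
#' @param emb Precomputed embeddings (internal use).
#' @return List: `score` (numeric), `class` (argmax of the class head).
#' @export
predict_affinity <- function(model, pairs, emb = NULL) {
  spec <- model$spec
  if (is.null(emb)) emb <- .embed_pairs(pairs, spec)
  n <- length(emb$pep)
  score <- numeric(n); cls <- integer(n)
  chunk <- split(seq_len(n), ceiling(seq_len(n) / 256))
  for (idx in chunk) {
    pepb <- pad_batch(emb$pep[idx])
    protb <- pad_batch(emb$prot[idx])
    pe <- model$pe
    need <- max(dim(pepb$X)[1], dim(protb$X)[1])
    if (nrow(pe) < need) pe <- posenc(need, spec$embed_dim)
    ag_tape_begin()
    pn <- params_as_nodes(model$parameters)
    out <- .affinity_forward(pn, spec, pepb, protb, pe)
    score[idx] <- as.numeric(out$score$value) * (model$ysd %||% 1) +
      (model$ymu %||% 0)
    cls[idx] <- apply(out$logits$value, 1, which.max)
  }
  list(score = score, class = AFFINITY_CLASSES[cls])
}

# ---- half-life -----------------------------------------------------------

#' Convert a half-life measurement to hours
#'
#' @param value Measured value (> 0).
#' @param unit `"min"`, `"h"` or `"d"`.
#' @return Half-life in hours.
#' @export
halflife_normalize <- function(value, unit = c("h", "min", "d")) {
  unit <- match.arg(unit)
  if (any(value <= 0)) stop("half-life must be > 0")
  switch(unit, min = value / 60, h = value, d = value * 24)
}

#' Create a half-life record
#'
#' @param peptide A `peptide_record`.
#' @param hours Half-life in hours (> 0).
#' @return A `halflife_record` with `target = log(1 + hours)` (natural
#'   log; the base is configurable downstream but defaults to e).
#' @export
halflife_record <- function(peptide, hours) {
  stopifnot(inherits(peptide, "peptide_record"), hours > 0)
  structure(list(peptide = peptide, hours = hours,
                 target = log1p(hours)),
            class = "halflife_record")
}

.featurize_seqs <- function(seqs, family) {
  spec <- embedder_spec("baseline_seq", "AA")
  featurize_dataset(seqs, spec, pooled = family %in% POOLED_FAMILIES)
}

#' Stability-pretrain then half-life fine-tune regression
#'
#' Models supporting warm starts (neural families) are pretrained on the
#' large continuous stability corpus and fine-tuned on the sparse
#' half-life data, copying all weights except the output layer; tree and
#' linear families do not support warm starts and are trained directly on
#' half-life (with a logged notice). Evaluation is k-fold cross-validation
#' with per-fold and mean Pearson / Spearman / R2.
#'
#' @param stability_data `property_dataset` for the `stability` task (AA).
#' @param halflife_data List of `halflife_record`s.
#' @param family `"mlp"`, `"transformer"`, `"gbt"`, `"enet"` or `"svr"`.
#' @param target `"log1p"` (log(1 + hours), default) or `"hours"`.
#' @param n_folds Cross-validation folds (default 5).
#' @param warm_start Use stability pretraining where the family supports
#'   it.
#' @param hyperparams Overrides for the head family.
#' @param seed Integer seed.
#' @return List: `per_fold` (data.frame), `mean` (named list),
#'   `warm_started` (logical).
#' @export
pretrain_finetune_halflife <- function(stability_data, halflife_data,
                                       family = "mlp", target = "log1p",
                                       n_folds = 5, warm_start = TRUE,
                                       hyperparams = list(), seed = 1) {
  n <- length(halflife_data)
  if (n < n_folds)
    stop("half-life data smaller than fold count (", n, " < ",
         n_folds, ")")
  neural <- family %in% c("mlp", "cnn", "transformer")
  warm_started <- warm_start && neural
  if (warm_start && !neural)
    message("family '", family,
            "' does not support warm starts; training directly")
  init <- NULL
  if (warm_started) {
    sX <- .featurize_seqs(dataset_payloads(stability_data), family)
    sy <- dataset_labels(stability_data)
    pre_spec <- head_spec(family, "regression",
                          hyperparams = modifyList(
                            list(epochs = 40), hyperparams),
                          seed = seed)
    pre <- train_head(pre_spec, sX, sy)
    init <- pre$parameters$params
  }
  hl_seqs <- vapply(halflife_data, function(r) r$peptide$payload,
                    character(1))
  hl <- list(
    X = .featurize_seqs(hl_seqs, family),
    y = vapply(halflife_data, function(r)
      if (target == "log1p") r$target else r$hours, numeric(1)))
  set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  per_fold <- NULL
  hp <- modifyList(list(epochs = 30), hyperparams)
  if (!is.null(init)) {
    # warm start: copy all weights except the output layer
    init_ft <- init
    out_names <- intersect(c("W2", "b2", "Wout", "bout"), names(init_ft))
    init_ft[out_names] <- NULL
    hp$init_params <- init_ft
  }
  for (f in seq_len(n_folds)) {
    trn <- which(folds != f); val <- which(folds == f)
    spec <- head_spec(family, "regression", hyperparams = hp,
                      seed = seed + f)
    Xtr <- if (is.matrix(hl$X)) hl$X[trn, , drop = FALSE] else hl$X[trn]
    Xva <- if (is.matrix(hl$X)) hl$X[val, , drop = FALSE] else hl$X[val]
    fit <- train_head(spec, Xtr, hl$y[trn])
    pred <- predict_head(fit, Xva)
    m <- regression_metrics(hl$y[val], pred)
    per_fold <- rbind(per_fold, data.frame(
      fold = f, pearson_r = m$pearson_r, spearman_rho = m$spearman_rho,
      r2 = m$r2))
  }
  list(per_fold = per_fold,
       mean = as.list(colMeans(per_fold[, -1])),
       warm_started = warm_started, family = family, target = target)
}

#' Run the four half-life regression configurations
#'
#' gbt vs transformer crossed with hours vs log(1 + hours), each under
#' k-fold cross-validation.
#'
#' @inheritParams pretrain_finetune_halflife
#' @return Named list of results keyed `<family>_<target>`.
#' @export
run_halflife_protocol <- function(stability_data, halflife_data,
                                  n_folds = 5, seed = 1,
                                  hyperparams = list()) {
  out <- list()
  for (family in c("gbt", "transformer")) {
    for (target in c("hours", "log1p")) {
      out[[paste0(family, "_", target)]] <- pretrain_finetune_halflife(
        stability_data, halflife_data, family = family, target = target,
        n_folds = n_folds, hyperparams = hyperparams, seed = seed)
    }
  }
  out
}
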