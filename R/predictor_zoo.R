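# Predictor heads trained on frozen embeddings, with uniform train/predict
# contracts. Classical families (enet, svm, svr, gbt, mlp) consume pooled
# embeddings; positional families (cnn, transformer) consume unpooled,
# padded-and-masked batches. The routing rule is enforced, not advisory.

HEAD_FAMILIES <- c("enet", "svm", "svr", "gbt", "mlp", "cnn", "transformer")
POOLED_FAMILIES <- c("enet", "svm", "svr", "gbt", "mlp")

#' Huber loss
#'
#' \eqn{r^2/2} for \eqn{|r| \le \delta}, else \eqn{\delta(|r| - \delta/2)}:
#' continuous and once-differentiable at the knee.
#'
#' @param r Residual(s).
#' @param delta Transition point between the L2 and L1 regimes (> 0).
#' @return Loss value(s), vectorized over `r`.
#' @export
huber_loss <- function(r, delta) {
  if (delta <= 0) stop("delta must be > 0")
  a <- abs(r)
  ifelse(a <= delta, r^2 / 2, delta * (a - delta / 2))
}

#' Specify a predictor head
#'
#' @param family One of `enet`, `svm`, `svr`, `gbt`, `mlp` (pooled input)
#'   or `cnn`, `transformer` (unpooled input).
#' @param task_type `"binary"` or `"regression"`.
#' @param hyperparams Named list overriding the family defaults.
#' @param loss Regression loss: `"mse"` (default) or `"huber"`.
#' @param huber_delta Huber transition parameter.
#' @param seed Single integer seed controlling initialization, shuffling
#'   and subsampling.
#' @return A `head_spec`; `input_mode` is derived from the family.
#' @export
head_spec <- function(family, task_type = c("binary", "regression"),
                      hyperparams = list(), loss = NULL, huber_delta = 1,
                      seed = 1) {
  family <- match.arg(family, HEAD_FAMILIES)
  task_type <- match.arg(task_type)
  if (family == "svr" && task_type == "binary")
    stop("svr is a regression family")
  if (is.null(loss))
    loss <- if (task_type == "binary") "logistic" else "mse"
  structure(list(family = family, task_type = task_type,
                 hyperparams = hyperparams,
                 input_mode = if (family %in% POOLED_FAMILIES) "pooled"
                              else "unpooled",
                 loss = loss, huber_delta = huber_delta,
                 seed = as.integer(seed)),
            class = "head_spec")
}

.hp <- function(spec, name, default) spec$hyperparams[[name]] %||% default

.reg_loss <- function(spec) {
  if (spec$loss == "huber")
    function(z, y) loss_huber(z, y, spec$huber_delta)
  else loss_mse
}

# ---- classical families --------------------------------------------------

.train_enet <- function(spec, X, y) {
  fam <- if (spec$task_type == "binary") "binomial" else "gaussian"
  alpha <- .hp(spec, "alpha", 0.5)
  lambda <- .hp(spec, "lambda", 1e-3)
  if (all(apply(X, 2, sd) < 1e-12)) {
    # intercept-only: constant features carry no information
    const <- if (fam == "binomial") mean(y) else mean(y)
    return(list(kind = "enet", fit = NULL, const = const))
  }
  Xa <- cbind(X, 0) # glmnet needs >= 2 columns
  if (ncol(Xa) < 2) Xa <- cbind(Xa, 0)
  fit <- glmnet::glmnet(Xa, y, family = fam, alpha = alpha,
                        lambda = lambda, standardize = TRUE)
  list(kind = "enet", fit = fit, ncol = ncol(X))
}

.predict_enet <- function(par, X, task_type) {
  if (is.null(par$fit)) return(rep(par$const, nrow(X)))
  Xa <- cbind(X, 0)
  if (ncol(Xa) < 2) Xa <- cbind(Xa, 0)
  type <- if (task_type == "binary") "response" else "link"
  as.numeric(predict(par$fit, Xa, type = type))
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}
.standardize_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

# linear SVM (hinge) / SVR (epsilon-insensitive) by full-batch Adam
.train_linear_margin <- function(spec, X, y) {
  st <- .standardize_fit(X)
  Xs <- .standardize_apply(X, st)
  n <- nrow(Xs); d <- ncol(Xs)
  lambda <- .hp(spec, "lambda", 1e-3)
  iters <- .hp(spec, "iters", 300)
  lr <- .hp(spec, "lr", 0.05)
  svr <- spec$family == "svr"
  eps <- .hp(spec, "epsilon", 0.1)
  ymu <- 0; ysd <- 1
  if (svr) { ymu <- mean(y); ysd <- max(sd(y), 1e-12); y <- (y - ymu) / ysd }
  s <- if (svr) NULL else 2 * y - 1
  w <- numeric(d); b <- 0
  opt <- adam_new(list(w = w, b = b), lr = lr)
  params <- list(w = w, b = b)
  for (it in seq_len(iters)) {
    z <- as.numeric(Xs %*% params$w) + params$b
    if (svr) {
      r <- z - y
      g <- sign(r) * (abs(r) > eps)
    } else {
      viol <- (s * z) < 1
      g <- -s * viol
    }
    gw <- as.numeric(crossprod(Xs, g)) / n + 2 * lambda * params$w
    gb <- mean(g)
    up <- adam_step(params, list(w = gw, b = gb), opt)
    params <- up$params; opt <- up$state
  }
  list(kind = spec$family, w = params$w, b = params$b, st = st,
       ymu = ymu, ysd = ysd)
}

.predict_linear_margin <- function(par, X, task_type) {
  z <- as.numeric(.standardize_apply(X, par$st) %*% par$w) + par$b
  if (task_type == "binary") plogis(z) else z * par$ysd + par$ymu
}

# ---- gradient-boosted trees ----------------------------------------------

# depth-limited regression tree on (X, residual r) with per-sample weights
.fit_tree <- function(X, r, w, depth, min_leaf = 5) {
  n <- length(r)
  leaf_value <- sum(r) / max(sum(w), 1e-12)
  if (depth == 0 || n < 2 * min_leaf)
    return(list(leaf = TRUE, value = leaf_value))
  best <- NULL
  sw <- sum(w); swr <- sum(w * r)
  base_score <- swr^2 / max(sw, 1e-12)
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xo <- X[ord, j]; ro <- r[ord]; wo <- w[ord]
    cw <- cumsum(wo); cwr <- cumsum(wo * ro)
    valid <- which(xo[-n] < xo[-1])
    valid <- valid[valid >= min_leaf & valid <= n - min_leaf]
    if (length(valid) == 0) next
    gain <- cwr[valid]^2 / pmax(cw[valid], 1e-12) +
      (swr - cwr[valid])^2 / pmax(sw - cw[valid], 1e-12) - base_score
    k <- valid[which.max(gain)]
    if (is.null(best) || max(gain) > best$gain) {
      best <- list(gain = max(gain), j = j,
                   thr = (xo[k] + xo[k + 1]) / 2)
    }
  }
  if (is.null(best) || best$gain <= 1e-12)
    return(list(leaf = TRUE, value = leaf_value))
  left <- X[, best$j] <= best$thr
  list(leaf = FALSE, j = best$j, thr = best$thr,
       left = .fit_tree(X[left, , drop = FALSE], r[left], w[left],
                        depth - 1, min_leaf),
       right = .fit_tree(X[!left, , drop = FALSE], r[!left], w[!left],
                         depth - 1, min_leaf))
}

.predict_tree <- function(tree, X) {
  if (tree$leaf) return(rep(tree$value, nrow(X)))
  out <- numeric(nrow(X))
  left <- X[, tree$j] <= tree$thr
  if (any(left)) out[left] <- .predict_tree(tree$left,
                                            X[left, , drop = FALSE])
  if (any(!left)) out[!left] <- .predict_tree(tree$right,
                                              X[!left, , drop = FALSE])
  out
}

.train_gbt <- function(spec, X, y) {
  nrounds <- .hp(spec, "nrounds", 100)
  lr <- .hp(spec, "learning_rate", 0.1)
  depth <- .hp(spec, "max_depth", 3)
  min_leaf <- .hp(spec, "min_leaf", 5)
  binary <- spec$task_type == "binary"
  f0 <- if (binary) {
    p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
    log(p0 / (1 - p0))
  } else mean(y)
  Fx <- rep(f0, length(y))
  trees <- vector("list", nrounds)
  for (m in seq_len(nrounds)) {
    if (binary) {
      p <- plogis(Fx)
      r <- y - p
      w <- pmax(p * (1 - p), 1e-6)
    } else {
      r <- y - Fx
      w <- rep(1, length(y))
    }
    tr <- .fit_tree(X, r, w, depth, min_leaf)
    trees[[m]] <- tr
    Fx <- Fx + lr * .predict_tree(tr, X)
  }
  list(kind = "gbt", f0 = f0, lr = lr, trees = trees)
}

.predict_gbt <- function(par, X, task_type) {
  z <- rep(par$f0, nrow(X))
  for (tr in par$trees) z <- z + par$lr * .predict_tree(tr, X)
  if (task_type == "binary") plogis(z) else z
}

# ---- neural families -----------------------------------------------------

# warm-start support: copy matching pretrained tensors over fresh ones
.apply_warm_start <- function(params, init) {
  if (is.null(init)) return(params)
  for (k in names(init)) {
    if (k %in% names(params) &&
        identical(dim(params[[k]]), dim(init[[k]])) &&
        length(params[[k]]) == length(init[[k]]))
      params[[k]] <- init[[k]]
  }
  params
}

.nn_minibatches <- function(n, batch) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch))
}

.nn_loss_fn <- function(spec) {
  if (spec$task_type == "binary") loss_bce_logits else .reg_loss(spec)
}

.train_mlp <- function(spec, X, y) {
  st <- .standardize_fit(X)
  Xs <- .standardize_apply(X, st)
  hidden <- .hp(spec, "hidden", 32)
  epochs <- .hp(spec, "epochs", 80)
  lr <- .hp(spec, "lr", 3e-3)
  batch <- .hp(spec, "batch", 64)
  d <- ncol(Xs)
  params <- list(W1 = nn_init_param(d, hidden), b1 = nn_init_param(hidden),
                 W2 = nn_init_param(hidden, 1), b2 = nn_init_param(1))
  params <- .apply_warm_start(params, .hp(spec, "init_params", NULL))
  lossfn <- .nn_loss_fn(spec)
  opt <- adam_new(params, lr = lr)
  for (ep in seq_len(epochs)) {
    for (mb in .nn_minibatches(nrow(Xs), batch)) {
      ag_tape_begin()
      pn <- params_as_nodes(params)
      h <- ag_relu(ag_add_bias(ag_mm(ag_var(Xs[mb, , drop = FALSE]),
                                     pn$W1), pn$b1))
      out <- ag_add_bias(ag_mm(h, pn$W2), pn$b2)
      l <- lossfn(out$value, y[mb])
      ag_backward(out, l$grad)
      up <- adam_step(params, collect_grads(pn), opt)
      params <- up$params; opt <- up$state
    }
  }
  list(kind = "mlp", params = params, st = st)
}

.predict_mlp <- function(par, X, task_type) {
  Xs <- .standardize_apply(X, par$st)
  h <- pmax(sweep(Xs %*% par$params$W1, 2, par$params$b1, "+"), 0)
  z <- as.numeric(h %*% par$params$W2) + par$params$b2
  if (task_type == "binary") plogis(z) else z
}

# im2col for 1-d convolution over a padded cube
.conv_cols <- function(X, mask, k) {
  d <- dim(X) # (L, D, N)
  Lo <- d[1] - k + 1
  if (Lo < 1) stop("input shorter than the convolution kernel")
  col <- array(0, c(Lo, k * d[2], d[3]))
  cmask <- matrix(1, Lo, d[3])
  for (o in seq_len(k)) {
    col[, ((o - 1) * d[2] + 1):(o * d[2]), ] <-
      X[o:(o + Lo - 1), , , drop = FALSE]
    cmask <- cmask * mask[o:(o + Lo - 1), , drop = FALSE]
  }
  list(col = col, mask = cmask)
}

.cnn_forward <- function(pn, col, cmask, hp) {
  a <- ag_relu(ag_add_bias(ag_cube_mm(ag_var(col), pn$Wc), pn$bc))
  pooled <- ag_masked_meanpool(a, cmask)
  h <- ag_relu(ag_add_bias(ag_mm(pooled, pn$W1), pn$b1))
  ag_add_bias(ag_mm(h, pn$W2), pn$b2)
}

.train_cnn <- function(spec, X, y) {
  k <- .hp(spec, "kernel", 5)
  nf <- .hp(spec, "filters", 32)
  hidden <- .hp(spec, "hidden", 16)
  epochs <- .hp(spec, "epochs", 60)
  lr <- .hp(spec, "lr", 3e-3)
  batch <- .hp(spec, "batch", 64)
  D <- ncol(X[[1]])
  params <- list(Wc = nn_init_param(k * D, nf), bc = nn_init_param(nf),
                 W1 = nn_init_param(nf, hidden), b1 = nn_init_param(hidden),
                 W2 = nn_init_param(hidden, 1), b2 = nn_init_param(1))
  lossfn <- .nn_loss_fn(spec)
  opt <- adam_new(params, lr = lr)
  for (ep in seq_len(epochs)) {
    for (mb in .nn_minibatches(length(X), batch)) {
      pb <- pad_batch(X[mb])
      cc <- .conv_cols(pb$X, pb$mask, k)
      ag_tape_begin()
      pn <- params_as_nodes(params)
      out <- .cnn_forward(pn, cc$col, cc$mask, NULL)
      l <- lossfn(out$value, y[mb])
      ag_backward(out, l$grad)
      up <- adam_step(params, collect_grads(pn), opt)
      params <- up$params; opt <- up$state
    }
  }
  list(kind = "cnn", params = params, k = k)
}

.predict_cnn <- function(par, X, task_type) {
  pb <- pad_batch(X)
  cc <- .conv_cols(pb$X, pb$mask, par$k)
  ag_tape_begin()
  pn <- params_as_nodes(par$params)
  out <- .cnn_forward(pn, cc$col, cc$mask, NULL)
  z <- as.numeric(out$value)
  if (task_type == "binary") plogis(z) else z
}

.tf_forward <- function(pn, Xc, mask, n_heads, pe) {
  Xp <- ag_add_posenc(ag_add_bias(ag_cube_mm(ag_var(Xc), pn$Win), pn$bin),
                      pe)
  Z <- mha_forward(pn, Xp, Xp, mask, n_heads)
  pooled <- ag_masked_meanpool(Z, mask)
  ag_add_bias(ag_mm(pooled, pn$Wout), pn$bout)
}

.train_transformer <- function(spec, X, y) {
  Dm <- .hp(spec, "dim", 32)
  n_heads <- .hp(spec, "n_heads", 4)
  epochs <- .hp(spec, "epochs", 60)
  lr <- .hp(spec, "lr", 2e-3)
  batch <- .hp(spec, "batch", 64)
  D <- ncol(X[[1]])
  params <- c(list(Win = nn_init_param(D, Dm), bin = nn_init_param(Dm)),
              mha_init(Dm),
              list(Wout = nn_init_param(Dm, 1), bout = nn_init_param(1)))
  params <- .apply_warm_start(params, .hp(spec, "init_params", NULL))
  pe <- posenc(max(vapply(X, nrow, numeric(1))) + 8, Dm)
  lossfn <- .nn_loss_fn(spec)
  opt <- adam_new(params, lr = lr)
  for (ep in seq_len(epochs)) {
    for (mb in .nn_minibatches(length(X), batch)) {
      pb <- pad_batch(X[mb])
      ag_tape_begin()
      pn <- params_as_nodes(params)
      out <- .tf_forward(pn, pb$X, pb$mask, n_heads, pe)
      l <- lossfn(out$value, y[mb])
      ag_backward(out, l$grad)
      up <- adam_step(params, collect_grads(pn), opt)
      params <- up$params; opt <- up$state
    }
  }
  list(kind = "transformer", params = params, n_heads = n_heads, pe = pe)
}

.predict_transformer <- function(par, X, task_type) {
  pb <- pad_batch(X)
  pe <- par$pe
  if (nrow(pe) < dim(pb$X)[1])
    pe <- posenc(dim(pb$X)[1], ncol(par$params$Win))
  ag_tape_begin()
  pn <- params_as_nodes(par$params)
  out <- .tf_forward(pn, pb$X, pb$mask, par$n_heads, pe)
  z <- as.numeric(out$value)
  if (task_type == "binary") plogis(z) else z
}

# ---- uniform contract ----------------------------------------------------

#' Train a predictor head on frozen embeddings
#'
#' @param spec A `head_spec`.
#' @param X Pooled families: numeric matrix (n x D). Positional families:
#'   list of L_i x D matrices (padded and masked internally; masked
#'   positions never influence outputs).
#' @param y Labels: 0/1 for binary, finite reals for regression.
#' @param featurizer_id Recorded provenance of the embeddings (defaults to
#'   the `featurizer_id` attribute of `X`).
#' @return A `trained_head`; predictions are deterministic after fitting.
#' @export
train_head <- function(spec, X, y, featurizer_id = NULL) {
  stopifnot(inherits(spec, "head_spec"))
  featurizer_id <- featurizer_id %||% attr(X, "featurizer_id") %||% "unknown"
  pooled_in <- is.matrix(X)
  if (spec$input_mode == "pooled" && !pooled_in)
    stop(spec$family, " requires pooled input (a matrix)")
  if (spec$input_mode == "unpooled" && pooled_in)
    stop(spec$family, " requires unpooled input (a list of matrices)")
  n <- if (pooled_in) nrow(X) else length(X)
  if (n != length(y)) stop("X and y are not aligned")
  if (!all(is.finite(y))) stop("non-finite label(s)")
  if (spec$task_type == "binary") {
    if (!all(y %in% c(0, 1)))
      stop("binary task given non-0/1 labels (continuous labels?)")
    if (length(unique(y)) < 2)
      stop("single-class training set for binary task")
  }
  set.seed(spec$seed)
  par <- switch(spec$family,
    enet = .train_enet(spec, X, y),
    svm = .train_linear_margin(spec, X, y),
    svr = .train_linear_margin(spec, X, y),
    gbt = .train_gbt(spec, X, y),
    mlp = .train_mlp(spec, X, y),
    cnn = .train_cnn(spec, X, y),
    transformer = .train_transformer(spec, X, y))
  probe_x <- if (pooled_in) X[seq_len(min(5, n)), , drop = FALSE]
             else X[seq_len(min(5, n))]
  head <- structure(
    list(spec = spec, parameters = par,
         train_meta = list(n_train = n, seed = spec$seed),
         metrics = NULL, featurizer_id = featurizer_id,
         task = NA_character_, modality = NA_character_,
         probe = list(x = probe_x)),
    class = "trained_head")
  head$probe$y <- predict_head(head, probe_x)
  head
}

#' Predict with a trained head
#'
#' Binary heads return class-1 probabilities in `[0, 1]` (threshold at 0.5
#' for hard labels); regression heads return finite reals.
#'
#' @param head A `trained_head`.
#' @param X Input embeddings in the head's input mode.
#' @param featurizer_id Optional provenance check against the training
#'   featurizer.
#' @param strict Error (TRUE) or warn (FALSE, default) on featurizer
#'   mismatch.
#' @return Numeric vector of scores.
#' @export
predict_head <- function(head, X, featurizer_id = NULL, strict = FALSE) {
  stopifnot(inherits(head, "trained_head"))
  featurizer_id <- featurizer_id %||% attr(X, "featurizer_id")
  if (!is.null(featurizer_id) && head$featurizer_id != "unknown" &&
      !identical(featurizer_id, head$featurizer_id)) {
    msg <- paste0("featurizer mismatch: head trained on '",
                  head$featurizer_id, "', input is '", featurizer_id, "'")
    if (strict) stop(msg) else warning(msg)
  }
  pooled_in <- is.matrix(X)
  if (head$spec$input_mode == "pooled" && !pooled_in)
    stop("head expects pooled input")
  if (head$spec$input_mode == "unpooled" && pooled_in)
    stop("head expects unpooled input")
  par <- head$parameters
  tt <- head$spec$task_type
  switch(head$spec$family,
    enet = .predict_enet(par, X, tt),
    svm = .predict_linear_margin(par, X, tt),
    svr = .predict_linear_margin(par, X, tt),
    gbt = .predict_gbt(par, X, tt),
    mlp = .predict_mlp(par, X, tt),
    cnn = .predict_cnn(par, X, tt),
    transformer = .predict_transformer(par, X, tt))
}
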