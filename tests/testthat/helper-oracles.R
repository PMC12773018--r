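# Independent brute-force oracles used by the equivalence tests. These
# re-implement the contracts in plain R, separately from the package's
# compiled/vectorized paths, and share only the documented tie rules.

rand_seqs <- function(n, lmin, lmax) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  vapply(sample(seq(lmin, lmax), n, replace = TRUE), function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), character(1))
}

# plain-R Gotoh overlap alignment mirroring the documented scoring:
# match +1, mismatch 0, affine interior gaps, free end gaps; identity =
# matches / columns between first and last aligned pair
oracle_align <- function(a, b, gap_open = 1, gap_ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  tM <- matrix(0L, n + 1, m + 1); tX <- matrix(0L, n + 1, m + 1)
  tY <- matrix(0L, n + 1, m + 1)
  M[, 1] <- 0; M[1, ] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- as.numeric(av[i - 1] == bv[j - 1])
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      arg <- which.max(cand)
      M[i, j] <- cand[arg] + s; tM[i, j] <- arg
      xo <- M[i - 1, j] - gap_open; xe <- X[i - 1, j] - gap_ext
      if (xo >= xe) { X[i, j] <- xo; tX[i, j] <- 1L }
      else { X[i, j] <- xe; tX[i, j] <- 2L }
      yo <- M[i, j - 1] - gap_open; ye <- Y[i, j - 1] - gap_ext
      if (yo >= ye) { Y[i, j] <- yo; tY[i, j] <- 1L }
      else { Y[i, j] <- ye; tY[i, j] <- 3L }
    }
  }
  bi <- n; bj <- m; best <- M[n + 1, m + 1]
  for (j in 1:m) if (M[n + 1, j + 1] > best) { best <- M[n + 1, j + 1]; bi <- n; bj <- j }
  for (i in 1:n) if (M[i + 1, m + 1] > best) { best <- M[i + 1, m + 1]; bi <- i; bj <- m }
  i <- bi; j <- bj; state <- 1L
  matches <- 0L; columns <- 0L
  first_i <- bi; first_j <- bj
  while (i > 0 && j > 0) {
    if (state == 1L) {
      if (av[i] == bv[j]) matches <- matches + 1L
      columns <- columns + 1L
      first_i <- i; first_j <- j
      state <- tM[i + 1, j + 1]; i <- i - 1; j <- j - 1
      if (state == 0L) state <- 1L
    } else if (state == 2L) {
      columns <- columns + 1L
      state <- tX[i + 1, j + 1]; i <- i - 1
    } else {
      columns <- columns + 1L
      state <- tY[i + 1, j + 1]; j <- j - 1
    }
  }
  c(identity = if (columns > 0) matches / columns else 0,
    cov_a = (bi - first_i + 1) / n,
    cov_b = (bj - first_j + 1) / m,
    matches = matches, columns = columns)
}

# canonical-orientation wrapper matching pairwise_identity's symmetry rule
oracle_pairwise <- function(a, b) {
  swap <- nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)
  st <- if (swap) oracle_align(b, a) else oracle_align(a, b)
  if (swap) st[c("cov_a", "cov_b")] <- st[c("cov_b", "cov_a")]
  st
}

# exhaustive representative-scan clustering with the package's ordering
# and tie rules, built on the R alignment oracle
oracle_identity_cluster <- function(seqs, min_id = 0.3, min_cov = 0.8) {
  ids <- names(seqs)
  ord <- order(-nchar(seqs), seqs)
  reps <- integer(0)
  cl <- integer(length(seqs))
  for (k in seq_along(ord)) {
    i <- ord[k]
    assigned <- NA_integer_
    for (r in seq_along(reps)) {
      st <- oracle_align(seqs[[reps[r]]], seqs[[i]]) # canonical orientation
      if (st["identity"] >= min_id && st["cov_a"] >= min_cov &&
          st["cov_b"] >= min_cov) { assigned <- r - 1L; break }
    }
    if (is.na(assigned)) {
      reps <- c(reps, i)
      assigned <- length(reps) - 1L
    }
    cl[i] <- assigned
  }
  stats::setNames(cl, ids)
}

# brute-force Taylor-Butina from a precomputed similarity matrix
oracle_butina <- function(S, sim_threshold = 0.6) {
  n <- nrow(S)
  nbr <- lapply(seq_len(n), function(i)
    setdiff(which(S[i, ] >= sim_threshold), i))
  assigned <- rep(FALSE, n)
  cl <- integer(n); cid <- 0L
  while (!all(assigned)) {
    counts <- sapply(seq_len(n), function(i)
      if (assigned[i]) -1L else sum(!assigned[nbr[[i]]]))
    c0 <- which.max(counts)
    mem <- c(c0, nbr[[c0]][!assigned[nbr[[c0]]]])
    cl[mem] <- cid; assigned[mem] <- TRUE; cid <- cid + 1L
  }
  cl
}

# AUC as the exhaustive concordant-pair fraction (ties count 1/2)
oracle_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  tot / (length(pos) * length(neg))
}

make_fp <- function(bits, nbits = 64) {
  structure(sort(unique(as.integer(bits))), class = "fingerprint",
            nbits = nbits, radius = 2, chirality = TRUE,
            n_on = length(unique(bits)))
}
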