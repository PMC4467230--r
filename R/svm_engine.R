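# Calibrated linear-SVM engine.
#
# Decoders are linear support vector machines (libsvm via e1071) with cost
# C = 1, turned into probabilistic classifiers by Platt sigmoid scaling of
# each one-vs-one margin followed by pairwise coupling of the binary
# probabilities into a distribution over classes. The sigmoid is fitted on
# the training-set decision values of the already-trained machine (with
# Platt's conservative targets), rather than by an inner refitting loop;
# the outer cross-validation still guarantees that every reported
# posterior comes from a model that never saw the scored trial.

# Platt (1999) sigmoid fit by Newton descent with backtracking; a direct
# transcription of the standard algorithm. `dec` are decision values,
# `pos` a logical vector marking the pair's first class.
platt_fit <- function(dec, pos) {
  prior1 <- sum(pos)
  prior0 <- length(pos) - prior1
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  tt <- ifelse(pos, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  sigma <- 1e-12
  fobj <- function(A, B) {
    fApB <- dec * A + B
    sum(ifelse(fApB >= 0,
      tt * fApB + log1p(exp(-fApB)),
      (tt - 1) * fApB + log1p(exp(fApB))
    ))
  }
  fval <- fobj(A, B)
  for (it in seq_len(100L)) {
    fApB <- dec * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sum(dec * dec * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(dec * d2)
    d1 <- tt - p
    g1 <- sum(dec * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    while (stepsize >= 1e-10) {
      newA <- A + stepsize * dA
      newB <- B + stepsize * dB
      newf <- fobj(newA, newB)
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA
        B <- newB
        fval <- newf
        break
      }
      stepsize <- stepsize / 2
    }
    if (stepsize < 1e-10) break
  }
  c(A = A, B = B)
}

platt_prob <- function(dec, ab) {
  fApB <- dec * ab[["A"]] + ab[["B"]]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# Pairwise coupling of one-vs-one probabilities into class posteriors
# (Wu, Lin & Weng 2004, second method -- the libsvm scheme). `r` is a
# k x k matrix with r[i, j] = P(class i | i or j); returns p of length k.
couple_pairwise <- function(r) {
  k <- nrow(r)
  if (k == 2L) {
    p <- c(r[1L, 2L], r[2L, 1L])
    return(p / sum(p))
  }
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(r[-t, t]^2)
    for (j in seq_len(k)) {
      if (j != t) Q[t, j] <- -r[j, t] * r[t, j]
    }
  }
  p <- rep(1 / k, k)
  eps <- 0.005 / k
  for (it in seq_len(100L)) {
    Qp <- as.vector(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < eps) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[t, ]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p
}

# Fit the calibrated machine on one feature matrix. `y` must be a factor
# whose levels are all present. Returns the svm fit plus per-pair sigmoids.
fit_calibrated_svm <- function(X, y, tolerance = 0.01) {
  lev <- levels(y)
  if (any(grepl("/", lev, fixed = TRUE))) {
    stop("class labels must not contain `/`", call. = FALSE)
  }
  if (any(table(y) == 0L)) {
    stop(
      "class(es) absent from a training set: ",
      paste(lev[table(y) == 0L], collapse = ", "),
      "; rebalance the trial selection (see `select_subset()`)",
      call. = FALSE
    )
  }
  m <- e1071::svm(
    x = X, y = y, kernel = "linear", cost = 1,
    scale = FALSE, tolerance = tolerance
  )
  D <- attr(stats::predict(m, X, decision.values = TRUE), "decision.values")
  pair_names <- colnames(D)
  pairs <- strsplit(pair_names, "/", fixed = TRUE)
  sig <- lapply(seq_along(pairs), function(j) {
    a <- pairs[[j]][1L]
    b <- pairs[[j]][2L]
    rows <- y == a | y == b
    platt_fit(D[rows, j], (y == a)[rows])
  })
  names(sig) <- pair_names
  list(model = m, sigmoids = sig, pairs = pairs, levels = lev)
}

# Calibrated class posteriors for new data; rows of `X` are scored
# independently, so stacking test sets is safe.
predict_calibrated <- function(fit, X) {
  k <- length(fit$levels)
  D <- attr(stats::predict(fit$model, X, decision.values = TRUE), "decision.values")
  n <- nrow(X)
  # per-pair calibrated probability of the pair's first class
  R <- vapply(
    seq_along(fit$pairs),
    function(j) platt_prob(D[, j], fit$sigmoids[[j]]),
    numeric(n)
  )
  if (n == 1L) R <- matrix(R, nrow = 1L)
  # clip away exact 0/1 for coupling stability (libsvm convention)
  R <- pmin(pmax(R, 1e-7), 1 - 1e-7)
  idx <- match(
    vapply(fit$pairs, function(p) p[1L], character(1)),
    fit$levels
  )
  jdx <- match(
    vapply(fit$pairs, function(p) p[2L], character(1)),
    fit$levels
  )
  P <- matrix(0, n, k, dimnames = list(NULL, fit$levels))
  r <- matrix(0, k, k)
  for (s in seq_len(n)) {
    r[cbind(idx, jdx)] <- R[s, ]
    r[cbind(jdx, idx)] <- 1 - R[s, ]
    P[s, ] <- couple_pairwise(r)
  }
  P
}
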