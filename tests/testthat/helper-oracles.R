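# Independent per-scalar transliterations of the method's formulas, used as
# oracles against the vectorized implementation. Deliberately loop-based and
# kept free of any package internals.

oracle_gip <- function(P, gamma_prime = 1) {
  n <- nrow(P)
  msn <- 0
  for (a in seq_len(n)) msn <- msn + sum(P[a, ]^2)
  msn <- msn / n
  gamma <- gamma_prime / msn
  S <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      S[a, b] <- exp(-gamma * sum((P[a, ] - P[b, ])^2))
    }
  }
  S
}

# scalar evaluation of the projection formulas on a delta-substituted A
oracle_projection <- function(A, MS, DS, delta = 1e-30) {
  Ap <- A * 1
  Ap[Ap == 0] <- delta
  nd <- nrow(A); nm <- ncol(A)
  msp <- dsp <- ncp <- matrix(NA_real_, nd, nm)
  for (i in seq_len(nd)) {
    for (j in seq_len(nm)) {
      msp[i, j] <- sum(Ap[i, ] * MS[, j]) / sqrt(sum(Ap[i, ]^2))
      dsp[i, j] <- sum(DS[i, ] * Ap[, j]) / sqrt(sum(Ap[, j]^2))
      ncp[i, j] <- (dsp[i, j] + msp[i, j]) /
        (sqrt(sum(DS[i, ]^2)) + sqrt(sum(MS[, j]^2)))
    }
  }
  list(msp = msp, dsp = dsp, ncp = ncp)
}

# exhaustive threshold enumeration for the rank-percentile ROC: walks a dense
# grid of thresholds, counts positives per trial with explicit loops
oracle_rank_auc <- function(ranks, n_candidates) {
  grid <- sort(unique(c(0, 1, unlist(lapply(
    n_candidates, function(n) if (n > 1) (0:(2 * n)) / (2 * (n - 1)) else 0
  )))))
  grid <- grid[grid <= 1]
  tpr <- fpr <- numeric(length(grid))
  for (g in seq_along(grid)) {
    t <- grid[g]
    tps <- fps <- numeric(length(ranks))
    for (k in seq_along(ranks)) {
      n <- n_candidates[k]
      pct <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
      pos <- sum(pct <= t + 1e-9)
      test_pct <- if (n > 1) (ranks[k] - 1) / (n - 1) else 0
      hit <- as.numeric(test_pct <= t + 1e-9)
      tps[k] <- hit
      fps[k] <- if (n > 1) (pos - hit) / (n - 1) else 0
    }
    tpr[g] <- mean(tps)
    fpr[g] <- mean(fps)
  }
  x <- c(0, fpr); y <- c(0, tpr)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# quick builders -------------------------------------------------------------

toy_net <- function(A) {
  dimnames(A) <- list(sprintf("d%d", seq_len(nrow(A))),
                      sprintf("m%d", seq_len(ncol(A))))
  structure(
    list(diseases = rownames(A), microbes = colnames(A),
         A = A, order = "first-appearance"),
    class = "association_network"
  )
}

random_net <- function(nd, nm, p = 0.4) {
  repeat {
    A <- matrix(rbinom(nd * nm, 1L, p), nd, nm)
    if (sum(A) >= 2) return(toy_net(A))
  }
}

# scalar TF-IDF + cosine symptom similarity
oracle_ss <- function(W, base = 10) {
  N <- nrow(W); M <- ncol(W)
  w <- matrix(0, N, M)
  for (m in seq_len(M)) {
    n_m <- sum(W[, m] > 0)
    if (n_m > 0) {
      for (i in seq_len(N)) w[i, m] <- W[i, m] * log(N / n_m, base = base)
    }
  }
  S <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      ni <- sqrt(sum(w[i, ]^2)); nj <- sqrt(sum(w[j, ]^2))
      S[i, j] <- if (ni > 0 && nj > 0) sum(w[i, ] * w[j, ]) / (ni * nj) else 0
    }
  }
  diag(S)[sqrt(rowSums(w^2)) > 0] <- 1
  S
}

# deterministic edge list with exact totals: every microbe gets one disease
# cyclically, then extra distinct pairs with a shifted disease offset
totals_edgelist <- function(n_diseases, n_microbes, n_edges) {
  d1 <- ((seq_len(n_microbes) - 1) %% n_diseases) + 1
  extra <- n_edges - n_microbes
  stopifnot(extra >= 0, extra <= n_microbes)
  j <- seq_len(extra)
  d2 <- ((j - 1 + 7) %% n_diseases) + 1
  tibble::tibble(
    disease = sprintf("d%02d", c(d1, d2)),
    microbe = sprintf("m%03d", c(seq_len(n_microbes), j))
  )
}
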