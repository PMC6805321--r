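# Independent oracles the implementation is checked against. These stay
# deliberately naive: explicit loops, enumeration, no shared code paths with
# the package internals.

# Pairwise-sum form of the hypergraph smoothness penalty:
# (1/2) sum_e sum_{(i,j) in e x e} (w(e)/f(e)) ||s_i - s_j||^2
oracle_pairwise_regularizer <- function(V, hg) {
  H <- as.matrix(hg$incidence)
  total <- 0
  for (e in seq_len(hg$n_hyperedges)) {
    members <- which(H[, e] == 1)
    for (i in members) for (j in members) {
      total <- total + (hg$edge_weights[e] / hg$edge_degrees[e]) *
        sum((V[, i] - V[, j])^2)
    }
  }
  total / 2
}

# Classical Lee-Seung multiplicative NMF (squared Frobenius loss), coded
# independently of the package solver; init replicates the documented
# Uniform(0,1) * sqrt(mean(X)/k) scheme under `seed`.
oracle_lee_seung <- function(X, k, seed, iters) {
  set.seed(seed)
  s <- sqrt(mean(X) / k)
  U <- matrix(runif(nrow(X) * k), nrow(X), k) * s
  V <- matrix(runif(k * ncol(X)), k, ncol(X)) * s
  traj <- numeric(iters)
  for (it in seq_len(iters)) {
    U <- U * (X %*% t(V)) / (U %*% V %*% t(V))
    V <- V * (t(U) %*% X) / (t(U) %*% U %*% V)
    traj[it] <- sum((X - U %*% V)^2)
  }
  list(U = U, V = V, trajectory = traj)
}

# All permutations of 1..n (n <= 7), for exhaustive label-matching search.
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Best match count over all injective maps from predicted to true labels,
# by brute force over permutations of the padded label set.
oracle_best_match_count <- function(pred, true) {
  pf <- as.integer(factor(pred))
  tf <- as.integer(factor(true))
  r <- max(pf); cc <- max(tf); s <- max(r, cc)
  best <- 0L
  for (p in oracle_perms(s)) {
    m <- sum(tf == p[pf])
    if (m > best) best <- m
  }
  best
}

# Contingency-table NMI by explicit double loop, natural log.
oracle_nmi <- function(a, b) {
  af <- as.integer(factor(a)); bf <- as.integer(factor(b))
  n <- length(a)
  mi <- 0
  for (i in unique(af)) for (j in unique(bf)) {
    nij <- sum(af == i & bf == j)
    if (nij > 0) {
      mi <- mi + (nij / n) * log((nij * n) / (sum(af == i) * sum(bf == j)))
    }
  }
  ent <- function(z) {
    h <- 0
    for (i in unique(z)) {
      p <- sum(z == i) / length(z)
      h <- h - p * log(p)
    }
    h
  }
  den <- max(ent(af), ent(bf))
  if (den == 0) 0 else mi / den
}

# Small random non-negative matrix.
rand_nonneg <- function(m, n, seed) {
  set.seed(seed)
  matrix(runif(m * n), m, n)
}
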