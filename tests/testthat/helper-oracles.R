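# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code path with the package internals.

# --- phylogenetic covariance by explicit per-pair root-to-MRCA path sums ----

# list of ancestor nodes (root .. node) for every node, from the edge matrix
.ancestor_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lapply(seq_len(max(tree$edge)), function(nd) {
    path <- nd
    while (nd != root) {
      nd <- parent[nd]
      path <- c(nd, path)
    }
    path
  })
}

oracle_vcv <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  # depth of each node = sum of branch lengths root -> node
  depth <- numeric(max(tree$edge))
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  paths <- .ancestor_paths(tree)
  for (nd in seq_along(depth)) depth[nd] <- sum(elen[paths[[nd]]])
  V <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip)) {
    for (j in seq_len(n_tip)) {
      common <- intersect(paths[[i]], paths[[j]])
      mrca <- common[which.max(depth[common])]
      V[i, j] <- depth[mrca]
    }
  }
  V
}

# --- clade enumeration and MCC scoring by recursive traversal --------------

oracle_clade_keys <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(nd) {
    if (nd <= n_tip) return(tree$tip.label[nd])
    unlist(lapply(kids[[as.character(nd)]], tips_below))
  }
  internal <- sort(unique(tree$edge[, 1]))
  vapply(internal, function(nd) paste(sort(tips_below(nd)), collapse = "\r"),
         character(1))
}

oracle_mcc_index <- function(trees) {
  n <- length(trees)
  keysets <- lapply(trees, oracle_clade_keys)
  counts <- table(unlist(keysets))
  scores <- vapply(keysets, function(k) sum(log(as.numeric(counts[k]) / n)),
                   numeric(1))
  which.max(scores)
}

# --- GLS by explicit Cholesky whitening then textbook OLS via lm -----------

oracle_gls <- function(y, X, V) {
  L <- t(chol(V))                      # V = L L'
  yt <- solve(L, y)
  Xt <- solve(L, X)
  fit <- stats::lm(yt ~ Xt - 1)
  sm <- summary(fit)
  co <- sm$coefficients
  list(beta = unname(co[, 1]), se = unname(co[, 2]), t = unname(co[, 3]),
       p = unname(co[, 4]), sigma2 = sm$sigma^2)
}

# --- BM likelihood by direct MVN density with a parameter grid -------------

oracle_mvn_loglik <- function(x, mu, S) {
  n <- length(x)
  Si <- solve(S)
  -0.5 * (n * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus[1] +
            drop(t(x - mu) %*% Si %*% (x - mu)))
}

oracle_bm_profile <- function(x, V, lam, z0_grid, s2_grid) {
  W <- V * lam
  diag(W) <- diag(V)
  best <- -Inf
  for (z0 in z0_grid) for (s2 in s2_grid) {
    ll <- oracle_mvn_loglik(x, rep(z0, length(x)), s2 * W)
    if (ll > best) best <- ll
  }
  best
}

# --- HDP by exhaustive window scan -----------------------------------------

oracle_hdp <- function(sample, mass) {
  s <- sort(sample)
  n <- length(s)
  m <- min(n, ceiling(mass * n))
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1L)) {
    lo <- s[i]; hi <- s[i + m - 1L]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# --- misc helpers ----------------------------------------------------------

random_labeled_tree <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  tr <- ape::rtree(n)
  tr$tip.label <- sample(labels)
  tr
}

# minimal valid specimen table built in code
toy_specimens <- function() {
  grid <- expand.grid(specimen_id = c("a", "b", "c"), repeat_id = 1:3,
                      stringsAsFactors = FALSE)
  data.frame(
    species = "Parus_major",
    specimen_id = grid$specimen_id,
    repeat_id = grid$repeat_id,
    cup_depth_cm = 5 + as.numeric(factor(grid$specimen_id)),
    nest_height_cm = 10,
    internal_diameter_cm = 6,
    external_diameter_cm = 12,
    year = 1950, latitude = 48.2,
    stringsAsFactors = FALSE)
}
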