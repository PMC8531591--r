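# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: ranks by pairwise counting, Holm by explicit
# step-down, Shapley by exhaustive subset enumeration over the tree dump.

# midrank of each value by counting comparisons
naive_ranks <- function(x) {
  vapply(x, function(v) 1 + sum(x < v) + (sum(x == v) - 1) / 2, numeric(1))
}

# Kruskal-Wallis H from first principles (tie-corrected)
naive_kw_H <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- naive_ranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(match(x, unique(x)))
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}

# Dunn z for one contrast from first principles
naive_dunn_z <- function(values, groups, g, ref) {
  N <- length(values)
  r <- naive_ranks(values)
  ties <- table(match(values, unique(values)))
  var_term <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  (mean(r[groups == g]) - mean(r[groups == ref])) /
    sqrt(var_term * (1 / sum(groups == g) + 1 / sum(groups == ref)))
}

# Holm step-down written out longhand
naive_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Exhaustive-subset Shapley values for a booster, using the path-dependent
# value function (features outside S marginalized by training covers).
tree_value_S <- function(tree, x, S, j = 1L) {
  if (!is.na(tree$value[j])) return(tree$value[j])
  f <- tree$feature[j]
  if (f %in% S) {
    nxt <- if (x[f] < tree$split[j]) tree$yes[j] else tree$no[j]
    return(tree_value_S(tree, x, S, nxt))
  }
  (tree$cover[tree$yes[j]] * tree_value_S(tree, x, S, tree$yes[j]) +
   tree$cover[tree$no[j]] * tree_value_S(tree, x, S, tree$no[j])) /
    tree$cover[j]
}

shapley_brute_force <- function(model, features) {
  pb <- hspmark:::parse_booster(model, colnames(features))
  xq <- matrix(hspmark:::float32(features), nrow(features))
  p <- ncol(features)
  v <- function(x, S) sum(vapply(pb$trees, tree_value_S, 0, x = x, S = S))
  t(vapply(seq_len(nrow(features)), function(s) {
    x <- xq[s, ]
    phi <- numeric(p)
    for (i in seq_len(p)) {
      rest <- setdiff(seq_len(p), i)
      for (k in 0:length(rest)) {
        combs <- if (k == 0) list(integer(0))
                 else asplit(utils::combn(rest, k), 2)
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        for (S in combs)
          phi[i] <- phi[i] + w * (v(x, c(S, i)) - v(x, S))
      }
    }
    phi
  }, numeric(p)))
}

# small labeled classification fixture with planted signal features
make_signal_data <- function(n = 200, n_noise = 5, effect = 1.5, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(1L, 0L), length.out = n)
    x <- matrix(rnorm(n * (2 + n_noise)), n, 2 + n_noise)
    colnames(x) <- c("sig1", "sig2",
                     if (n_noise > 0) paste0("noise", seq_len(n_noise)))
    x[, "sig1"] <- x[, "sig1"] + effect * y
    x[, "sig2"] <- x[, "sig2"] + effect * y
    list(x = x, y = y)
  })
}

default_point <- function(nrounds = 20) {
  c(eta = 0.3, max_depth = 3, nrounds = nrounds, subsample = 1,
    colsample_bytree = 1, min_child_weight = 1)
}

# small search config used where the full desk-scale defaults are too slow
tiny_search <- function(seed = 1L, n1 = 3L, n2 = 2L, K = 5L)
  search_config(n1 = n1, n2 = n2, K = K, seed = seed,
                bounds = default_search_bounds(nrounds_max = 40))
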