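## Exact path-dependent Shapley attributions for gradient-boosted trees,
## computed in double precision from the booster's tree dump. The booster's
## own (float32) contribution predictor serves as an independent
## cross-check in the test suite.

float32 <- function(v)
  readBin(writeBin(as.vector(v, "numeric"), raw(), size = 4),
          "numeric", size = 4, n = length(v))

## Parse an xgb.Booster into per-tree arrays. Split thresholds and input
## values are quantized to float32 so routing matches the booster exactly.
parse_booster <- function(model, feature_names) {
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  base_score <- as.numeric(
    xgboost::xgb.config(model)$learner$learner_model_param$base_score)
  trees <- lapply(split(dump, dump$Tree), function(tt) {
    tt <- tt[order(tt$Node), ]
    id2idx <- stats::setNames(seq_len(nrow(tt)), tt$ID)
    leaf <- tt$Feature == "Leaf"
    fidx <- match(tt$Feature, feature_names)
    if (anyNA(fidx[!leaf]))
      stop("feature-name mismatch between model and matrix: model splits ",
           "on ", paste(unique(tt$Feature[!leaf][is.na(fidx[!leaf])]),
                        collapse = ", "))
    list(
      feature = ifelse(leaf, NA_integer_, fidx),
      split = float32(tt$Split),
      yes = ifelse(leaf, NA_integer_, unname(id2idx[tt$Yes])),
      no = ifelse(leaf, NA_integer_, unname(id2idx[tt$No])),
      cover = tt$Cover,
      value = ifelse(leaf, tt$Gain, NA_real_)
    )
  })
  list(trees = trees, base_margin = stats::qlogis(base_score))
}

## Exact double-precision margin: walk every tree.
tree_walk_value <- function(tree, x) {
  j <- 1L
  while (is.na(tree$value[j]))
    j <- if (x[tree$feature[j]] < tree$split[j]) tree$yes[j] else tree$no[j]
  tree$value[j]
}

## Cover-weighted expected leaf value of one tree.
tree_expected_value <- function(tree, j = 1L) {
  if (!is.na(tree$value[j])) return(tree$value[j])
  (tree$cover[tree$yes[j]] * tree_expected_value(tree, tree$yes[j]) +
   tree$cover[tree$no[j]] * tree_expected_value(tree, tree$no[j])) /
    tree$cover[j]
}

## EXTEND: grow the feature path by one (feature, zero fraction, one
## fraction) triple, updating the subset-permutation weights.
path_extend <- function(m, pz, po, pi) {
  l <- length(m$w)
  L <- l + 1L
  m$d <- c(m$d, pi)
  m$z <- c(m$z, pz)
  m$o <- c(m$o, po)
  m$w <- c(m$w, if (l == 0L) 1 else 0)
  if (l > 0L) for (i in l:1) {
    m$w[i + 1L] <- m$w[i + 1L] + po * m$w[i] * i / L
    m$w[i] <- pz * m$w[i] * (L - i) / L
  }
  m
}

## weights of the path with element i unwound (without removing it)
path_unwound_sum <- function(m, i) {
  L <- length(m$w)
  n <- m$w[L]
  tot <- 0
  oi <- m$o[i]
  zi <- m$z[i]
  for (j in (L - 1L):1L) {
    if (oi != 0) {
      t <- n * L / (j * oi)
      tot <- tot + t
      n <- m$w[j] - t * zi * (L - j) / L
    } else {
      tot <- tot + m$w[j] * L / (zi * (L - j))
    }
  }
  tot
}

## UNWIND: remove element i from the path
path_unwind <- function(m, i) {
  L <- length(m$w)
  n <- m$w[L]
  oi <- m$o[i]
  zi <- m$z[i]
  w <- m$w
  for (j in (L - 1L):1L) {
    if (oi != 0) {
      t <- w[j]
      w[j] <- n * L / (j * oi)
      n <- t - w[j] * zi * (L - j) / L
    } else {
      w[j] <- w[j] * L / (zi * (L - j))
    }
  }
  keep <- setdiff(seq_len(L), i)
  list(d = m$d[keep], z = m$z[keep], o = m$o[keep], w = w[-L])
}

## Shapley attributions of one tree for one sample (Lundberg-style
## path-dependent recursion; covers define the background distribution).
tree_shap_one <- function(tree, x, p) {
  phi <- numeric(p)
  recurse <- function(j, m, pz, po, pi) {
    m <- path_extend(m, pz, po, pi)
    if (!is.na(tree$value[j])) {
      L <- length(m$w)
      if (L >= 2L) for (i in 2:L) {
        w <- path_unwound_sum(m, i)
        phi[m$d[i]] <<- phi[m$d[i]] +
          w * (m$o[i] - m$z[i]) * tree$value[j]
      }
    } else {
      f <- tree$feature[j]
      hot <- if (x[f] < tree$split[j]) tree$yes[j] else tree$no[j]
      cold <- if (hot == tree$yes[j]) tree$no[j] else tree$yes[j]
      iz <- 1
      io <- 1
      k <- which(m$d == f)[1]
      if (!is.na(k) && k > 1L) {
        iz <- m$z[k]
        io <- m$o[k]
        m <- path_unwind(m, k)
      }
      recurse(hot, m, iz * tree$cover[hot] / tree$cover[j], io, f)
      recurse(cold, m, iz * tree$cover[cold] / tree$cover[j], 0, f)
    }
  }
  recurse(1L, list(d = integer(), z = numeric(), o = numeric(),
                   w = numeric()), 1, 1, 0L)
  phi
}

#' Double-precision tree Shapley values for a boosted binary classifier
#'
#' Path-dependent Shapley attributions on the margin (log-odds) scale,
#' computed from the booster's tree structure with training covers as the
#' background weights; per sample, `base + rowSums(phi)` reproduces the
#' exact margin to double precision.
#'
#' @param model An `xgb.Booster`.
#' @param features Samples x features matrix (column order must match the
#'   model's training matrix).
#' @return List with `phi` (samples x features), `base` (expected margin)
#'   and `margin` (exact per-sample margins).
#' @export
tree_shap <- function(model, features) {
  stopifnot(is.matrix(features))
  pb <- parse_booster(model, colnames(features))
  p <- ncol(features)
  xq <- matrix(float32(features), nrow(features))
  base <- pb$base_margin +
    sum(vapply(pb$trees, tree_expected_value, 0))
  phi <- matrix(0, nrow(features), p,
                dimnames = list(rownames(features), colnames(features)))
  margin <- rep(pb$base_margin, nrow(features))
  for (tree in pb$trees) {
    if (length(tree$value) == 1L) {  # stump-free tree: constant leaf
      margin <- margin + tree$value
      next
    }
    for (s in seq_len(nrow(features))) {
      phi[s, ] <- phi[s, ] + tree_shap_one(tree, xq[s, ], p)
      margin[s] <- margin[s] + tree_walk_value(tree, xq[s, ])
    }
  }
  list(phi = phi, base = base, margin = margin)
}
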