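# Exact TreeSHAP for the boosted-tree bundles, computed in double
# precision from the serialized trees. Each shallow tree touches only a
# handful of distinct features, so its Shapley values can be obtained
# exactly by enumerating the subsets of that tree's own feature set and
# evaluating cover-weighted conditional expectations (the path-dependent
# value function): masked features descend both children weighted by
# training cover, unmasked features follow the patient's value. Summing
# per-tree attributions is exact because Shapley values are additive
# across an ensemble sum.
#
# The deep random-forest bundles (too many distinct features per tree for
# enumeration) fall back to xgboost's native predcontrib, which computes
# the same quantity in single precision.

# round-trip through 4-byte floats: xgboost compares feature values and
# split thresholds in single precision, so we must too
f32 <- function(v) readBin(writeBin(as.numeric(v), raw(), size = 4L),
                           "numeric", n = length(v), size = 4L)

parse_trees <- function(bundle) {
  j <- jsonlite::fromJSON(rawToChar(xgboost::xgb.save.raw(bundle$booster,
                                                          raw_format = "json")),
                          simplifyVector = TRUE)
  tr <- j$learner$gradient_booster$model$trees
  manifest <- bundle$manifest
  lapply(seq_along(tr$left_children), function(k) {
    left <- tr$left_children[[k]]
    is_leaf <- left == -1L
    list(feature = ifelse(is_leaf, NA_character_,
                          manifest[tr$split_indices[[k]] + 1L]),
         # serialized as shortest round-trip decimals of float32 values:
         # re-round so double comparisons reproduce float32 comparisons
         split = f32(tr$split_conditions[[k]]),
         yes = tr$left_children[[k]] + 1L,
         no = tr$right_children[[k]] + 1L,
         value = ifelse(is_leaf, tr$split_conditions[[k]], NA_real_),
         cover = tr$sum_hessian[[k]])
  })
}

# expected tree output for all rows of x with features outside `keep`
# marginalized by cover weights; x must already be f32-rounded
eval_tree_masked <- function(tree, x, keep) {
  n <- nrow(x)
  rec <- function(node) {
    f <- tree$feature[node]
    if (is.na(f)) return(rep(tree$value[node], n))
    yes <- tree$yes[node]; no <- tree$no[node]
    if (f %in% keep) {
      goyes <- x[, f] < tree$split[node]
      ifelse(goyes, rec(yes), rec(no))
    } else {
      wy <- tree$cover[yes] / (tree$cover[yes] + tree$cover[no])
      wy * rec(yes) + (1 - wy) * rec(no)
    }
  }
  rec(1L)
}

exact_tree_shap <- function(bundle, x) {
  trees <- parse_trees(bundle)
  x <- apply(x, 2L, f32)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, bundle$manifest))
  n <- nrow(x)
  phi <- matrix(0, n, length(bundle$manifest),
                dimnames = list(rownames(x), bundle$manifest))
  base <- bundle$base_margin
  for (tree in trees) {
    feats <- unique(tree$feature[!is.na(tree$feature)])
    k <- length(feats)
    if (k == 0L) {            # stump: constant contribution
      base <- base + tree$value[1L]
      next
    }
    nsub <- 2^k
    bits <- 2^(seq_len(k) - 1L)
    v <- vector("list", nsub)
    for (mask in 0:(nsub - 1L)) {
      keep <- feats[bitwAnd(mask, bits) > 0]
      v[[mask + 1L]] <- eval_tree_masked(tree, x, keep)
    }
    base <- base + v[[1L]][1L]   # v(empty set) is row-independent
    fact <- factorial(0:k)
    for (i in seq_len(k)) {
      bit <- bits[i]
      for (mask in 0:(nsub - 1L)) {
        if (bitwAnd(mask, bit) > 0) next
        s <- sum(bitwAnd(mask, bits) > 0)
        w <- fact[s + 1L] * fact[k - s] / fact[k + 1L]
        phi[, feats[i]] <- phi[, feats[i]] +
          w * (v[[mask + bit + 1L]] - v[[mask + 1L]])
      }
    }
  }
  list(values = phi, base = rep(base, n))
}

# double-precision margin from the serialized trees (the reference against
# which SHAP local accuracy is exact)
predict_margin_exact <- function(bundle, x) {
  trees <- parse_trees(bundle)
  x <- apply(x, 2L, f32)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, bundle$manifest))
  out <- rep(bundle$base_margin, nrow(x))
  for (tree in trees) {
    out <- out + eval_tree_masked(tree, x, unique(tree$feature))
  }
  out
}
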