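## Independent oracles used by the cross-check tests. These deliberately
## re-derive quantities by the most literal route available (explicit
## loops, closed forms) and share nothing with the package implementation
## except, where the check is about the boosting logic itself, the weak
## learner.

## Half-up rounding at the precision accuracy tables print.
round_half_up <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

## Brute-force pooled within-cluster SD: explicit sorted scan building
## clusters, then explicit double loop over squared deviations.
oracle_cstd <- function(intervals, gap_threshold = NULL) {
  if (is.null(gap_threshold)) gap_threshold <- 0.12 * median(intervals)
  s <- sort(intervals)
  clusters <- list(s[1])
  for (i in seq_along(s)[-1]) {
    if (s[i] - s[i - 1] > gap_threshold) {
      clusters[[length(clusters) + 1]] <- s[i]
    } else {
      clusters[[length(clusters)]] <- c(clusters[[length(clusters)]], s[i])
    }
  }
  ss <- 0
  for (cl in clusters) {
    mu <- sum(cl) / length(cl)
    for (v in cl) ss <- ss + (v - mu)^2
  }
  sqrt(ss / length(s))
}

## Row-at-a-time tree walk, independent of the vectorized implementation.
oracle_walk_tree <- function(node, row) {
  while (is.null(node$leaf)) {
    node <- if (row[[node$feature]] <= node$threshold) node$left
            else node$right
  }
  node$leaf
}

## Independent AdaBoost.M1 loop. Shares only the weak-learner fitter with
## the implementation under test (the check is that the reweighting and
## voting logic agree), and predicts by explicit per-row tree walks.
oracle_adaboost <- function(X, y, rounds, max_depth) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (t in seq_len(rounds)) {
    wl <- afibscreen::fit_weak_learner(X, y, w, max_depth)
    pred <- vapply(seq_len(n),
                   function(i) oracle_walk_tree(wl$tree, X[i, ]), "")
    miss <- pred != y
    eps <- sum(w[miss])
    if (eps >= 0.5) break
    if (eps == 0) {
      trees <- c(trees, list(wl$tree))
      alphas <- c(alphas, log(1e6))
      break
    }
    beta <- eps / (1 - eps)
    trees <- c(trees, list(wl$tree))
    alphas <- c(alphas, log(1 / beta))
    w[!miss] <- w[!miss] * beta
    w <- w / sum(w)
  }
  list(trees = trees, alphas = alphas)
}

oracle_adaboost_predict <- function(model, X) {
  out <- character(nrow(X))
  margins <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    score <- 0
    for (t in seq_along(model$trees)) {
      vote <- if (oracle_walk_tree(model$trees[[t]], X[i, ]) == "AFIB")
        1 else -1
      score <- score + model$alphas[t] * vote
    }
    margins[i] <- score / sum(model$alphas)
    out[i] <- if (margins[i] > 0) "AFIB" else "NON_AFIB"
  }
  list(label = out, margin = margins)
}

## Fixed 40-row toy feature table: overlapping classes so boosting runs
## several imperfect rounds (the regime where the reweighting logic is
## actually exercised).
toy_feature_table <- function() {
  ds <- c(
    lapply(1:10, function(i) afibscreen::simulate_afib(20, cv = 0.13,
                                                       seed = 300 + i)),
    lapply(1:10, function(i) afibscreen::simulate_afib(20, cv = 0.06,
                                                       seed = 400 + i)),
    lapply(1:10, function(i) afibscreen::simulate_sinus(20,
                                                        jitter_sd = 0.05,
                                                        seed = 500 + i)),
    lapply(1:10, function(i) afibscreen::simulate_pc(20, pattern = "random",
                                                     pc_probability = 0.3,
                                                     jitter_sd = 0.04,
                                                     seed = 600 + i))
  )
  ## relabel the low-cv group as AFib too: makes the classes overlap
  for (i in 11:20) ds[[i]]$label <- "AFIB"
  afibscreen::feature_table(ds)
}

## Small standard training config used by several tests (same class mix
## as the default, scaled down).
small_config <- function(n_afib = 100L, n_sinus = 50L, n_big = 25L,
                         n_rand = 25L) {
  cfg <- afibscreen::default_config()
  cfg$simulate$n_afib <- n_afib
  cfg$simulate$n_sinus <- n_sinus
  cfg$simulate$n_pc_bigeminy <- n_big
  cfg$simulate$n_pc_random <- n_rand
  cfg
}
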