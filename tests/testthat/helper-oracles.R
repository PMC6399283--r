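## Independent oracles and fixture builders shared across tests.

## Direct per-variable evaluation of the Gower formula, written without
## reference to the package implementation.
gower_oracle <- function(df, specs) {
  n <- nrow(df)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (s in specs) {
      a <- df[[s$name]][i]; b <- df[[s$name]][j]
      if (s$kind == "numeric") {
        rng <- diff(s$range)
        num <- num + if (rng > 0) s$weight * abs(a - b) / rng else 0
        den <- den + s$weight
      } else if (s$kind == "binary_asymmetric") {
        if (!(a == 0 && b == 0)) {
          num <- num + s$weight * (a != b)
          den <- den + s$weight
        }
      } else {
        num <- num + s$weight * (a != b)
        den <- den + s$weight
      }
    }
    out[i, j] <- if (den > 0) num / den else 0
  }
  out
}

## Exhaustive greedy complete-linkage agglomeration on a square
## distance matrix: returns merge heights (in merge order) and the
## partition at every k.
complete_linkage_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partitions <- vector("list", n)
  partitions[[n]] <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best_h <- Inf; best <- c(NA, NA)
    for (i in 2:length(clusters)) for (j in seq_len(i - 1)) {
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(j, i) }
    }
    heights[step] <- best_h
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[n - step]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

same_partition <- function(a, b) {
  isTRUE(all.equal(cluster_agreement(a, b), 1))
}

## Random five-factor cohort with no planted structure.
random_cohort <- function(n, seed) {
  set.seed(seed)
  data.frame(sex = rbinom(n, 1, 0.5),
             age = runif(n, 40, 70),
             bmi = rnorm(n, 25, 3),
             htn = rbinom(n, 1, 0.3),
             fhdm = rbinom(n, 1, 0.2),
             dm = rbinom(n, 1, 0.2))
}

## Three well-separated clusters with chosen prevalences: categorical
## combinations differ and the numeric variables are tight around
## distinct centres.
separated_cohort <- function(n_per = 200, prevs = c(0.05, 0.25, 0.60),
                             seed = 1) {
  set.seed(seed)
  k <- length(prevs)
  data.frame(
    sex = rep(c(0, 1, 0)[seq_len(k)], each = n_per),
    age = c(rnorm(n_per, 45, 2), rnorm(n_per, 55, 2),
            rnorm(n_per, 65, 2))[seq_len(k * n_per)],
    bmi = c(rnorm(n_per, 22, 1), rnorm(n_per, 25, 1),
            rnorm(n_per, 29, 1))[seq_len(k * n_per)],
    htn = rep(c(0, 0, 1)[seq_len(k)], each = n_per),
    fhdm = rep(c(0, 1, 0)[seq_len(k)], each = n_per),
    dm = rbinom(k * n_per, 1, rep(prevs, each = n_per)),
    true_cluster = rep(paste0("S", seq_len(k)), each = n_per))
}

## Exhaustive pair-counting AUC (ties count one half).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
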