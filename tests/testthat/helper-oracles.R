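# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity by direct enumeration, sharing no code with the
# package implementation.

# Exhaustive O(N^2) template-pair counts for sample entropy:
# B over all n-m+1 length-m templates, A over the n-m length-(m+1) templates.
oracle_sampen_counts <- function(x, m, r) {
  n <- length(x)
  nB <- n - m + 1
  nA <- n - m
  B <- A <- 0
  for (i in seq_len(nB - 1)) {
    for (j in seq.int(i + 1, nB)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (i <= nA && j <= nA &&
            max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) {
          A <- A + 1
        }
      }
    }
  }
  c(B = B, A = A)
}

oracle_sampen <- function(x, m, r) {
  cnt <- oracle_sampen_counts(x, m, r)
  if (cnt["A"] == 0 || cnt["B"] == 0) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}

# All-pairs concordance count for the AUC (ties counted 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}

# Exact one-sided (greater) signed-rank p-value by full 2^n sign enumeration.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_null <- as.matrix(signs) %*% r
  mean(W_null >= W_obs)
}

# Textbook DFA (fluctuation convention): per-box lm detrending, slope of
# log F(n) vs log n. Independent of the package's closed-form residuals.
oracle_dfa_alpha <- function(x, scales) {
  y <- cumsum(x - mean(x))
  N <- length(y)
  fn <- sapply(scales, function(n) {
    nb <- floor(N / n)
    sq <- function(seg) {
      t <- seq_along(seg)
      fit <- lm(seg ~ t)
      mean(residuals(fit)^2)
    }
    msrs <- c(
      sapply(seq_len(nb), function(b) sq(y[((b - 1) * n + 1):(b * n)])),
      sapply(seq_len(nb), function(b) {
        sq(y[(N - b * n + 1):(N - (b - 1) * n)])
      })
    )
    sqrt(mean(msrs))
  })
  unname(coef(lm(log(fn) ~ log(scales)))[2])
}

# Small, quick cohort configuration for pipeline tests (shorter stays than
# the default world so suites stay fast; structure unchanged).
quick_config <- function(n = 12, seed = 11, event_fraction = 0.25, ...) {
  cohort_config(n_admissions = n, event_fraction = event_fraction,
                stay_meanlog = log(30), stay_sdlog = 0.2, seed = seed, ...)
}

quick_run_config <- function(seed = 11, n = 10, event_fraction = 0.3,
                             n_boot = 25) {
  cfg <- default_run_config(seed = seed)
  cfg$cohort$n_admissions <- n
  cfg$cohort$event_fraction <- event_fraction
  cfg$cohort$stay_meanlog <- log(30)
  cfg$cohort$stay_sdlog <- 0.2
  cfg$evaluation$n_boot <- n_boot
  cfg
}
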