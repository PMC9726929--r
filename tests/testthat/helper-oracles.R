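# Independent oracles used across test files.

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxon_enumeration_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  center <- n * (n + 1) / 4
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  mean(abs(vs - center) >= abs(v_obs - center) - 1e-9)
}

# all permutations of 1..n (tiny n)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Shapley values as the average marginal contribution over all |F|!
# feature orderings, with the interventional value function recomputed
# from scratch
shap_permutation_oracle <- function(f, x, bg) {
  p <- length(x)
  v <- function(S) {
    h <- bg
    if (length(S)) h[, S] <- matrix(x[S], nrow(bg), length(S), byrow = TRUE)
    mean(f(h))
  }
  perms <- all_permutations(p)
  shap <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    S <- integer(0)
    for (i in perms[r, ]) {
      shap[i] <- shap[i] + v(c(S, i)) - v(S)
      S <- c(S, i)
    }
  }
  shap / nrow(perms)
}
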