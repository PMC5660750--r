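# Independent oracles used across the suite.  These deliberately use naive
# formula-level implementations (explicit inverse, exhaustive pair counting,
# elementwise loops) so they share no code with the package internals.

# exhaustive Mann-Whitney pair counting, ties at 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# dual ridge prediction via explicit matrix inverse: f(x) = y' (K+lI)^-1 k_x
oracle_krr_predict <- function(K, y, lambda, kx) {
  drop(t(y) %*% solve(K + lambda * diag(nrow(K))) %*% kx)
}

# primal ridge closed form from the normal equations on explicit features
oracle_primal_ridge <- function(X, y, lambda, xq) {
  # X is n x m (rows = samples); w = (X'X + lambda I_m)^-1 X' y
  w <- solve(t(X) %*% X + lambda * diag(ncol(X)), t(X) %*% y)
  drop(xq %*% w)
}

# direct confusion-metric recomputation
oracle_metrics <- function(tp, fp, tn, fn) {
  list(sn = tp / (fn + tp), sp = tn / (tn + fp), pre = tp / (fp + tp),
       f1 = 2 * (tp / (fp + tp)) * (tp / (fn + tp)) /
         ((tp / (fp + tp)) + (tp / (fn + tp))),
       mcc = (tp * tn - fp * fn) /
         sqrt((tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)))
}

# elementwise kernel recomputation on a bundle (direct formula evaluation)
oracle_seq_raw <- function(w1, w2, pad = "X") {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62
  total <- 0
  for (k in seq_len(nchar(w1))) {
    a1 <- substr(w1, k, k); a2 <- substr(w2, k, k)
    if (a1 == pad || a2 == pad) next
    total <- total + b[a1, a2]
  }
  total
}

oracle_jaccard <- function(a, b) {
  if (length(union(a, b)) == 0) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

oracle_gaussian <- function(y1, y2, gamma) exp(-gamma * sum((y1 - y2)^2))

# random strictly-PD kernel of size n
random_pd_kernel <- function(n, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * (n + 2)), n + 2, n)
    K <- crossprod(A) / (n + 2) + diag(0.1, n)
  })
  dimnames(K) <- list(paste0("s", 1:n), paste0("s", 1:n))
  K
}

random_windows <- function(n, seed) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(aa, 15, replace = TRUE), collapse = ""), "")
  })
}
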