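# Independent oracles used to cross-check the package's ML machinery.

# EM for a multinomial mixture with fixed component distributions (the columns
# of a transition matrix): monotone-likelihood fixed-point iteration, entirely
# independent of the package's quasi-Newton path.
em_mixture <- function(Tmat, counts, starts = 20, max_iter = 5e4,
                       tol = 1e-13, seed = 1) {
  set.seed(seed)
  best <- NULL
  for (s in seq_len(starts)) {
    pi <- as.numeric(rexp(ncol(Tmat)))
    pi <- pi / sum(pi)
    for (i in seq_len(max_iter)) {
      ps <- as.numeric(Tmat %*% pi)
      post <- sweep(Tmat, 2L, pi, "*") / ps
      pin <- as.numeric(crossprod(post, counts)) / sum(counts)
      if (max(abs(pin - pi)) < tol) { pi <- pin; break }
      pi <- pin
    }
    ll <- sum(counts[counts > 0] * log((Tmat %*% pi)[counts > 0]))
    if (is.null(best) || ll > best$ll) best <- list(pi = pi, ll = ll)
  }
  best
}

# Dense grid search over the K-simplex (step `by`), brute-force ML oracle.
grid_search_simplex <- function(Tmat, counts, by = 1e-3) {
  K <- ncol(Tmat)
  stopifnot(K %in% c(3L, 4L))
  g <- seq(0, 1, by = by)
  if (K == 3L) {
    cand <- expand.grid(a = g, b = g)
    cand <- cand[cand$a + cand$b <= 1 + 1e-12, ]
    P <- rbind(cand$a, cand$b, 1 - cand$a - cand$b)
  } else {
    cand <- expand.grid(a = g, b = g, c = g)
    cand <- cand[cand$a + cand$b + cand$c <= 1 + 1e-12, ]
    P <- rbind(cand$a, cand$b, cand$c, 1 - cand$a - cand$b - cand$c)
  }
  PS <- Tmat %*% P                       # profiles x candidates
  pos <- counts > 0
  ll <- colSums(counts[pos] * log(PS[pos, , drop = FALSE]))
  ll[!is.finite(ll)] <- -Inf
  j <- which.max(ll)
  list(pi = P[, j], ll = ll[j], step = by)
}

expect_colsums_one <- function(tm, tol = 1e-12) {
  block <- attr(tm, "block")
  if (is.null(block)) block <- rep(1L, nrow(tm))
  for (b in unique(block)) {
    cs <- colSums(tm[block == b, , drop = FALSE])
    expect_true(all(abs(cs - 1) <= tol))
  }
}
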