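# Independent oracles used by unit and acceptance tests.  Nothing here calls
# the package's Laplace code path: the quadrature oracle integrates the exact
# latent posterior by a Gauss-Hermite product rule.

# Gauss-Hermite nodes/weights (physicists' convention) by Golub-Welsch.
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact GP-probit predictive probability by brute-force quadrature over the
# n-dimensional latent posterior (n = number of training points, <= 5).
exact_gpc_prob <- function(X, y, xstar, amplitude, bias = 0,
                           normalize = TRUE, nq = 14) {
  X <- as.matrix(X)
  n <- nrow(X)
  K0 <- tcrossprod(X)
  f <- if (normalize) n / sum(diag(K0)) else 1
  K <- amplitude * K0 * f + bias + diag(1e-8, n)
  ks <- amplitude * f * as.numeric(X %*% xstar) + bias
  kss <- amplitude * f * sum(xstar^2) + bias
  Kinv_ks <- solve(K, ks)
  s2 <- max(kss - sum(ks * Kinv_ks), 0) + 1e-12
  gh <- gauss_hermite(nq)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nq)), n)))
  Zm <- matrix(gh$nodes[grid], nrow(grid), n)
  logw <- rowSums(matrix(log(gh$weights[grid]), nrow(grid), n)) -
    n / 2 * log(pi)
  Fm <- sqrt(2) * Zm %*% chol(K)
  loglik <- rowSums(pnorm(Fm * matrix(y, nrow(Fm), n, byrow = TRUE),
                          log.p = TRUE))
  w <- exp(logw + loglik)
  mu <- as.numeric(Fm %*% Kinv_ks)
  sum(w * pnorm(mu / sqrt(1 + s2))) / sum(w)
}

# A null group spec: zero pattern amplitude everywhere (pure noise).
null_group <- function(label = "HC", n_subjects = 18, noise_sd = 1,
                       subject_variability = 0.2) {
  group_spec(label, n_subjects,
             pattern_amplitude = c(neutral = 0, mild_happy = 0,
                                   intense_happy = 0),
             pattern_overlap = 0, subject_variability = subject_variability,
             noise_sd = noise_sd)
}

# A noiseless, perfectly separable group: disjoint condition patterns, no
# subject variability, no noise... except classifiers need nonzero variance
# across subjects to form a mask and invert kernels, so a whisper of noise
# is allowed via `noise_sd`.
separable_group <- function(label = "HC", n_subjects = 18, amplitude = 1,
                            noise_sd = 0) {
  group_spec(label, n_subjects,
             pattern_amplitude = c(neutral = amplitude,
                                   mild_happy = amplitude,
                                   intense_happy = amplitude),
             pattern_overlap = 0, subject_variability = 0,
             noise_sd = noise_sd)
}
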