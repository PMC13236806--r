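# Independent oracles and fixture builders shared across the test files.
# Oracles are written from the defining formulas (explicit normal equations,
# step-up definition, exhaustive greedy), never by calling the functions they
# check.

# Explicit weighted-least-squares solution: beta = (X'WX)^-1 X'W y,
# var = (X'WX)^-1 (fixed-effects scaling).
oracle_wls <- function(X, w, y) {
  X <- as.matrix(X)
  XtWX <- t(X) %*% (w * X)
  inv <- solve(XtWX)
  list(beta = drop(inv %*% t(X) %*% (w * y)), se = sqrt(diag(inv)))
}

# Textbook OLS via normal equations, returning slope stats for column 1.
oracle_ols <- function(X, y) {
  X <- as.matrix(X)
  inv <- solve(t(X) %*% X)
  beta <- drop(inv %*% t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = beta, se = sqrt(s2 * diag(inv)))
}

# Definitional Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive greedy clumping on a precomputed r-squared matrix; same
# deterministic tie-break (p, then position, then id) as documented.
oracle_clump <- function(ids, p, pos, r2mat, threshold) {
  ord <- order(p, pos, ids)
  ids <- ids[ord]; p <- p[ord]
  r2mat <- r2mat[ord, ord, drop = FALSE]
  assigned <- rep(FALSE, length(ids))
  out <- list()
  while (!all(assigned)) {
    i <- which(!assigned)[1]
    mem <- which(!assigned & (r2mat[i, ] >= threshold | seq_along(ids) == i))
    assigned[mem] <- TRUE
    out[[length(out) + 1]] <- list(index = ids[i], members = sort(ids[mem]))
  }
  out
}

# Direct enumeration oracle for the exact Hardy-Weinberg test.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  hets <- seq(min(n_a, 2 * n - n_a) %% 2, min(n_a, 2 * n - n_a), by = 2)
  pr <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2
    hbb <- n - haa - h
    exp(h * log(2) + lgamma(n + 1) - lgamma(haa + 1) - lgamma(h + 1) -
          lgamma(hbb + 1) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) -
          lgamma(2 * n + 1))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Dosage columns with an exact target correlation structure: orthonormalise
# random uniforms, mix to the target correlation, then affinely rescale into
# [0.1, 1.9] (affine maps preserve correlation exactly).
make_corr_dosages <- function(n, R, seed = 1) {
  set.seed(seed)
  k <- nrow(R)
  raw <- matrix(runif(n * k), n, k)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  ortho <- qr.Q(qr(raw))
  L <- t(chol(R))
  X <- ortho %*% t(L)
  apply(X, 2, function(col) {
    0.1 + 1.8 * (col - min(col)) / (max(col) - min(col))
  })
}

# Random harmonised instrument-outcome pairs (all-positive gamma).
make_pairs <- function(J, seed) {
  set.seed(seed)
  tibble::tibble(variant_id = paste0("v", seq_len(J)),
                 gamma = runif(J, 0.2, 1.5),
                 se_gamma = runif(J, 0.02, 0.1),
                 Gamma = rnorm(J, 0, 0.3),
                 se_Gamma = runif(J, 0.02, 0.2),
                 flipped = FALSE)
}

# Summary-level two-sample MR pairs under a large-sample design with an
# optional shared direct (pleiotropic) outcome effect alpha.
make_pleiotropy_pairs <- function(theta, alpha, seed, J = 10,
                                  se_gamma = 0.02, se_Gamma = 0.02) {
  set.seed(seed)
  g <- seq(0.3, 1.2, length.out = J)
  tibble::tibble(variant_id = paste0("v", seq_len(J)),
                 gamma = g + rnorm(J, 0, se_gamma),
                 se_gamma = se_gamma,
                 Gamma = theta * g + alpha + rnorm(J, 0, se_Gamma),
                 se_Gamma = se_Gamma,
                 flipped = FALSE)
}

# Minimal phenotype table with standard covariates.
make_pheno <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(sample_id = paste0("s", seq_len(n)),
                 age = rnorm(n, 50, 10),
                 sex = sample(c("female", "male"), n, replace = TRUE),
                 bmi = rnorm(n, 27, 5),
                 y = rnorm(n))
}

expect_tibble_equal_num <- function(a, b, tol = 1e-10) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
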