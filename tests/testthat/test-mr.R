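test_that("harmonisation orients exposure effects positive and drops unmatched", {
  inst <- tibble::tibble(variant_id = c("v1", "v2"),
                         gamma = c(-0.5, 0.3), se_gamma = c(0.1, 0.1))
  outc <- tibble::tibble(variant_id = c("v1", "v2"),
                         Gamma = c(0.2, 0.1), se_Gamma = c(0.1, 0.1))
  pairs <- harmonise(inst, outc)
  expect_equal(pairs$gamma, c(0.5, 0.3))
  expect_equal(pairs$Gamma, c(-0.2, 0.1))
  # the Wald ratio is invariant under the flip
  expect_equal(pairs$Gamma[1] / pairs$gamma[1], 0.2 / -0.5)
  # already-positive gamma is untouched
  expect_false(pairs$flipped[2])
  # unmatched instrument dropped with a warning
  expect_warning(p2 <- harmonise(inst, outc[1, ]), "absent from outcome")
  expect_equal(nrow(p2), 1)
  expect_error(suppressWarnings(harmonise(inst, outc[0, ])), "no harmonised")
  # allele-aware reconciliation: swapped alleles flip Gamma
  inst2 <- dplyr::mutate(inst, effect_allele = "G", other_allele = "A")
  outc2 <- tibble::tibble(variant_id = c("v1", "v2"),
                          Gamma = c(0.2, 0.1), se_Gamma = c(0.1, 0.1),
                          effect_allele = c("A", "G"),
                          other_allele = c("G", "A"))
  p3 <- harmonise(inst2, outc2)
  expect_equal(p3$Gamma[1], 0.2) # swapped then gamma-flip restores sign
  expect_equal(p3$gamma[1], 0.5)
})

test_that("Wald ratio matches closed form and its Monte-Carlo delta SE", {
  w <- wald_ratio(0.5, 0.1, 0.2, 0.1)
  expect_equal(w$theta, 0.4)
  expect_equal(w$se_theta, 0.2)
  expect_equal(w$or_value, exp(0.4))
  expect_equal(wald_ratio(0.5, 0.1, 0, 0.1)$theta, 0)
  expect_error(wald_ratio(0, 0.1, 0.2, 0.1), "gamma = 0")
  # second-order delta SE against the SD of simulated ratios
  w2 <- wald_ratio(0.5, 0.1, 0.2, 0.1, second_order = TRUE)
  expect_equal(w2$se_theta, sqrt(0.1^2 / 0.5^2 + 0.2^2 * 0.1^2 / 0.5^4))
  set.seed(71)
  ratios <- rnorm(1e6, 0.2, 0.1) / rnorm(1e6, 0.5, 0.1)
  # a normal ratio has no finite variance (heavy tails), so compare against
  # the normal-consistent robust scale of the simulated ratios
  mc_sd <- mad(ratios)
  expect_lt(abs(w2$se_theta - mc_sd) / mc_sd, 0.05)
})

test_that("IVW matches the zero-intercept WLS oracle and reduces to Wald", {
  pairs <- tibble::tibble(variant_id = c("a", "b"), gamma = c(0.5, 1),
                          se_gamma = 0.1, Gamma = c(0.2, 0.4),
                          se_Gamma = c(0.1, 0.2), flipped = FALSE)
  f <- ivw_fixed(pairs)
  expect_equal(f$theta, 0.4)
  expect_equal(f$se_theta, 1 / sqrt(50))
  expect_equal(cochran_q(pairs)$Q, 0, tolerance = 1e-12)
  # single pair == wald exactly
  w <- wald_ratio(0.5, 0.1, 0.2, 0.1)
  f1 <- ivw_fixed(pairs[1, ])
  expect_equal(f1$theta, w$theta)
  expect_equal(f1$se_theta, w$se_theta)
  expect_identical(f1$method, "wald")
  # oracle on random sets
  for (i in 1:25) {
    p <- make_pairs(sample(2:8, 1), seed = 800 + i)
    fit <- ivw_fixed(p)
    o <- oracle_wls(matrix(p$gamma, ncol = 1), 1 / p$se_Gamma^2, p$Gamma)
    expect_equal(fit$theta, o$beta, tolerance = 1e-10)
    expect_equal(fit$se_theta, o$se, tolerance = 1e-10)
  }
})

test_that("Cochran's Q follows its hand computation and null distribution", {
  pairs <- tibble::tibble(variant_id = c("a", "b"), gamma = c(1, 1),
                          se_gamma = 0.05, Gamma = c(0.2, 0.4),
                          se_Gamma = c(0.1, 0.1), flipped = FALSE)
  q <- cochran_q(pairs)
  expect_equal(q$Q, 2.0)
  expect_equal(q$p, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(round(q$p, 4), 0.1573)
  # under a valid-instrument null, Q ~ chi-squared with J-1 df
  set.seed(72)
  J <- 5
  qs <- replicate(400, {
    g <- runif(J, 0.5, 1.5)
    seG <- runif(J, 0.05, 0.15)
    p <- tibble::tibble(variant_id = paste0("v", 1:J), gamma = g,
                        se_gamma = 0.001, Gamma = 0.3 * g + rnorm(J, 0, seG),
                        se_Gamma = seG, flipped = FALSE)
    cochran_q(p)$Q
  })
  expect_lt(abs(mean(qs) - (J - 1)), 4 * sqrt(2 * (J - 1) / 400))
})

test_that("multiplicative random-effects IVW floors at the fixed-effects SE", {
  # Q below its df: identical to fixed
  pairs <- make_pairs(4, seed = 73)
  pairs$Gamma <- 0.3 * pairs$gamma # perfectly proportional, Q ~ 0
  fx <- ivw_fixed(pairs); rd <- ivw_random(pairs)
  expect_equal(rd$theta, fx$theta)
  expect_equal(rd$se_theta, fx$se_theta)
  # engineered Q = 8 with J = 3 doubles the SE
  g <- c(1, 1, 1); seG <- c(0.1, 0.1, 0.1)
  delta <- sqrt(8 / 2 * 0.01) # each deviation contributes w*d^2 = 8/3... solve directly
  r <- c(-1, 0, 1) * sqrt(8 / 2) * 0.1
  p3 <- tibble::tibble(variant_id = c("a", "b", "c"), gamma = g,
                       se_gamma = 0.001, Gamma = 0.2 + r, se_Gamma = seG,
                       flipped = FALSE)
  q3 <- cochran_q(p3)
  expect_equal(q3$Q, 8, tolerance = 1e-10)
  fx3 <- ivw_fixed(p3); rd3 <- ivw_random(p3)
  expect_equal(rd3$se_theta, fx3$se_theta * 2, tolerance = 1e-10)
  expect_equal(rd3$theta, fx3$theta)
})

test_that("Egger matches the WLS-with-intercept oracle and exact lines", {
  pairs <- tibble::tibble(variant_id = c("a", "b", "c"), gamma = c(1, 2, 3),
                          se_gamma = 0.01, Gamma = c(0.3, 0.5, 0.7),
                          se_Gamma = 0.1, flipped = FALSE)
  e <- egger(pairs)
  expect_equal(e$theta, 0.2, tolerance = 1e-12)
  expect_equal(e$intercept, 0.1, tolerance = 1e-12)
  expect_equal(e$Q_egger, 0, tolerance = 1e-20)
  expect_error(egger(pairs[1:2, ]), "at least 3")
  expect_error(egger(dplyr::mutate(pairs, gamma = -gamma)), "all-positive")
  # oracle on random sets (overdispersion factor applied identically)
  for (i in 1:25) {
    p <- make_pairs(sample(3:8, 1), seed = 820 + i)
    fit <- egger(p)
    w <- 1 / p$se_Gamma^2
    o <- oracle_wls(cbind(1, p$gamma), w, p$Gamma)
    res <- p$Gamma - cbind(1, p$gamma) %*% o$beta
    qe <- sum(w * res^2)
    infl <- max(1, sqrt(qe / (nrow(p) - 2)))
    expect_equal(fit$theta, o$beta[2], tolerance = 1e-10)
    expect_equal(fit$intercept, o$beta[1], tolerance = 1e-10)
    expect_equal(fit$se_theta, o$se[2] * infl, tolerance = 1e-10)
    expect_equal(fit$se_intercept, o$se[1] * infl, tolerance = 1e-10)
    expect_equal(fit$Q_egger, qe, tolerance = 1e-10)
  }
  # reduction: constraining the Egger intercept to zero recovers IVW
  for (i in 1:5) {
    p <- make_pairs(5, seed = 840 + i)
    o0 <- oracle_wls(matrix(p$gamma, ncol = 1), 1 / p$se_Gamma^2, p$Gamma)
    expect_equal(ivw_fixed(p)$theta, o0$beta, tolerance = 1e-10)
  }
})

test_that("Egger intercept test is calibrated without pleiotropy", {
  set.seed(74)
  rej <- mean(replicate(400, {
    p <- make_pleiotropy_pairs(theta = 0.2, alpha = 0, seed = sample.int(1e6, 1))
    egger(p)$p_intercept < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.05)
})

test_that("the Rucker decision tree selects methods as specified", {
  # equal ratios: no heterogeneity, fixed-effects IVW kept
  pairs <- tibble::tibble(variant_id = c("a", "b"), gamma = c(0.5, 1),
                          se_gamma = 0.05, Gamma = c(0.2, 0.4),
                          se_Gamma = c(0.1, 0.2), flipped = FALSE)
  r <- rucker_select(pairs)
  expect_identical(r$method, "ivw_fixed")
  expect_equal(r$cochran_Q, 0, tolerance = 1e-12)
  expect_equal(r$cochran_Q_p, 1)
  # J = 1: Wald
  r1 <- rucker_select(pairs[1, ])
  expect_identical(r1$method, "wald")
  expect_true(is.na(r1$cochran_Q))
  # J = 2 with significant Q: random-effects IVW, Rucker p unavailable
  p2 <- tibble::tibble(variant_id = c("a", "b"), gamma = c(1, 1),
                       se_gamma = 0.001, Gamma = c(0.0, 0.8),
                       se_Gamma = c(0.1, 0.1), flipped = FALSE)
  r2 <- rucker_select(p2)
  expect_identical(r2$method, "ivw_random")
  expect_true(is.na(r2$rucker_p))
  expect_lt(r2$cochran_Q_p, 0.05)
  # the Q-difference test reproduces the chi-squared tail
  rq <- rucker_q_test(10, 5.35)
  expect_equal(rq$q_diff, 4.65)
  expect_equal(round(rq$p, 3), 0.031)
})

test_that("MR statistics are scale-equivariant and permutation-invariant", {
  p <- make_pairs(6, seed = 75)
  base <- ivw_fixed(p)
  c1 <- 2.5
  p_g <- dplyr::mutate(p, gamma = gamma * c1) # se_gamma unused by IVW
  expect_equal(ivw_fixed(p_g)$theta, base$theta / c1, tolerance = 1e-12)
  p_G <- dplyr::mutate(p, Gamma = Gamma * c1, se_Gamma = se_Gamma * c1)
  expect_equal(ivw_fixed(p_G)$theta, base$theta * c1, tolerance = 1e-12)
  # permutation invariance across all statistics
  set.seed(76)
  perm <- p[sample(nrow(p)), ]
  r_a <- rucker_select(p); r_b <- rucker_select(perm)
  expect_equal(r_a$estimate$theta, r_b$estimate$theta, tolerance = 1e-12)
  expect_equal(r_a$cochran_Q, r_b$cochran_Q, tolerance = 1e-12)
  expect_equal(r_a$rucker_Q_diff, r_b$rucker_Q_diff, tolerance = 1e-12)
  expect_identical(r_a$method, r_b$method)
})

test_that("batch MR returns one row per CpG and handles degenerate sets", {
  mk_set <- function(cpg, vid) {
    structure(list(cpg = cpg, tissue = "hepatocyte",
                   instruments = tibble::tibble(variant_id = vid, gamma = 0.6,
                                                se_gamma = 0.05,
                                                p_gamma = 1e-9,
                                                r2_exposure = 0.1),
                   cumulative_F = 40, n = 56, screened = TRUE),
              class = "instrument_set")
  }
  sets <- lapply(1:4, function(i) mk_set(paste0("cg", i), paste0("rs", i)))
  empty <- mk_set("cg_empty", "rs_none")
  empty$instruments <- empty$instruments[0, ]
  outc <- tibble::tibble(variant_id = paste0("rs", 1:4),
                         Gamma = c(0.25, -0.1, 0.05, 0.3),
                         se_Gamma = 0.12)
  expect_warning(res <- mr_all_cpgs(c(sets, list(empty)), outc),
                 "no instruments")
  expect_equal(nrow(res), 4)
  expect_true(all(res$method == "wald"))
  expect_true(all(is.na(res$cochran_Q)))
  expect_true(all(res$or_value > 0))
  expect_true("q" %in% names(res))
  # tidy/glance accessors
  rs <- attr(res, "results")
  td <- tidy(rs[[1]])
  expect_true(all(c("method", "theta", "selected") %in% names(td)))
  gl <- glance(rs[[1]])
  expect_equal(gl$n_instruments, 1L)
})

test_that("MR scatter and triangulation plots build without error", {
  s <- simulate_mr_study(seed = 77, theta = -0.3)
  r <- rucker_select(harmonise(s$instruments, s$outcome), cpg = "cg_target",
                     tissue = "blood")
  pl <- ggplot2::autoplot(r)
  expect_s3_class(pl, "ggplot")
})
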