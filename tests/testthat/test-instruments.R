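test_that("exact HWE test matches a direct enumeration oracle", {
  expect_equal(meqtlmr:::hwe_exact_p(25, 50, 25), 1, tolerance = 1e-9)
  expect_lt(meqtlmr:::hwe_exact_p(0, 100, 0), 1e-6)
  set.seed(51)
  for (i in 1:25) {
    cts <- as.vector(stats::rmultinom(1, sample(20:200, 1),
                                      prob = c(0.25, 0.5, 0.25)))
    expect_equal(meqtlmr:::hwe_exact_p(cts[1], cts[2], cts[3]),
                 oracle_hwe(cts[1], cts[2], cts[3]), tolerance = 1e-9)
  }
})

test_that("variant QC removes markers failing each filter", {
  n <- 200
  set.seed(52)
  good <- rbinom(n, 2, 0.3)
  rare <- rbinom(n, 2, 0.005)             # MAF < 1%
  allhet <- rep(1, n)                     # extreme HWE violation
  holes <- good; holes[1:20] <- NA        # 10% missing
  D <- cbind(v_good = good, v_rare = rare, v_het = allhet, v_miss = holes)
  rownames(D) <- paste0("s", 1:n)
  anno <- tibble::tibble(variant_id = colnames(D), chrom = "1",
                         pos = c(100L, 200L, 300L, 400L),
                         ref_allele = "A", alt_allele = "G",
                         info_score = c(1, 1, 1, 1))
  G <- geno_matrix(D, variants = anno)
  out <- qc_variants(G)
  expect_identical(colnames(out$dosages), "v_good")
  rm_counts <- attr(out, "removed")
  expect_gte(rm_counts[["maf"]], 1)
  expect_gte(rm_counts[["hwe"]], 1)
  expect_gte(rm_counts[["missingness"]], 1)
  # low INFO removed when annotated
  anno$info_score <- c(0.5, 1, 1, 1)
  out2 <- qc_variants(geno_matrix(D, variants = anno))
  expect_false("v_good" %in% colnames(out2$dosages))
})

test_that("ld_r2 is the definitional squared Pearson correlation", {
  set.seed(53)
  x <- runif(100, 0, 2)
  D <- cbind(a = x, b = x, c = runif(100, 0, 2))
  rownames(D) <- paste0("s", 1:100)
  G <- geno_matrix(D)
  expect_equal(ld_r2(G, "a", "b"), 1)
  brute <- (sum((D[, "a"] - mean(D[, "a"])) * (D[, "c"] - mean(D[, "c"]))) /
              sqrt(sum((D[, "a"] - mean(D[, "a"]))^2) *
                     sum((D[, "c"] - mean(D[, "c"]))^2)))^2
  expect_equal(ld_r2(G, "a", "c"), brute, tolerance = 1e-12)
  # orthogonalised column has r2 = 0
  resid <- lm.fit(cbind(1, D[, "a"]), D[, "c"])$residuals
  D2 <- cbind(D[, "a", drop = FALSE],
              d = 1 + (resid - min(resid)) / (max(resid) - min(resid)))
  rownames(D2) <- rownames(D)
  expect_lt(ld_r2(geno_matrix(D2), "a", "d"), 1e-20)
})

test_that("cis window arithmetic and probe-overlap exclusion are enforced", {
  set.seed(54)
  n <- 120
  D <- matrix(runif(n * 3, 0, 2), n, 3,
              dimnames = list(paste0("s", 1:n), c("v_near", "v_far", "v_on")))
  anno <- tibble::tibble(variant_id = colnames(D), chrom = "2",
                         pos = c(5000034L, 6200000L, 5000000L),
                         ref_allele = "A", alt_allele = "G",
                         info_score = 1)
  G <- geno_matrix(D, variants = anno)
  v <- matrix(rnorm(n), n, 1, dimnames = list(rownames(D), "cg1"))
  M <- methyl_matrix(v, probes = tibble::tibble(probe_id = "cg1", chrom = "2",
                                                pos = 5000000L))
  ph <- tibble::tibble(sample_id = rownames(D))
  res <- map_cis_meqtls(G, M, ph, window_bp = 2e6, covariates = character())
  # 34 bp away: tested; 1.2 Mb away: outside the +/- 1 Mb window; on-probe:
  # excluded
  expect_identical(sort(res$variant_id), "v_near")
  expect_false("v_on" %in% res$variant_id)
  expect_false("v_far" %in% res$variant_id)
  # no variants in any window -> empty with warning
  M2 <- methyl_matrix(v, probes = tibble::tibble(probe_id = "cg1", chrom = "9",
                                                 pos = 1L))
  expect_warning(res2 <- map_cis_meqtls(G, M2, ph, covariates = character()),
                 "no variants")
  expect_equal(nrow(res2), 0)
})

test_that("vectorised meQTL fits equal per-pair lm with covariates", {
  set.seed(55)
  n <- 150
  blocks <- list(list(n_variants = 4, freq = c(0.2, 0.4), r = 0.3))
  G <- simulate_genotypes(n, blocks, seed = 56)
  probes <- tibble::tibble(probe_id = c("cg1", "cg2"), chrom = "1",
                           pos = c(1000100L, 1011000L))
  tr <- truth_record(meqtl = tibble::tibble(probe_id = "cg1",
                                            variant_id = "snp_b1_2",
                                            gamma = 0.4))
  M <- simulate_methylation(G, tr, probes, seed = 57)$t1
  ph <- tibble::tibble(sample_id = rownames(G$dosages),
                       age = rnorm(n, 50, 8),
                       sex = sample(c("female", "male"), n, TRUE))
  res <- map_cis_meqtls(G, M, ph, window_bp = 2e6,
                        covariates = c("age", "sex"))
  for (k in seq_len(nrow(res))) {
    y <- M$values[, res$probe_id[k]]
    x <- G$dosages[, res$variant_id[k]]
    f <- summary(lm(y ~ x + ph$age + factor(ph$sex)))$coefficients
    expect_equal(res$beta[k], f["x", "Estimate"], tolerance = 1e-10)
    expect_equal(res$se[k], f["x", "Std. Error"], tolerance = 1e-10)
    expect_equal(res$p[k], f["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("greedy clumping reproduces the worked 3-SNP example", {
  R <- matrix(c(1, sqrt(0.5), sqrt(0.05),
                sqrt(0.5), 1, sqrt(0.02),
                sqrt(0.05), sqrt(0.02), 1), 3, 3)
  D <- make_corr_dosages(400, R, seed = 58)
  colnames(D) <- c("SNP1", "SNP2", "SNP3")
  rownames(D) <- paste0("s", 1:400)
  anno <- tibble::tibble(variant_id = colnames(D), chrom = "1",
                         pos = c(100L, 200L, 300L), ref_allele = "A",
                         alt_allele = "G", info_score = 1)
  G <- geno_matrix(D, variants = anno)
  expect_equal(ld_r2(G, "SNP1", "SNP2"), 0.5, tolerance = 1e-9)
  expect_equal(ld_r2(G, "SNP1", "SNP3"), 0.05, tolerance = 1e-9)
  assoc <- tibble::tibble(variant_id = c("SNP1", "SNP2", "SNP3"),
                          p = c(1e-8, 1e-5, 1e-3))
  cl <- clump(assoc, G, r2_threshold = 0.1)
  expect_identical(cl$index_variant, c("SNP1", "SNP3"))
  expect_identical(sort(cl$members[[1]]), c("SNP1", "SNP2"))
  # single SNP clumps to itself
  cl1 <- clump(assoc[1, ], G)
  expect_identical(cl1$index_variant, "SNP1")
  expect_equal(cl1$n_members, 1L)
  # strict threshold semantics: r2 = 0.09 stays independent
  R2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  D2 <- make_corr_dosages(400, R2, seed = 59)
  colnames(D2) <- c("A1", "A2"); rownames(D2) <- paste0("s", 1:400)
  G2 <- geno_matrix(D2, variants = tibble::tibble(
    variant_id = c("A1", "A2"), chrom = "1", pos = c(1L, 2L),
    ref_allele = "A", alt_allele = "G", info_score = 1))
  expect_equal(ld_r2(G2, "A1", "A2"), 0.09, tolerance = 1e-9)
  cl2 <- clump(tibble::tibble(variant_id = c("A1", "A2"), p = c(1e-4, 1e-2)),
               G2, r2_threshold = 0.1)
  expect_equal(nrow(cl2), 2)
  # unknown variant errors
  expect_error(clump(tibble::tibble(variant_id = "nope", p = 0.1), G),
               "absent from LD reference")
})

test_that("clumping equals the exhaustive greedy oracle and partitions the set", {
  for (i in 1:30) {
    set.seed(900 + i)
    k <- sample(3:8, 1)
    n <- 80
    D <- matrix(runif(n * k, 0, 2), n, k,
                dimnames = list(paste0("s", 1:n), paste0("v", 1:k)))
    # induce some correlation
    for (j in seq(2, k, by = 2)) {
      D[, j] <- pmin(pmax(D[, j - 1] + rnorm(n, 0, 0.4), 0), 2)
    }
    anno <- tibble::tibble(variant_id = colnames(D), chrom = "1",
                           pos = seq_len(k) * 10L, ref_allele = "A",
                           alt_allele = "G", info_score = 1)
    G <- geno_matrix(D, variants = anno)
    p <- round(runif(k), 2) # rounded to produce occasional ties
    assoc <- tibble::tibble(variant_id = colnames(D), p = p)
    cl <- clump(assoc, G, r2_threshold = 0.1)
    r2mat <- outer(seq_len(k), seq_len(k),
                   Vectorize(function(a, b) ld_r2(G, colnames(D)[a],
                                                  colnames(D)[b])))
    orc <- oracle_clump(colnames(D), p, anno$pos, r2mat, 0.1)
    expect_identical(cl$index_variant,
                     vapply(orc, function(x) x$index, character(1)))
    expect_identical(lapply(cl$members, sort),
                     lapply(orc, function(x) x$members))
    # members partition the input set
    expect_setequal(unlist(cl$members), colnames(D))
    expect_equal(sum(cl$n_members), k)
    # indices pairwise independent at the threshold
    idx <- cl$index_variant
    if (length(idx) > 1) {
      combs <- utils::combn(idx, 2)
      r2s <- apply(combs, 2, function(pair) ld_r2(G, pair[1], pair[2]))
      expect_true(all(r2s < 0.1))
    }
  }
})

test_that("cumulative F follows its closed form", {
  expect_equal(cumulative_f(0.1, 606), 604 * (0.1 / 0.9))
  expect_equal(round(cumulative_f(0.1, 606), 2), 67.11)
  expect_equal(cumulative_f(c(0, 0), 100), 0)
  expect_error(cumulative_f(c(0.6, 0.5), 100), "R-squared >= 1")
  expect_true(is.na(cumulative_f(numeric(0), 100)))
})

test_that("instrument sets carry marginal r2 and pass the F > 10 bar", {
  s <- simulate_mr_study(seed = 61, gamma = c(0.5, 0.5, 0.5))
  inst <- s$instruments
  expect_s3_class(inst, "instrument_set")
  expect_equal(nrow(inst$instruments), 3)
  expect_gt(inst$cumulative_F, 10)
  # r2_exposure is the squared partial correlation of the marginal fit
  expect_true(all(inst$instruments$r2_exposure > 0 &
                    inst$instruments$r2_exposure < 1))
})

test_that("the confounder screen removes confounded instruments only", {
  set.seed(62)
  n <- 400
  blocks <- list(list(n_variants = 2, freq = 0.3, r = 0))
  G <- simulate_genotypes(n, blocks, seed = 63)
  ph <- tibble::tibble(sample_id = rownames(G$dosages),
                       age = rnorm(n, 50, 10),
                       sex = sample(c("female", "male"), n, TRUE),
                       bmi = 25 + 2 * G$dosages[, 1] + rnorm(n), # confounded
                       waist = rnorm(n, 90, 10),
                       hip = rnorm(n, 100, 10),
                       smoker = runif(n) < 0.1)
  inst <- structure(list(cpg = "cg1", tissue = "blood",
                         instruments = tibble::tibble(
                           variant_id = c("snp_b1_1", "snp_b1_2"),
                           gamma = c(0.5, 0.4), se_gamma = c(0.05, 0.05),
                           p_gamma = c(1e-10, 1e-8),
                           r2_exposure = c(0.1, 0.08)),
                         cumulative_F = 50, n = n, screened = FALSE),
                    class = "instrument_set")
  out <- screen_instruments(inst, G, ph)
  expect_false("snp_b1_1" %in% out$kept$instruments$variant_id)
  expect_true("snp_b1_1" %in% out$excluded$variant_id)
  expect_true(out$kept$screened)
  # relaxed mode (age/sex only) keeps the BMI-confounded instrument
  out_rel <- screen_instruments(inst, G, ph, relaxed = TRUE)
  expect_true("snp_b1_1" %in% out_rel$kept$instruments$variant_id)
})

test_that("a null instrument survives the 6-confounder screen at the nominal rate", {
  kept <- 0
  reps <- 150
  for (i in 1:reps) {
    set.seed(1500 + i)
    n <- 250
    G <- simulate_genotypes(n, list(list(n_variants = 1, freq = 0.3, r = 0)),
                            seed = 1600 + i)
    ph <- tibble::tibble(sample_id = rownames(G$dosages),
                         age = rnorm(n, 50, 10),
                         sex = sample(c("female", "male"), n, TRUE),
                         bmi = rnorm(n, 27, 5), waist = rnorm(n, 90, 10),
                         hip = rnorm(n, 100, 10), smoker = runif(n) < 0.2)
    inst <- structure(list(cpg = "cg1", tissue = "blood",
                           instruments = tibble::tibble(
                             variant_id = "snp_b1_1", gamma = 0.5,
                             se_gamma = 0.05, p_gamma = 1e-10,
                             r2_exposure = 0.1),
                           cumulative_F = 50, n = n, screened = FALSE),
                      class = "instrument_set")
    out <- screen_instruments(inst, G, ph)
    kept <- kept + (nrow(out$kept$instruments) == 1)
  }
  # expected keep rate 0.95^6 ~ 0.735 under six independent nominal screens
  expect_lt(abs(kept / reps - 0.95^6), 0.1)
})
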