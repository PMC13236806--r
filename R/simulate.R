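# Two-cohort synthetic data with the causal structure the analysis assumes:
# SNP -> CpG methylation (cis meQTL effects gamma), CpG -> disease liability
# (theta, log-odds per M-unit), optional direct SNP -> outcome pleiotropy,
# longitudinal methylation drift, follow-up HbA1c, and cis-correlated tissue
# expression. Ground truth is recorded so recovery and calibration tests can
# compare estimates with the generating parameters.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically fork one master seed into per-stage seeds (< 2^31).
fork_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Ground-truth record for a synthetic cohort
#'
#' @param theta named numeric: causal log-odds of disease per M-value unit,
#'   one entry per causal CpG (zero-effect CpGs may be omitted).
#' @param meqtl tibble with `probe_id`, `variant_id`, `gamma` (M-units per
#'   alternate allele): the cis SNP-to-methylation effects.
#' @param pleiotropy tibble with `variant_id`, `alpha` (direct log-odds on the
#'   outcome, bypassing methylation); `NULL` for none.
#' @param prevalence named numeric of target disease prevalences per cohort.
#' @param drift named numeric of per-CpG mean M-value change between time
#'   points (default none).
#' @param lambda_follow linear coefficient linking centred causal-CpG burden
#'   to follow-up HbA1c (mmol/mol per liability unit).
#' @return A `truth_record` list.
#' @export
truth_record <- function(theta = numeric(), meqtl = NULL, pleiotropy = NULL,
                         prevalence = c(cohort = 0.05), drift = numeric(),
                         lambda_follow = 0) {
  meqtl <- if (is.null(meqtl)) {
    tibble(probe_id = character(), variant_id = character(), gamma = numeric())
  } else as_tibble(meqtl)
  pleiotropy <- if (is.null(pleiotropy)) {
    tibble(variant_id = character(), alpha = numeric())
  } else as_tibble(pleiotropy)
  structure(list(theta = theta, meqtl = meqtl, pleiotropy = pleiotropy,
                 prevalence = prevalence, drift = drift,
                 lambda_follow = lambda_follow),
            class = "truth_record")
}

#' Simulate genotype dosages with block LD structure
#'
#' Each variant's two allele copies are thresholded latent Gaussians; within a
#' block the latents share an exchangeable correlation `r`, which yields
#' Hardy-Weinberg genotype frequencies per variant, tunable within-block LD
#' (empirical r-squared increasing with `r`) and independence across blocks.
#'
#' @param n number of samples.
#' @param blocks list of blocks, each a list with `n_variants`, `freq` (either
#'   one allele frequency or a `c(lo, hi)` range to draw from) and `r`
#'   (latent within-block correlation, `0 <= r < 1`). Optional `chrom` and
#'   `start_pos` place the block; defaults spread blocks across chromosomes
#'   with 5 kb variant spacing.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param id_prefix prefix for sample ids.
#' @return A `geno_matrix` with variant annotation (chrom, pos, alleles,
#'   population alt frequency, `info_score = 1`).
#' @export
simulate_genotypes <- function(n, blocks, seed = NULL, id_prefix = "s") {
  stopifnot(n >= 1)
  with_seed(seed, {
    mats <- vector("list", length(blocks))
    annos <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      m <- blk$n_variants
      r <- blk$r %||% 0
      if (r >= 1 || r < 0) abort("within-block r must satisfy 0 <= r < 1")
      fr <- blk$freq
      freqs <- if (length(fr) == 2) runif(m, fr[1], fr[2]) else rep(fr, m)
      if (any(freqs <= 0 | freqs >= 1)) abort("allele frequencies must lie in (0,1)")
      thr <- qnorm(freqs)
      dos <- matrix(0, n, m)
      for (copy in 1:2) {
        z0 <- rnorm(n)
        Z <- sqrt(r) * z0 + sqrt(1 - r) * matrix(rnorm(n * m), n, m)
        dos <- dos + (Z < matrix(thr, n, m, byrow = TRUE))
      }
      chrom <- blk$chrom %||% as.character((b - 1) %% 22 + 1)
      start <- blk$start_pos %||% (1e6 + ((b - 1) %/% 22) * 1e8)
      ids <- sprintf("snp_b%d_%d", b, seq_len(m))
      colnames(dos) <- ids
      mats[[b]] <- dos
      annos[[b]] <- tibble(variant_id = ids, chrom = chrom,
                           pos = as.integer(start + (seq_len(m) - 1) * 5000),
                           ref_allele = "A", alt_allele = "G",
                           alt_freq = freqs, info_score = 1)
    }
    D <- do.call(cbind, mats)
    rownames(D) <- paste0(id_prefix, seq_len(n))
    geno_matrix(D, variants = dplyr::bind_rows(annos))
  })
}

#' Simulate blood cell-type proportions
#'
#' Dirichlet draws over the six Houseman-style leukocyte fractions (CD8T,
#' CD4T, NK, B, Mono, Neu); rows sum to one. Default means reproduce the
#' discovery-cohort mean composition (13.7, 21.3, 5.0, 8.3, 8.1, 43.2 percent).
#'
#' @param n number of samples.
#' @param means length-6 fractions summing to ~1 (renormalised internally).
#' @param concentration Dirichlet concentration; larger = less between-sample
#'   variability (30 gives realistic spreads).
#' @param seed integer seed.
#' @return Tibble with columns CD8T, CD4T, NK, B, Mono, Neu.
#' @export
simulate_cell_proportions <- function(n,
                                      means = c(13.7, 21.3, 5.0, 8.3, 8.1, 43.2) / 100,
                                      concentration = 30, seed = NULL) {
  stopifnot(length(means) == 6, all(means > 0))
  means <- means / sum(means)
  with_seed(seed, {
    g <- matrix(rgamma(n * 6, shape = rep(means * concentration, each = n)), n, 6)
    g <- g / rowSums(g)
    colnames(g) <- cell_prop_cols
    as_tibble(g)
  })
}

#' Simulate methylation M-values from genotypes and ground truth
#'
#' M_ij = intercept_j + sum_k gamma_jk * dosage_ik + covariate effects +
#' N(0, noise_sd^2). When `drift` is supplied, a second time point is
#' generated as the time-1 values plus N(drift_j, drift_sd^2) per CpG,
#' emulating methylation re-profiled years later.
#'
#' @param G a `geno_matrix`; every truth meQTL variant must be present.
#' @param truth a [truth_record()] whose `meqtl` tibble defines the SNP->CpG
#'   effects.
#' @param probes probe annotation tibble (`probe_id`, `chrom`, `pos`); probes
#'   without meQTL entries are pure noise.
#' @param covars optional tibble of covariates aligned to `G`'s samples.
#' @param covar_effects named list mapping covariate column to a per-probe
#'   common linear effect (numeric scalar).
#' @param noise_sd residual SD on the M scale (> 0).
#' @param intercepts per-probe intercepts (recycled); default 2 (beta ~ 0.8).
#' @param drift optional named numeric of per-probe M drift (names =
#'   probe ids; probes absent default to 0); triggers a second time point.
#' @param drift_sd SD of the per-sample drift noise.
#' @param seed integer seed.
#' @return A list with elements `t1` (and `t2` when `drift` is non-NULL),
#'   each a `methyl_matrix` on the M scale.
#' @export
simulate_methylation <- function(G, truth, probes, covars = NULL,
                                 covar_effects = NULL, noise_sd = 1,
                                 intercepts = 2, drift = NULL, drift_sd = 0.1,
                                 seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  probes <- validate_probe_annotation(probes)
  missing <- setdiff(truth$meqtl$variant_id, colnames(G$dosages))
  if (length(missing) > 0) {
    abort(sprintf("truth meQTL variants absent from genotypes: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  n <- nrow(G$dosages)
  J <- nrow(probes)
  intercepts <- rep_len(intercepts, J)
  with_seed(seed, {
    M <- matrix(rnorm(n * J, sd = noise_sd), n, J)
    M <- sweep(M, 2, intercepts, "+")
    colnames(M) <- probes$probe_id
    rownames(M) <- rownames(G$dosages)
    if (nrow(truth$meqtl) > 0) {
      for (k in seq_len(nrow(truth$meqtl))) {
        pid <- truth$meqtl$probe_id[k]
        if (!pid %in% probes$probe_id) next
        M[, pid] <- M[, pid] +
          truth$meqtl$gamma[k] * G$dosages[, truth$meqtl$variant_id[k]]
      }
    }
    if (!is.null(covar_effects) && !is.null(covars)) {
      for (cv in names(covar_effects)) {
        v <- covars[[cv]]
        if (is.logical(v) || is.character(v)) v <- as.numeric(factor(v)) - 1
        M <- M + covar_effects[[cv]] * v
      }
    }
    out <- list(t1 = methyl_matrix(M, probes = probes, scale = "m_value",
                                   time_point = 1L))
    if (!is.null(drift)) {
      d <- setNames(rep(0, J), probes$probe_id)
      d[names(drift)] <- drift
      M2 <- M + matrix(rnorm(n * J, sd = drift_sd), n, J) +
        matrix(d, n, J, byrow = TRUE)
      out$t2 <- methyl_matrix(M2, probes = probes, scale = "m_value",
                              time_point = 2L)
    }
    out
  })
}

#' Classify type 2 diabetes status
#'
#' Fasting plasma glucose >= 7.0 mmol/l, physician diagnosis, or use of
#' glucose-lowering medication.
#'
#' @param fasting_glucose mmol/l.
#' @param t2d_med_use logical.
#' @param diagnosed logical (self-reported physician diagnosis).
#' @return Logical vector.
#' @export
classify_t2d <- function(fasting_glucose, t2d_med_use = FALSE, diagnosed = FALSE) {
  (fasting_glucose >= 7.0) | (t2d_med_use %in% TRUE) | (diagnosed %in% TRUE)
}

#' Simulate phenotypes from the liability model
#'
#' Disease liability L_i = alpha + sum_j theta_j M_ij + sum pleiotropy_k
#' dosage_ik, with alpha solved so that mean disease probability equals the
#' target prevalence; T2D ~ Bernoulli(plogis(L)). Fasting glucose is affine in
#' L with standard-logistic noise, glucose = 7 + s(L + epsilon), so that the
#' >= 7.0 mmol/l rule reproduces the Bernoulli label in expectation exactly.
#' HbA1c is affine in glucose; follow-up HbA1c adds `lambda_follow` times the
#' centred causal methylation burden. HOMA indices use the classic
#' approximations HOMA-IR = glucose * insulin_mU / 22.5, HOMA-S = 100/HOMA-IR,
#' HOMA-B = 20 * insulin_mU / (glucose - 3.5); glucose draws <= 3.6 are
#' resampled (bounded retries) to keep the HOMA-B denominator positive.
#'
#' @param G a `geno_matrix` (for pleiotropic direct effects).
#' @param M a `methyl_matrix` (M scale) for the same samples.
#' @param truth a [truth_record()].
#' @param covars optional tibble of pre-simulated covariates (age, sex, cell
#'   proportions, ...) merged into the result.
#' @param prevalence target disease prevalence in this cohort.
#' @param treated_fraction fraction of cases flagged as on glucose-lowering
#'   medication.
#' @param glucose_scale `s` above (mmol/l per liability unit).
#' @param seed integer seed.
#' @return Phenotype tibble with `sample_id`, `t2d_status`, `t2d_med_use`,
#'   `fasting_glucose`, `insulin`, `hba1c`, `hba1c_followup`, `homa_s`,
#'   `homa_b` plus any `covars` columns.
#' @export
simulate_phenotypes <- function(G, M, truth, covars = NULL, prevalence = 0.047,
                                treated_fraction = 0, glucose_scale = 0.5,
                                seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"), inherits(M, "methyl_matrix"))
  n <- nrow(M$values)
  eta <- rep(0, n)
  th <- truth$theta
  for (pid in names(th)) {
    if (pid %in% colnames(M$values)) eta <- eta + th[[pid]] * M$values[, pid]
  }
  if (nrow(truth$pleiotropy) > 0) {
    for (k in seq_len(nrow(truth$pleiotropy))) {
      vid <- truth$pleiotropy$variant_id[k]
      if (vid %in% colnames(G$dosages)) {
        eta <- eta + truth$pleiotropy$alpha[k] * G$dosages[, vid]
      }
    }
  }
  f <- function(a) mean(plogis(a + eta)) - prevalence
  alpha <- uniroot(f, c(-50, 50), tol = 1e-10)$root
  L <- alpha + eta
  with_seed(seed, {
    t2d <- rbinom(n, 1, plogis(L)) == 1
    glucose <- 7 + glucose_scale * (L + stats::rlogis(n))
    for (try in 1:25) {
      low <- glucose <= 3.6
      if (!any(low)) break
      glucose[low] <- 7 + glucose_scale * (L[low] + stats::rlogis(sum(low)))
    }
    if (any(glucose <= 3.6)) {
      abort("could not draw fasting glucose > 3.6 mmol/l after bounded retries")
    }
    Lz <- if (stats::sd(L) > 0) (L - mean(L)) / stats::sd(L) else rep(0, n)
    insulin <- exp(log(60) + 0.25 * Lz + rnorm(n, sd = 0.4)) # pmol/l
    insulin_mu <- insulin / 6
    homa_ir <- glucose * insulin_mu / 22.5
    homa_s <- 100 / homa_ir
    homa_b <- 20 * insulin_mu / (glucose - 3.5)
    hba1c <- 36 + 6 * (glucose - 5.5) + rnorm(n, sd = 2)
    burden <- rep(0, n)
    for (pid in names(th)) {
      if (pid %in% colnames(M$values)) {
        burden <- burden + th[[pid]] * (M$values[, pid] - mean(M$values[, pid]))
      }
    }
    hba1c_follow <- hba1c + truth$lambda_follow * burden + rnorm(n, sd = 2)
    med <- t2d & (runif(n) < treated_fraction)
    out <- tibble(sample_id = rownames(M$values),
                  t2d_status = t2d, t2d_med_use = med,
                  fasting_glucose = glucose, insulin = insulin,
                  hba1c = hba1c, hba1c_followup = hba1c_follow,
                  homa_s = homa_s, homa_b = homa_b)
    if (!is.null(covars)) out <- dplyr::bind_cols(out, as_tibble(covars))
    out
  })
}

#' Simulate gene expression with cis/trans eQTM structure
#'
#' expr_ig = a_g + b_g * M_i,cpg(g) + N(0, noise_sd^2); each gene is anchored
#' at a configured signed offset from its CpG, so the cis/trans classification
#' of the eQTM stage can be exercised on known geometry.
#'
#' @param M a `methyl_matrix` (M scale).
#' @param cpg_gene_pairs tibble with `gene_id`, `probe_id`, `b` (expression
#'   units per M-unit) and `offset_bp` (gene TSS minus probe position; sign
#'   gives direction, magnitude > 1 Mb makes the pair trans).
#' @param intercepts per-gene expression intercepts (recycled).
#' @param noise_sd residual SD.
#' @param seed integer seed.
#' @return An `expr_matrix` with TSS annotation derived from the probe
#'   positions plus the offsets.
#' @export
simulate_expression <- function(M, cpg_gene_pairs, intercepts = 5,
                                noise_sd = 1, seed = NULL) {
  stopifnot(inherits(M, "methyl_matrix"))
  pairs <- as_tibble(cpg_gene_pairs)
  stopifnot(all(c("gene_id", "probe_id", "b", "offset_bp") %in% names(pairs)))
  missing <- setdiff(pairs$probe_id, colnames(M$values))
  if (length(missing) > 0) abort("cpg_gene_pairs reference unknown probes")
  n <- nrow(M$values)
  g <- nrow(pairs)
  intercepts <- rep_len(intercepts, g)
  with_seed(seed, {
    E <- matrix(rnorm(n * g, sd = noise_sd), n, g)
    for (k in seq_len(g)) {
      E[, k] <- E[, k] + intercepts[k] + pairs$b[k] * M$values[, pairs$probe_id[k]]
    }
    colnames(E) <- pairs$gene_id
    rownames(E) <- rownames(M$values)
    pr <- M$probes[match(pairs$probe_id, M$probes$probe_id), ]
    genes <- tibble(gene_id = pairs$gene_id, chrom = pr$chrom,
                    tss = as.integer(pr$pos + pairs$offset_bp), strand = "+")
    expr_matrix(E, genes = genes)
  })
}

# Demographic / technical covariates for one cohort.
simulate_covariates <- function(n, sites = "site1", n_plates = 4,
                                age_mean = 50, seed = NULL) {
  with_seed(seed, {
    cp <- simulate_cell_proportions(n)
    tibble(age = pmax(25, rnorm(n, age_mean, 12)),
           sex = ifelse(runif(n) < 0.62, "female", "male"),
           site = sample(sites, n, replace = TRUE),
           bmi = pmax(16, rnorm(n, 27, 5.5)),
           waist = pmax(55, rnorm(n, 92, 12)),
           hip = pmax(65, rnorm(n, 102, 11)),
           smoker = runif(n) < 0.03,
           plate = sample(paste0("plate", seq_len(n_plates)), n, replace = TRUE)) |>
      dplyr::bind_cols(cp)
  })
}

#' Simulate a complete two-cohort study
#'
#' Generates the full input set the analysis pipeline expects: a discovery
#' cohort (methylation at two time points + phenotypes; multi-site, low
#' disease prevalence), a meQTL cohort (genotypes + methylation + phenotypes;
#' single site, case-enriched), a disjoint outcome-GWAS cohort (genotypes +
#' phenotypes) and a small expression subset, with the shared ground truth
#' recorded. Defaults mirror the source study conditions: cohort sizes
#' 879 / 606 / 4120, prevalences 4.7% / 46.2% / 48.7%, and about 2,000 probes
#' with block-correlated variants (a desk-scale stand-in for an 850k array).
#'
#' @param n_discovery,n_meqtl,n_gwas cohort sample sizes.
#' @param n_probes number of CpG probes.
#' @param n_blocks,variants_per_block LD-block layout (total variants =
#'   product).
#' @param block_r within-block latent correlation.
#' @param n_causal number of CpGs given nonzero causal effect `theta`.
#' @param theta causal log-OR per M-unit for causal CpGs (recycled).
#' @param instruments_per_cpg independent cis meQTLs per causal CpG.
#' @param gamma meQTL effect (M-units per allele, recycled over instruments).
#' @param maf allele-frequency range for simulated variants.
#' @param prevalence named numeric (discovery, meqtl, gwas).
#' @param drift_sd per-sample SD of the time-2 methylation drift.
#' @param lambda_follow follow-up HbA1c coupling (see
#'   [simulate_phenotypes()]).
#' @param n_expression expression subset size; one cis (0.5 Mb) and one trans
#'   (1.94 Mb) gene are attached to the first causal CpG.
#' @param expression_b eQTM effect for the cis gene.
#' @param seed master integer seed, deterministically forked per stage.
#' @return List with `discovery` (meth_t1, meth_t2, pheno), `meqtl` (geno,
#'   meth, pheno), `gwas` (geno, pheno), `expression` (expr, pheno),
#'   `probes`, `truth`.
#' @export
simulate_cohort <- function(n_discovery = 879, n_meqtl = 606, n_gwas = 4120,
                            n_probes = 2000, n_blocks = 60,
                            variants_per_block = 10, block_r = 0.7,
                            n_causal = 4, theta = log(0.76),
                            instruments_per_cpg = 3, gamma = 0.5,
                            maf = c(0.1, 0.4),
                            prevalence = c(discovery = 0.047, meqtl = 0.462,
                                           gwas = 0.487),
                            drift_sd = 0.1, lambda_follow = 2,
                            n_expression = 55, expression_b = -0.366,
                            seed = 1L) {
  seeds <- fork_seeds(seed, 12)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    list(n_variants = variants_per_block, freq = maf, r = block_r,
         chrom = as.character((b - 1) %% 22 + 1),
         start_pos = 1e6 + ((b - 1) %/% 22) * 3e6)
  })
  G_disc <- simulate_genotypes(n_discovery, blocks, seed = seeds[1],
                               id_prefix = "disc_")
  G_meqtl <- simulate_genotypes(n_meqtl, blocks, seed = seeds[2],
                                id_prefix = "meqtl_")
  G_gwas <- simulate_genotypes(n_gwas, blocks, seed = seeds[3],
                               id_prefix = "gwas_")
  # Probes: place each causal CpG near the middle of its own block so its
  # instruments are cis; remaining probes spread over the same regions.
  vr <- G_meqtl$variants
  causal_blocks <- seq_len(n_causal)
  causal_probes <- tibble(
    probe_id = sprintf("cg%07d", seq_len(n_causal)),
    chrom = vapply(causal_blocks, function(b) vr$chrom[(b - 1) * variants_per_block + 1],
                   character(1)),
    pos = vapply(causal_blocks, function(b) {
      as.integer(vr$pos[(b - 1) * variants_per_block + 1] + 101)
    }, integer(1)),
    gene_label = NA_character_)
  n_null <- n_probes - n_causal
  null_blocks <- ((seq_len(n_null) - 1) %% n_blocks) + 1
  null_probes <- tibble(
    probe_id = sprintf("cg%07d", n_causal + seq_len(n_null)),
    chrom = vr$chrom[(null_blocks - 1) * variants_per_block + 1],
    pos = as.integer(vr$pos[(null_blocks - 1) * variants_per_block + 1] +
                       30000 + seq_len(n_null) * 7L),
    gene_label = NA_character_)
  probes <- dplyr::bind_rows(causal_probes, null_probes)
  theta_vec <- setNames(rep_len(theta, n_causal), causal_probes$probe_id)
  gamma_vec <- rep_len(gamma, instruments_per_cpg)
  meqtl_truth <- purrr::map_dfr(seq_len(n_causal), function(j) {
    b <- causal_blocks[j]
    # spread instruments across distinct latent sub-positions of the block
    idx <- (b - 1) * variants_per_block +
      unique(round(seq(1, variants_per_block, length.out = instruments_per_cpg)))
    tibble(probe_id = causal_probes$probe_id[j],
           variant_id = vr$variant_id[idx[seq_len(instruments_per_cpg)]],
           gamma = gamma_vec)
  })
  # modest M-scale drift at time 2 (~0.1-0.3% on the beta scale near beta 0.8)
  drift <- setNames(-c(0.03, rep(0.01, n_causal - 1))[seq_len(n_causal)],
                    causal_probes$probe_id)
  truth <- truth_record(theta = theta_vec, meqtl = meqtl_truth,
                        prevalence = prevalence, drift = drift,
                        lambda_follow = lambda_follow)
  cov_disc <- simulate_covariates(n_discovery,
                                  sites = c("rural", "urban", "amsterdam"),
                                  age_mean = 47, seed = seeds[4])
  cov_meqtl <- simulate_covariates(n_meqtl, sites = "ibadan", age_mean = 57,
                                   seed = seeds[5])
  cov_gwas <- simulate_covariates(n_gwas, sites = c("ghana", "nigeria"),
                                  age_mean = 50, seed = seeds[6])
  meth_disc <- simulate_methylation(G_disc, truth, probes, covars = cov_disc,
                                    covar_effects = list(age = 0.002),
                                    drift = drift, drift_sd = drift_sd,
                                    seed = seeds[7])
  meth_meqtl <- simulate_methylation(G_meqtl, truth, probes,
                                     covars = cov_meqtl,
                                     covar_effects = list(age = 0.002),
                                     seed = seeds[8])
  meth_gwas <- simulate_methylation(G_gwas, truth, probes[seq_len(n_causal), ],
                                    seed = seeds[9])
  ph_disc <- simulate_phenotypes(G_disc, meth_disc$t1, truth, covars = cov_disc,
                                 prevalence = prevalence[["discovery"]],
                                 treated_fraction = 0, seed = seeds[10])
  ph_meqtl <- simulate_phenotypes(G_meqtl, meth_meqtl$t1, truth,
                                  covars = cov_meqtl,
                                  prevalence = prevalence[["meqtl"]],
                                  treated_fraction = 0.45, seed = seeds[11])
  ph_gwas <- simulate_phenotypes(G_gwas, meth_gwas$t1, truth, covars = cov_gwas,
                                 prevalence = prevalence[["gwas"]],
                                 treated_fraction = 0.46, seed = seeds[12])
  expr_idx <- seq_len(min(n_expression, n_meqtl))
  pairs <- tibble(gene_id = c("gene_cis1", "gene_trans1"),
                  probe_id = causal_probes$probe_id[1],
                  b = c(expression_b, 0),
                  offset_bp = c(5e5, 1.94e6))
  Msub <- methyl_matrix(meth_meqtl$t1$values[expr_idx, , drop = FALSE],
                        probes = probes, scale = "m_value")
  expr <- simulate_expression(Msub, pairs, seed = seeds[1] + 1L)
  list(discovery = list(meth_t1 = meth_disc$t1, meth_t2 = meth_disc$t2,
                        pheno = ph_disc),
       meqtl = list(geno = G_meqtl, meth = meth_meqtl$t1, pheno = ph_meqtl),
       gwas = list(geno = G_gwas, pheno = ph_gwas),
       expression = list(expr = expr,
                         pheno = ph_meqtl[expr_idx, , drop = FALSE]),
       probes = probes, truth = truth)
}

#' Simulate one two-sample MR study and fit both sides
#'
#' Convenience wrapper used for calibration and recovery experiments: draws an
#' exposure sample (genotypes + methylation at one CpG), maps its cis meQTLs,
#' clumps them into independent instruments, draws a disjoint outcome sample
#' whose disease liability runs through the same (unmeasured) methylation, and
#' fits the per-variant outcome log-ORs by logistic regression.
#'
#' @param n_exposure,n_outcome sample sizes of the two (disjoint) samples.
#' @param gamma numeric vector of true SNP->CpG effects, one per instrument
#'   (each instrument lives in its own LD block, so instruments are
#'   independent).
#' @param theta true causal log-OR per M-unit.
#' @param pleiotropy direct per-allele log-OR on the outcome shared by all
#'   instruments (0 = valid instruments).
#' @param maf allele frequency of the instruments.
#' @param noise_sd methylation residual SD.
#' @param prevalence outcome-cohort disease prevalence.
#' @param seed integer seed.
#' @return List with `instruments` (an [instrument_set()]), `outcome`
#'   (an `outcome_assoc` tibble: `variant_id`, `Gamma`, `se_Gamma`) and
#'   `truth`.
#' @export
simulate_mr_study <- function(n_exposure = 600, n_outcome = 4000,
                              gamma = c(0.5, 0.5, 0.5), theta = 0,
                              pleiotropy = 0, maf = 0.3, noise_sd = 1,
                              prevalence = 0.3, seed = NULL) {
  J <- length(gamma)
  blocks <- lapply(seq_len(J), function(b) {
    list(n_variants = 1, freq = maf, r = 0, chrom = "1",
         start_pos = 1e6 + (b - 1) * 3e4)
  })
  seeds <- if (is.null(seed)) rep(list(NULL), 4) else as.list(fork_seeds(seed, 4))
  G_exp <- simulate_genotypes(n_exposure, blocks, seed = seeds[[1]],
                              id_prefix = "exp_")
  vids <- G_exp$variants$variant_id
  probes <- tibble(probe_id = "cg_target", chrom = "1",
                   pos = as.integer(min(G_exp$variants$pos) + 137L),
                   gene_label = NA_character_)
  truth <- truth_record(
    theta = c(cg_target = theta),
    meqtl = tibble(probe_id = "cg_target", variant_id = vids, gamma = gamma),
    pleiotropy = if (pleiotropy != 0) {
      tibble(variant_id = vids, alpha = pleiotropy)
    } else NULL,
    prevalence = c(outcome = prevalence))
  M_exp <- simulate_methylation(G_exp, truth, probes, noise_sd = noise_sd,
                                seed = seeds[[2]])$t1
  pheno_exp <- tibble(sample_id = rownames(G_exp$dosages))
  meqtl <- map_cis_meqtls(G_exp, M_exp, pheno_exp, window_bp = 2e6,
                          covariates = character())
  clumps <- clump(meqtl, G_exp)
  instr <- instrument_set("cg_target", meqtl, clumps, n = n_exposure)
  G_out <- simulate_genotypes(n_outcome, blocks, seed = seeds[[3]],
                              id_prefix = "out_")
  seeds4 <- seeds[[4]]
  M_out <- simulate_methylation(G_out, truth, probes, noise_sd = noise_sd,
                                seed = if (is.null(seeds4)) NULL else seeds4)$t1
  pheno_out <- simulate_phenotypes(G_out, M_out, truth,
                                   prevalence = prevalence,
                                   seed = if (is.null(seeds4)) NULL else seeds4 + 1L)
  gwas <- run_outcome_gwas(G_out, pheno_out,
                           spec = model_spec("t2d_status",
                                             family = "binomial-logit"),
                           exposure_ids = rownames(G_exp$dosages))
  outcome <- outcome_assoc(gwas)
  list(instruments = instr, outcome = outcome, truth = truth)
}
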