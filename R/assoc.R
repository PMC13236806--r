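# Covariate-adjusted association machinery shared by the EWAS, meQTL, GWAS
# and eQTM stages. Per-unit fits are ordinary least squares or maximum-
# likelihood logistic regression; the matrix stages use the
# Frisch-Waugh-Lovell residualisation identity, which reproduces the per-unit
# OLS estimates and standard errors exactly while scaling to thousands of
# units (verified against lm() in the test suite).

#' Convert beta-values to M-values and back
#'
#' M = log2(beta / (1 - beta)); beta = 2^M / (2^M + 1). Beta-values are the
#' methylated fraction in \[0,1\]; M-values are the statistical modelling
#' scale. Betas are clipped to \[1e-6, 1 - 1e-6\] before conversion so that
#' fully (un)methylated probes map to large finite M rather than +/-Inf.
#'
#' @param beta numeric vector of methylation fractions in \[0,1\].
#' @return `mvalue_from_beta`: M-values; `beta_from_mvalue`: beta-values.
#' @export
mvalue_from_beta <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("beta values must lie in [0,1]")
  }
  b <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  log2(b / (1 - b))
}

#' @param m numeric vector of M-values.
#' @rdname mvalue_from_beta
#' @export
beta_from_mvalue <- function(m) {
  2^m / (2^m + 1)
}

#' Specify an association model
#'
#' @param response phenotype column name (for the EWAS/GWAS stages) to regress
#'   on each unit.
#' @param covariates character vector of phenotype-table column names;
#'   categorical columns are expanded to indicator contrasts. If all six cell
#'   proportion columns (CD8T, CD4T, NK, B, Mono, Neu) are listed, the
#'   neutrophil column is dropped before fitting: the proportions sum to one,
#'   so keeping all six would make the design rank deficient.
#' @param family `"gaussian"` (OLS), `"binomial-logit"` (ML logistic) or
#'   `"gaussian-on-binary"` (OLS on a 0/1 response, mirroring linear-model
#'   GWAS/EWAS of binary disease status).
#' @param transform `"identity"` or `"log"` (natural log; requires a positive
#'   response, used for HOMA-S, HOMA-B and HbA1c).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, covariates = character(),
                       family = c("gaussian", "binomial-logit",
                                  "gaussian-on-binary"),
                       transform = c("identity", "log")) {
  structure(list(response = response, covariates = covariates,
                 family = match.arg(family), transform = match.arg(transform)),
            class = "model_spec")
}

# Build the covariate design matrix (with intercept) from the phenotype table.
# Drops Neu when the full compositional cell-proportion set is requested.
covariate_design <- function(pheno, covariates) {
  covariates <- unique(covariates)
  if (all(cell_prop_cols %in% covariates)) {
    covariates <- setdiff(covariates, "Neu")
  }
  missing <- setdiff(covariates, names(pheno))
  if (length(missing) > 0) {
    abort(sprintf("covariates not in phenotype table: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(covariates) == 0) {
    C <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
    return(C)
  }
  df <- as.data.frame(pheno[, covariates, drop = FALSE])
  for (col in names(df)) {
    if (is.character(df[[col]]) || is.logical(df[[col]])) {
      df[[col]] <- factor(df[[col]])
    }
  }
  # constant columns (e.g. a single recruitment site) carry no information
  # and break contrast construction; drop them
  constant <- vapply(df, function(v) length(unique(v[!is.na(v)])) < 2, logical(1))
  df <- df[, !constant, drop = FALSE]
  if (ncol(df) == 0) {
    return(matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(~ ., data = stats::model.frame(~ ., df, na.action = stats::na.pass))
}

response_vector <- function(pheno, spec) {
  y <- pheno[[spec$response]]
  if (is.null(y)) abort(sprintf("response '%s' not in phenotype table", spec$response))
  if (is.logical(y)) y <- as.numeric(y)
  if (is.character(y)) abort(sprintf("response '%s' is not numeric", spec$response))
  if (spec$transform == "log") {
    if (any(y <= 0, na.rm = TRUE)) {
      abort("log transform requires a strictly positive response")
    }
    y <- log(y)
  }
  y
}

#' Fit one unit-level association
#'
#' Regresses the response on a single unit (a probe's M-values or a variant's
#' dosages) plus covariates. Gaussian families use OLS with two-sided t
#' p-values; `binomial-logit` uses ML logistic regression with Wald z.
#'
#' @param predictor numeric vector aligned with the rows of `pheno` (one value
#'   per sample).
#' @param pheno phenotype/covariate tibble.
#' @param spec a [model_spec()].
#' @param min_cases minimum complete cases beyond the parameter count
#'   (default 5).
#' @return One-row tibble: `beta`, `se`, `p`, `n`, `flag` (`NA` or
#'   `"zero_variance"` when the predictor is constant, in which case the
#'   estimate columns are `NA` rather than an error).
#' @export
fit_unit_association <- function(predictor, pheno, spec, min_cases = 5) {
  y <- response_vector(pheno, spec)
  C <- covariate_design(pheno, spec$covariates)
  keep <- complete.cases(cbind(y, predictor, C))
  y <- y[keep]; x <- predictor[keep]; C <- C[keep, , drop = FALSE]
  p_par <- ncol(C) + 1
  if (length(y) < p_par + min_cases) {
    abort(sprintf("too few complete cases (%d) for %d parameters",
                  length(y), p_par))
  }
  if (var(x) == 0) {
    return(tibble(beta = NA_real_, se = NA_real_, p = NA_real_,
                  n = length(y), flag = "zero_variance"))
  }
  X <- cbind(x = x, C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    abort(sprintf("rank-deficient design; collinear columns: %s",
                  paste(drop_cols, collapse = ", ")))
  }
  if (spec$family %in% c("gaussian", "gaussian-on-binary")) {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- length(y) - ncol(X)
    XtXinv <- chol2inv(qr.R(qx))
    se <- sqrt(rss / df * XtXinv[1, 1])
    beta <- fit$coefficients[["x"]]
    pval <- 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE)
  } else {
    if (!all(y %in% c(0, 1))) abort("binomial-logit requires a 0/1 response")
    fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
    pp <- ncol(X)
    covmat <- chol2inv(fit$qr$qr[seq_len(pp), seq_len(pp), drop = FALSE])
    beta <- fit$coefficients[["x"]]
    se <- sqrt(covmat[1, 1])
    pval <- 2 * pnorm(abs(beta / se), lower.tail = FALSE)
  }
  tibble(beta = beta, se = se, p = pval, n = length(y), flag = NA_character_)
}

# Residualise the columns of Y on the design C (complete rows assumed).
residualize <- function(Y, C) {
  qc <- qr(C)
  Y - qr.fitted(qc, Y)
}

# Vectorised per-column OLS of a fixed response on each column of M, given
# covariates C (with intercept). Frisch-Waugh-Lovell; exact OLS.
ols_fixed_response <- function(y, M, C) {
  q <- qr(C)
  yr <- y - qr.fitted(q, y)
  Mr <- M - qr.fitted(q, M)
  ssm <- colSums(Mr^2)
  # columns with (numerically) no variation left after projection carry no
  # information; sweeping out the intercept alone bounds the total variation
  ss0 <- colSums(sweep(M, 2, colMeans(M))^2)
  zero <- !is.finite(ssm) | ss0 <= 0 | ssm <= 1e-10 * ss0
  ssm[zero] <- NA_real_
  slope <- colSums(Mr * yr) / ssm
  df <- length(y) - ncol(C) - 1
  sse <- sum(yr^2) - slope^2 * ssm
  sse <- pmax(sse, 0)
  se <- sqrt(sse / df / ssm)
  p <- 2 * stats::pt(abs(slope / se), df, lower.tail = FALSE)
  tibble(beta = slope, se = se, p = p, n = length(y),
         flag = ifelse(zero, "zero_variance", NA_character_))
}

#' Run an epigenome-wide association study
#'
#' One covariate-adjusted regression of the trait on each probe's M-values.
#' Samples of participants on glucose-lowering medication are excluded first
#' (methylation signatures of treated disease would otherwise contaminate the
#' discovery EWAS); analysis is complete-case per probe. The genomic inflation
#' factor lambda over all probe p-values is attached as attribute `"lambda"`,
#' and probes skipped for zero variance as attribute `"flagged"`.
#'
#' @param M a `methyl_matrix` (M-value scale recommended; beta-scale input is
#'   converted with [mvalue_from_beta()]).
#' @param pheno phenotype tibble with `sample_id` matching `M`'s samples.
#' @param spec a [model_spec()]; default gaussian-on-binary on `t2d_status`
#'   with the discovery covariates (age, sex, site, cell proportions, BMI,
#'   plate, intersected with available columns).
#' @param exclude_medicated drop samples with `t2d_med_use == TRUE` first.
#' @param exclude_ids further sample ids to drop.
#' @param trait,cohort labels stored in the result.
#' @return An [assoc_table()], one row per probe, plus a `q` column
#'   (Benjamini-Hochberg FDR across probes).
#' @export
run_ewas <- function(M, pheno, spec = NULL, exclude_medicated = TRUE,
                     exclude_ids = NULL, trait = NULL, cohort = "cohort") {
  stopifnot(inherits(M, "methyl_matrix"))
  if (is.null(spec)) {
    covs <- intersect(c("age", "sex", "site", cell_prop_cols, "bmi", "plate"),
                      names(pheno))
    spec <- model_spec("t2d_status", covariates = covs,
                       family = "gaussian-on-binary")
  }
  trait <- trait %||% spec$response
  pheno <- dplyr::filter(pheno, .data$sample_id %in% rownames(M$values))
  if (exclude_medicated && "t2d_med_use" %in% names(pheno)) {
    pheno <- dplyr::filter(pheno, !(.data$t2d_med_use %in% TRUE))
  }
  if (!is.null(exclude_ids)) {
    pheno <- dplyr::filter(pheno, !.data$sample_id %in% exclude_ids)
  }
  vals <- M$values[pheno$sample_id, , drop = FALSE]
  if (M$scale == "beta_value") vals <- mvalue_from_beta(vals)
  y <- response_vector(pheno, spec)
  if (spec$family %in% c("binomial-logit", "gaussian-on-binary") &&
      all(unique(y[!is.na(y)]) %in% c(0, 1))) {
    if (length(unique(y[!is.na(y)])) < 2) {
      abort("fewer than 2 phenotype classes after exclusions")
    }
  }
  C <- covariate_design(pheno, spec$covariates)
  base_keep <- complete.cases(cbind(y, C))
  res <- vector("list", 1)
  full <- base_keep & rowSums(is.na(vals)) == 0
  # Fast path: probes with no missing values among phenotype-complete samples
  # share one design; remaining probes are fitted one at a time.
  probe_missing <- colSums(is.na(vals[base_keep, , drop = FALSE])) > 0
  out <- matrix(NA_real_, ncol(vals), 4,
                dimnames = list(colnames(vals), c("beta", "se", "p", "n")))
  flag <- rep(NA_character_, ncol(vals))
  if (spec$family == "binomial-logit") {
    sub <- pheno[base_keep, , drop = FALSE]
    for (j in seq_len(ncol(vals))) {
      r <- fit_unit_association(vals[base_keep, j], sub, spec)
      out[j, ] <- c(r$beta, r$se, r$p, r$n); flag[j] <- r$flag
    }
  } else {
    if (any(!probe_missing)) {
      idx <- which(!probe_missing)
      r <- ols_fixed_response(y[base_keep], vals[base_keep, idx, drop = FALSE],
                              C[base_keep, , drop = FALSE])
      out[idx, ] <- cbind(r$beta, r$se, r$p, r$n); flag[idx] <- r$flag
    }
    sub <- pheno[base_keep, , drop = FALSE]
    for (j in which(probe_missing)) {
      r <- fit_unit_association(vals[base_keep, j], sub, spec)
      out[j, ] <- c(r$beta, r$se, r$p, r$n); flag[j] <- r$flag
    }
  }
  tab <- tibble(unit_id = rownames(out), beta = out[, "beta"],
                se = out[, "se"], p = out[, "p"], n = as.integer(out[, "n"]),
                trait = trait, cohort = cohort, flag = flag)
  flagged <- tab$unit_id[!is.na(tab$flag)]
  tab <- dplyr::filter(tab, is.na(.data$flag))
  tab$flag <- NULL
  tab$q <- bh_fdr(tab$p)
  tab <- assoc_table(tab)
  attr(tab, "lambda") <- if (nrow(tab) > 0) genomic_lambda(tab$p) else NA_real_
  attr(tab, "flagged") <- flagged
  tab
}

#' Genomic inflation factor
#'
#' lambda = median observed chi-square (1 df, from two-sided p) divided by the
#' null median 0.4549364. Values near 1 indicate well-calibrated tests;
#' inflation suggests confounding or model misspecification.
#'
#' @param p numeric vector of p-values.
#' @return lambda (positive scalar).
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) abort("no p-values supplied")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: q_(i) = min over j >= i of m * p_(j) / j, capped at 1,
#' returned in the input order. Thin wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines per-cohort association tables by unit id with weights
#' w_c = 1/se_c^2: beta = sum(w*beta)/sum(w), se = sum(w)^(-1/2) (the
#' METAL-style effect-size mode, which downstream MR requires since it needs
#' betas and SEs rather than z-scores). Cochran's Q across cohorts
#' (df = #cohorts - 1) quantifies between-cohort heterogeneity.
#'
#' @param tables list of [assoc_table()]s, one per cohort; effect alleles /
#'   probe scales must already be consistent across cohorts.
#' @return Tibble with one row per unit: `unit_id`, `beta_meta`, `se_meta`,
#'   `p_meta`, `n_total`, `direction` (one `+`/`-`/`?` per cohort),
#'   `q_meta`, `q_p`, `n_cohorts`.
#' @export
meta_fixed <- function(tables) {
  if (inherits(tables, "assoc_table")) tables <- list(tables)
  if (length(tables) == 0) abort("no cohort tables supplied")
  tables <- lapply(tables, assoc_table)
  k <- length(tables)
  units <- unique(unlist(lapply(tables, function(t) t$unit_id)))
  aligned <- lapply(tables, function(t) t[match(units, t$unit_id), ])
  beta <- vapply(aligned, function(t) t$beta, numeric(length(units)))
  se <- vapply(aligned, function(t) t$se, numeric(length(units)))
  nn <- vapply(aligned, function(t) as.numeric(t$n), numeric(length(units)))
  beta <- matrix(beta, ncol = k); se <- matrix(se, ncol = k)
  nn <- matrix(nn, ncol = k)
  if (any(se <= 0, na.rm = TRUE)) abort("meta_fixed: se must be > 0")
  w <- 1 / se^2
  w[is.na(beta)] <- NA
  sw <- rowSums(w, na.rm = TRUE)
  beta_meta <- rowSums(w * beta, na.rm = TRUE) / sw
  se_meta <- 1 / sqrt(sw)
  p_meta <- 2 * pnorm(abs(beta_meta / se_meta), lower.tail = FALSE)
  q_meta <- rowSums(w * (beta - beta_meta)^2, na.rm = TRUE)
  df <- rowSums(!is.na(beta)) - 1
  q_p <- ifelse(df > 0, pchisq(q_meta, df = pmax(df, 1), lower.tail = FALSE), NA_real_)
  direction <- apply(beta, 1, function(b) {
    paste(ifelse(is.na(b), "?", ifelse(b >= 0, "+", "-")), collapse = "")
  })
  tibble(unit_id = units, beta_meta = beta_meta, se_meta = se_meta,
         p_meta = p_meta, n_total = as.integer(rowSums(nn, na.rm = TRUE)),
         direction = direction, q_meta = q_meta, q_p = q_p,
         n_cohorts = as.integer(df + 1))
}

#' SNP-outcome genome-wide association scan
#'
#' Per-variant regression of the (binary) outcome on alternate-allele dosage
#' with covariate adjustment (age, sex, leading genetic principal components,
#' BMI in the source design). The outcome sample must be disjoint from the
#' meQTL (exposure) sample: two-sample MR is biased by sample overlap, so
#' shared ids are a hard error.
#'
#' @param G a `geno_matrix` for the outcome sample.
#' @param pheno phenotype tibble (must contain the response and covariates).
#' @param spec a [model_spec()]; default ML logistic (`binomial-logit`) of
#'   `t2d_status` on dosage with covariates intersected from
#'   age, sex, PC1-PC3, bmi. With family `"gaussian-on-binary"` the linear
#'   coefficient is converted to an approximate log-odds ratio via
#'   beta / (mu*(1-mu)) with mu the case fraction, and the result gains an
#'   `approx_logor = TRUE` column.
#' @param exposure_ids sample ids used on the exposure (meQTL) side; any
#'   overlap with `G`'s samples is an error.
#' @param trait,cohort labels stored in the result.
#' @return An [assoc_table()], one row per variant (log-OR scale).
#' @export
run_outcome_gwas <- function(G, pheno, spec = NULL, exposure_ids = NULL,
                             trait = "t2d", cohort = "outcome") {
  stopifnot(inherits(G, "geno_matrix"))
  if (!is.null(exposure_ids)) {
    overlap <- intersect(exposure_ids, rownames(G$dosages))
    if (length(overlap) > 0) {
      abort(sprintf("exposure/outcome sample overlap (%d ids, e.g. %s)",
                    length(overlap), overlap[1]))
    }
  }
  if (is.null(spec)) {
    covs <- intersect(c("age", "sex", "PC1", "PC2", "PC3", "bmi"), names(pheno))
    spec <- model_spec("t2d_status", covariates = covs, family = "binomial-logit")
  }
  pheno <- dplyr::filter(pheno, .data$sample_id %in% rownames(G$dosages))
  D <- G$dosages[pheno$sample_id, , drop = FALSE]
  approx <- spec$family == "gaussian-on-binary"
  rows <- vector("list", ncol(D))
  if (spec$family == "gaussian-on-binary") {
    y <- response_vector(pheno, spec)
    C <- covariate_design(pheno, spec$covariates)
    keep <- complete.cases(cbind(y, C)) & rowSums(is.na(D)) == 0
    fitted <- ols_fixed_response(y[keep], D[keep, , drop = FALSE],
                                 C[keep, , drop = FALSE])
    mu <- mean(y[keep])
    fitted$beta <- fitted$beta / (mu * (1 - mu))
    fitted$se <- fitted$se / (mu * (1 - mu))
    tab <- dplyr::mutate(fitted, unit_id = colnames(D), trait = trait,
                         cohort = cohort, approx_logor = TRUE)
  } else {
    for (j in seq_len(ncol(D))) {
      rows[[j]] <- fit_unit_association(D[, j], pheno, spec)
    }
    tab <- dplyr::bind_rows(rows)
    tab$unit_id <- colnames(D); tab$trait <- trait; tab$cohort <- cohort
  }
  tab <- dplyr::filter(tab, is.na(.data$flag))
  tab$flag <- NULL
  assoc_table(tab)
}
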