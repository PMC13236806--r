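# Phase-3 triangulation of CpGs flagged causal: temporal stability of
# methylation, baseline-methylation by follow-up-HbA1c tertile analysis, and
# cis/trans eQTM mapping against tissue expression.

#' Temporal stability of methylation (Bland-Altman)
#'
#' For each probe, mean methylation percentage at time points 1 and 2 over
#' the paired samples (intersection of sample ids), their difference
#' (t2 - t1) and the mean of means, plus per-probe limits of agreement
#' (mean +/- 1.96 SD of the per-sample differences). An across-probe
#' Bland-Altman summary is attached as attribute `"bland_altman"`. Stability
#' is assessed on the beta (percent) scale, the scale on which array
#' methylation is reported.
#'
#' @param M_t1,M_t2 `methyl_matrix` objects (beta or M scale; M is converted
#'   to percent beta).
#' @param probes optional probe ids to restrict to.
#' @return Tibble: `probe_id`, `mean_beta_t1`, `mean_beta_t2`, `diff`,
#'   `mean_of_means`, `sd_diff`, `loa_low`, `loa_high`, `n_pairs` (percent
#'   units).
#' @export
stability <- function(M_t1, M_t2, probes = NULL) {
  stopifnot(inherits(M_t1, "methyl_matrix"), inherits(M_t2, "methyl_matrix"))
  to_pct <- function(M) {
    v <- M$values
    if (M$scale == "m_value") v <- beta_from_mvalue(v)
    100 * v
  }
  ids <- intersect(rownames(M_t1$values), rownames(M_t2$values))
  if (length(ids) == 0) abort("no paired samples between time points")
  shared <- intersect(colnames(M_t1$values), colnames(M_t2$values))
  if (!is.null(probes)) shared <- intersect(shared, probes)
  if (length(shared) == 0) abort("no shared probes between time points")
  V1 <- to_pct(M_t1)[ids, shared, drop = FALSE]
  V2 <- to_pct(M_t2)[ids, shared, drop = FALSE]
  d <- V2 - V1
  mean_d <- unname(colMeans(d, na.rm = TRUE))
  sd_d <- unname(apply(d, 2, sd, na.rm = TRUE))
  m1 <- unname(colMeans(V1, na.rm = TRUE))
  m2 <- unname(colMeans(V2, na.rm = TRUE))
  out <- tibble(probe_id = shared,
                mean_beta_t1 = m1,
                mean_beta_t2 = m2,
                diff = m2 - m1,
                mean_of_means = (m1 + m2) / 2,
                sd_diff = sd_d,
                loa_low = mean_d - 1.96 * sd_d,
                loa_high = mean_d + 1.96 * sd_d,
                n_pairs = unname(colSums(!is.na(d))))
  attr(out, "bland_altman") <- tibble(
    mean_diff = mean(out$diff),
    loa_low = mean(out$diff) - 1.96 * sd(out$diff),
    loa_high = mean(out$diff) + 1.96 * sd(out$diff),
    n_probes = nrow(out), n_pairs = length(ids))
  out
}

#' Split values into tertiles
#'
#' Group labels 1-3 with boundaries at the empirical 1/3 and 2/3 quantiles;
#' ties are assigned to the lower tertile (minimum rank), so the groups
#' partition the sample deterministically and sizes differ by at most one
#' when values are distinct.
#'
#' @param values numeric vector (NAs keep an NA label).
#' @return Integer vector of labels in {1, 2, 3}.
#' @export
tertile_split <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0) abort("no non-missing values")
  r <- rank(values[ok], ties.method = "min")
  g <- ceiling(3 * r / n)
  g <- pmin(pmax(g, 1L), 3L)
  if (length(unique(values[ok])) == 1) {
    warn("all values equal; every sample assigned to tertile 1")
    g <- rep(1L, n)
  }
  out <- rep(NA_integer_, length(values))
  out[ok] <- as.integer(g)
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' H = 12/(N(N+1)) sum R_g^2/n_g - 3(N+1) with mid-rank ties and the standard
#' tie correction; p from chi-squared with (#groups - 1) df. Wraps
#' [stats::kruskal.test()].
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups) or a numeric
#'   vector with `labels` supplied.
#' @param labels optional group labels parallel to a vector `groups`.
#' @return Tibble with `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(groups, labels = NULL) {
  if (!is.list(groups)) {
    stopifnot(!is.null(labels))
    groups <- split(groups, labels)
  }
  groups <- groups[vapply(groups, function(g) sum(!is.na(g)) > 0, logical(1))]
  if (length(groups) < 2) abort("need >= 2 non-empty groups")
  kt <- kruskal.test(groups)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value, n = sum(lengths(groups)))
}

#' Baseline methylation by follow-up HbA1c tertile
#'
#' Categorises follow-up HbA1c into tertiles and summarises baseline
#' methylation percentage per tertile for each probe, with a Kruskal-Wallis
#' test of differing distributions — a temporality check: if methylation is
#' causally upstream, baseline methylation should differ by later glycaemia.
#'
#' @param M baseline `methyl_matrix` (converted to percent beta).
#' @param pheno phenotype tibble with `sample_id` and `hba1c_followup`.
#' @param probes probe ids to analyse (default: all in `M`).
#' @param exclude_t2d drop prevalent (untreated) T2D cases first
#'   (default FALSE: keep the full longitudinal subset).
#' @return Tibble: `probe_id`, `tertile`, `n`, `median_beta`, `q1`, `q3`,
#'   plus per-probe `H`, `df`, `p` repeated across the tertile rows.
#' @export
tertile_analysis <- function(M, pheno, probes = NULL, exclude_t2d = FALSE) {
  stopifnot(inherits(M, "methyl_matrix"))
  ph <- dplyr::filter(pheno, .data$sample_id %in% rownames(M$values),
                      !is.na(.data$hba1c_followup))
  if (exclude_t2d && "t2d_status" %in% names(ph)) {
    ph <- dplyr::filter(ph, !(.data$t2d_status %in% TRUE))
  }
  v <- M$values[ph$sample_id, , drop = FALSE]
  if (M$scale == "m_value") v <- beta_from_mvalue(v)
  v <- 100 * v
  if (is.null(probes)) probes <- colnames(v)
  tert <- tertile_split(ph$hba1c_followup)
  purrr::map_dfr(probes, function(pid) {
    x <- v[, pid]
    kw <- kruskal_wallis(x, labels = tert)
    dplyr::group_by(tibble(tertile = tert, beta = x), .data$tertile) |>
      dplyr::summarise(n = dplyr::n(),
                       median_beta = median(.data$beta, na.rm = TRUE),
                       q1 = quantile(.data$beta, 0.25, na.rm = TRUE),
                       q3 = quantile(.data$beta, 0.75, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(probe_id = pid, H = kw$H, df = kw$df, p = kw$p,
                    .before = 1)
  })
}

#' Map expression quantitative trait methylations (eQTMs)
#'
#' For each (probe, gene) combination, fits expression on methylation M-value
#' plus covariates (age, sex, medication use in the source design) by OLS,
#' classifies the pair cis (same chromosome, |TSS - probe pos| <= 1 Mb) or
#' trans, and computes Benjamini-Hochberg FDR per tissue over all tested
#' pairs. Both the FDR < 0.05 tier and a relaxed FDR < 0.2 exploratory tier
#' are flagged.
#'
#' @param M a `methyl_matrix` (M scale; beta converted).
#' @param expr an `expr_matrix` with TSS annotation.
#' @param pheno phenotype tibble.
#' @param tissue tissue label stored in the result.
#' @param covariates covariate columns (intersected with availability).
#' @param probes optional probe ids to restrict to.
#' @param cis_bp cis window around the probe (default 1 Mb).
#' @param min_n warn (but still run) below this sample size.
#' @return Tibble: `probe_id`, `gene_id`, `tissue`, `beta`, `se`, `p`, `q`,
#'   `relation` (`"cis"`/`"trans"`), `fdr05`, `fdr20`, `n`.
#' @export
eqtm_map <- function(M, expr, pheno, tissue = "blood",
                     covariates = c("age", "sex", "t2d_med_use"),
                     probes = NULL, cis_bp = 1e6, min_n = 20) {
  stopifnot(inherits(M, "methyl_matrix"), inherits(expr, "expr_matrix"))
  covariates <- intersect(covariates, names(pheno))
  ids <- intersect(rownames(M$values), rownames(expr$values))
  ids <- intersect(ids, pheno$sample_id)
  if (length(ids) < min_n) {
    warn(sprintf("eQTM sample size %d below %d; results are exploratory",
                 length(ids), min_n))
  }
  ph <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  v <- M$values[ids, , drop = FALSE]
  if (M$scale == "beta_value") v <- mvalue_from_beta(v)
  if (!is.null(probes)) v <- v[, intersect(colnames(v), probes), drop = FALSE]
  E <- expr$values[ids, , drop = FALSE]
  C <- covariate_design(ph, covariates)
  base <- complete.cases(C) & rowSums(is.na(v)) == 0 & rowSums(is.na(E)) == 0
  Cb <- C[base, , drop = FALSE]
  q <- qr(Cb)
  Mr <- v[base, , drop = FALSE] - qr.fitted(q, v[base, , drop = FALSE])
  Er <- E[base, , drop = FALSE] - qr.fitted(q, E[base, , drop = FALSE])
  ssm <- colSums(Mr^2)
  sse_tot <- colSums(Er^2)
  cp <- crossprod(Mr, Er) # probes x genes
  nb <- sum(base)
  df <- nb - ncol(Cb) - 1
  grid <- tidyr::expand_grid(probe_id = colnames(v), gene_id = colnames(E))
  ip <- match(grid$probe_id, colnames(v))
  ig <- match(grid$gene_id, colnames(E))
  slope <- unname(cp[cbind(ip, ig)] / ssm[ip])
  sse <- pmax(unname(sse_tot[ig] - slope^2 * ssm[ip]), 0)
  se <- unname(sqrt(sse / df / ssm[ip]))
  pval <- 2 * stats::pt(abs(slope / se), df, lower.tail = FALSE)
  pr <- M$probes[match(grid$probe_id, M$probes$probe_id), ]
  ge <- expr$genes[match(grid$gene_id, expr$genes$gene_id), ]
  cis <- in_cis_window(pr$chrom, pr$pos, ge$chrom, ge$tss, cis_bp)
  out <- tibble(probe_id = grid$probe_id, gene_id = grid$gene_id,
                tissue = tissue, beta = slope, se = se, p = pval,
                relation = ifelse(cis, "cis", "trans"), n = nb)
  out$q <- bh_fdr(out$p)
  out$fdr05 <- out$q < 0.05
  out$fdr20 <- out$q < 0.2
  out[, c("probe_id", "gene_id", "tissue", "beta", "se", "p", "q",
          "relation", "fdr05", "fdr20", "n")]
}
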