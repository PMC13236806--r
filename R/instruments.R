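# Phase-2 instrument construction: genotype QC, cis-meQTL mapping with
# probe-overlap exclusion, greedy LD clumping, instrument-strength (F)
# statistics, and the confounder screen.

# Exact Hardy-Weinberg test probability (two-sided, sum of genotype
# configurations no more likely than the observed one), enumerated over all
# heterozygote counts compatible with the allele counts.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2; hbb <- (n_b - h) / 2
    if (n_a <= n_b) {
      n_rare_hom <- haa; n_common_hom <- hbb
    } else {
      n_rare_hom <- hbb; n_common_hom <- haa
    }
    h * log(2) + lgamma(n + 1) - lgamma(n_rare_hom + 1) - lgamma(h + 1) -
      lgamma(n_common_hom + 1) + lgamma(n_a + 1) + lgamma(n_b + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_ab, hets)]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

#' Genotype quality control
#'
#' Removes variants failing any of: per-marker missingness above
#' `max_missing` (default 5%), minor allele frequency below `min_maf`
#' (default 1%), exact-test Hardy-Weinberg p-value at or below `hwe_p`
#' (default 1e-6; dosages are rounded to hard genotype calls for the test),
#' or imputation INFO score below `min_info` (default 0.8; variants without
#' an annotated score pass this filter). Counts removed per filter are
#' attached as attribute `"removed"`.
#'
#' @param G a `geno_matrix`.
#' @param max_missing,min_maf,hwe_p,min_info filter thresholds.
#' @return The filtered `geno_matrix`.
#' @export
qc_variants <- function(G, max_missing = 0.05, min_maf = 0.01,
                        hwe_p = 1e-6, min_info = 0.8) {
  stopifnot(inherits(G, "geno_matrix"))
  D <- G$dosages
  miss <- colMeans(is.na(D))
  af <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hard <- round(D)
  hwe <- vapply(seq_len(ncol(D)), function(j) {
    g <- hard[, j]; g <- g[!is.na(g)]
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  info <- G$variants$info_score
  fail_miss <- miss > max_missing
  fail_maf <- maf < min_maf
  fail_hwe <- !is.na(hwe) & hwe <= hwe_p
  fail_info <- !is.na(info) & info < min_info
  keep <- !(fail_miss | fail_maf | fail_hwe | fail_info)
  out <- geno_matrix(D[, keep, drop = FALSE],
                     variants = G$variants[keep, , drop = FALSE])
  attr(out, "removed") <- c(missingness = sum(fail_miss), maf = sum(fail_maf),
                            hwe = sum(fail_hwe), info = sum(fail_info))
  out
}

#' Pairwise LD as squared Pearson correlation of dosages
#'
#' @param G a `geno_matrix` (the LD reference panel).
#' @param v1,v2 variant ids.
#' @return r-squared over samples with both dosages observed.
#' @export
ld_r2 <- function(G, v1, v2) {
  d1 <- G$dosages[, v1]; d2 <- G$dosages[, v2]
  ok <- !is.na(d1) & !is.na(d2)
  suppressWarnings(stats::cor(d1[ok], d2[ok]))^2
}

# Shared interval test: is (chrom2, pos2) within `bp` of (chrom1, pos1)?
# Used by both the cis-meQTL window and the eQTM cis/trans call so the two
# stages cannot drift apart.
in_cis_window <- function(chrom1, pos1, chrom2, pos2, bp) {
  !is.na(chrom1) & !is.na(chrom2) & chrom1 == chrom2 &
    abs(as.numeric(pos2) - as.numeric(pos1)) <= bp
}

#' Map cis meQTLs
#'
#' For every (CpG, variant) pair on the same chromosome with
#' |pos_variant - pos_cpg| <= `window_bp / 2` (a `window_bp` region centred
#' on the CpG), fits methylation M-value on alternate-allele dosage plus
#' covariates by OLS and reports the additive effect. Variants overlapping
#' the CpG dinucleotide itself (position in \[pos, pos + 1\]) are excluded
#' before testing, since a polymorphism under the probe corrupts the
#' methylation measurement. Benjamini-Hochberg FDR is computed over all
#' tested pairs.
#'
#' @param G a `geno_matrix` with positional annotation.
#' @param M a `methyl_matrix` (M scale; beta input converted) with positional
#'   annotation.
#' @param pheno phenotype tibble (`sample_id` plus covariates).
#' @param window_bp total cis window size centred on the CpG (default 2 Mb,
#'   i.e. +/- 1 Mb).
#' @param covariates covariate column names (blood design: age, sex,
#'   medication use, cell proportions).
#' @param cohort label stored in the result.
#' @return An [assoc_table()] with one row per tested pair (`unit_id` =
#'   `"variant:probe"`), extra columns `variant_id`, `probe_id`, `distance`,
#'   `df`, `q`. Empty (with a warning) when no variant falls in any window.
#' @export
map_cis_meqtls <- function(G, M, pheno, window_bp = 2e6,
                           covariates = c("age", "sex", "t2d_med_use",
                                          cell_prop_cols),
                           cohort = "meqtl") {
  stopifnot(inherits(G, "geno_matrix"), inherits(M, "methyl_matrix"))
  covariates <- intersect(covariates, names(pheno))
  ids <- intersect(rownames(G$dosages), rownames(M$values))
  ids <- intersect(ids, pheno$sample_id)
  pheno <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  D <- G$dosages[ids, , drop = FALSE]
  vals <- M$values[ids, , drop = FALSE]
  if (M$scale == "beta_value") vals <- mvalue_from_beta(vals)
  vr <- G$variants; pr <- M$probes
  # candidate pairs via per-chromosome position matching
  pairs <- purrr::map_dfr(seq_len(nrow(pr)), function(j) {
    hit <- in_cis_window(pr$chrom[j], pr$pos[j], vr$chrom, vr$pos, window_bp / 2)
    overlap <- !is.na(vr$pos) & vr$chrom == pr$chrom[j] &
      vr$pos >= pr$pos[j] & vr$pos <= pr$pos[j] + 1
    hit <- hit & !overlap
    if (!any(hit)) return(NULL)
    tibble(probe_id = pr$probe_id[j], variant_id = vr$variant_id[hit],
           distance = abs(vr$pos[hit] - pr$pos[j]))
  })
  if (nrow(pairs) == 0) {
    warn("no variants fall in any cis window")
    out <- assoc_table(tibble(unit_id = character(), beta = numeric(),
                              se = numeric(), p = numeric(), n = integer(),
                              trait = character(), cohort = character()))
    return(out)
  }
  C <- covariate_design(pheno, covariates)
  base <- complete.cases(C)
  Cb <- C[base, , drop = FALSE]
  Db <- D[base, , drop = FALSE]; Vb <- vals[base, , drop = FALSE]
  n_base <- sum(base)
  used_v <- unique(pairs$variant_id); used_p <- unique(pairs$probe_id)
  clean_v <- used_v[colSums(is.na(Db[, used_v, drop = FALSE])) == 0]
  clean_p <- used_p[colSums(is.na(Vb[, used_p, drop = FALSE])) == 0]
  fast <- pairs$variant_id %in% clean_v & pairs$probe_id %in% clean_p
  res <- matrix(NA_real_, nrow(pairs), 5,
                dimnames = list(NULL, c("beta", "se", "p", "n", "df")))
  if (any(fast)) {
    q <- qr(Cb)
    Gr <- Db[, clean_v, drop = FALSE] - qr.fitted(q, Db[, clean_v, drop = FALSE])
    Mr <- Vb[, clean_p, drop = FALSE] - qr.fitted(q, Vb[, clean_p, drop = FALSE])
    ssg <- colSums(Gr^2)
    ssm <- colSums(Mr^2)
    cp <- crossprod(Gr, Mr) # variants x probes
    df <- n_base - ncol(Cb) - 1
    iv <- match(pairs$variant_id[fast], clean_v)
    ip <- match(pairs$probe_id[fast], clean_p)
    slope <- cp[cbind(iv, ip)] / ssg[iv]
    sse <- pmax(ssm[ip] - slope^2 * ssg[iv], 0)
    se <- sqrt(sse / df / ssg[iv])
    pv <- 2 * stats::pt(abs(slope / se), df, lower.tail = FALSE)
    res[fast, ] <- cbind(slope, se, pv, n_base, df)
  }
  if (any(!fast)) {
    sub <- pheno[base, , drop = FALSE]
    for (k in which(!fast)) {
      x <- Db[, pairs$variant_id[k]]
      y <- Vb[, pairs$probe_id[k]]
      ok <- !is.na(x) & !is.na(y)
      spec <- model_spec("..y", covariates = covariates, family = "gaussian")
      ph <- sub; ph$..y <- y
      r <- fit_unit_association(x, ph[ok, , drop = FALSE], spec)
      res[k, ] <- c(r$beta, r$se, r$p, r$n, r$n - ncol(Cb) - 1)
    }
  }
  zerovar <- is.na(res[, "beta"]) | !is.finite(res[, "se"]) | res[, "se"] <= 0
  tab <- tibble(unit_id = paste(pairs$variant_id, pairs$probe_id, sep = ":"),
                beta = res[, "beta"], se = res[, "se"], p = res[, "p"],
                n = as.integer(res[, "n"]), trait = "meqtl", cohort = cohort,
                variant_id = pairs$variant_id, probe_id = pairs$probe_id,
                distance = pairs$distance, df = as.integer(res[, "df"]))
  tab <- tab[!zerovar, , drop = FALSE]
  tab$q <- bh_fdr(tab$p)
  assoc_table(tab)
}

#' Greedy LD clumping
#'
#' Sorts variants by ascending p-value (ties broken by ascending position,
#' then lexicographic id, so results are deterministic); repeatedly takes the
#' best unassigned variant as a clump index and assigns every unassigned
#' variant with r-squared at or above `r2_threshold` to that clump. Clump
#' indices are mutually independent at the strict `r2 < r2_threshold` level
#' and are the variants carried forward as instruments.
#'
#' @param assoc association rows for one CpG: needs `variant_id` (or
#'   `unit_id`) and `p`.
#' @param G_ref `geno_matrix` LD reference panel containing every variant.
#' @param r2_threshold independence threshold (default 0.1).
#' @param p_threshold only variants with `p <= p_threshold` enter clumping.
#' @return Tibble with one row per clump: `index_variant`, `index_p`,
#'   `members` (list column of member variant ids, index included),
#'   `n_members`.
#' @export
clump <- function(assoc, G_ref, r2_threshold = 0.1, p_threshold = 1) {
  stopifnot(inherits(G_ref, "geno_matrix"))
  assoc <- as_tibble(assoc)
  if (!"variant_id" %in% names(assoc)) assoc$variant_id <- assoc$unit_id
  assoc <- dplyr::filter(assoc, .data$p <= p_threshold)
  if (nrow(assoc) == 0) {
    return(tibble(index_variant = character(), index_p = numeric(),
                  members = list(), n_members = integer()))
  }
  missing <- setdiff(assoc$variant_id, colnames(G_ref$dosages))
  if (length(missing) > 0) {
    abort(sprintf("variants absent from LD reference: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  pos <- G_ref$variants$pos[match(assoc$variant_id, G_ref$variants$variant_id)]
  ord <- order(assoc$p, pos, assoc$variant_id)
  vids <- assoc$variant_id[ord]
  ps <- assoc$p[ord]
  Dc <- scale(G_ref$dosages[, vids, drop = FALSE], center = TRUE, scale = FALSE)
  assigned <- rep(FALSE, length(vids))
  out <- list()
  while (!all(assigned)) {
    i <- which(!assigned)[1]
    cand <- which(!assigned)
    r2 <- vapply(cand, function(j) {
      if (j == i) return(1)
      ld_r2(G_ref, vids[i], vids[j])
    }, numeric(1))
    mem <- cand[r2 >= r2_threshold | cand == i]
    assigned[mem] <- TRUE
    out[[length(out) + 1]] <- tibble(index_variant = vids[i], index_p = ps[i],
                                     members = list(vids[mem]),
                                     n_members = length(mem))
  }
  dplyr::bind_rows(out)
}

#' Cumulative instrument-strength F statistic
#'
#' R-squared is summed over the (approximately independent, clumped)
#' instruments' marginal exposure variances explained, then
#' F = ((n - k - 1) / k) * R2 / (1 - R2) with k instruments. F > 10 is the
#' conventional weak-instrument bar for admission to MR.
#'
#' @param r2_exposure per-instrument fractions of exposure variance explained.
#' @param n exposure-sample size.
#' @return F statistic (scalar).
#' @export
cumulative_f <- function(r2_exposure, n) {
  k <- length(r2_exposure)
  if (k == 0) return(NA_real_)
  R2 <- sum(r2_exposure)
  if (R2 >= 1) abort("cumulative R-squared >= 1; marginal r2 values inconsistent")
  ((n - k - 1) / k) * (R2 / (1 - R2))
}

#' Bundle clumped meQTLs into an instrument set for one CpG
#'
#' Takes the clump indices for a CpG, pulls their SNP-exposure effects from
#' the meQTL association table, computes per-instrument exposure r-squared
#' from the marginal fit (squared partial correlation t^2 / (t^2 + df)) and
#' the cumulative F statistic.
#'
#' @param cpg probe id.
#' @param meqtl_assoc [map_cis_meqtls()] output (rows for this CpG are
#'   selected automatically when a `probe_id` column is present).
#' @param clumps [clump()] output for this CpG.
#' @param n exposure-sample size used for the F statistic.
#' @param tissue `"blood"`, `"hepatocyte"` or other label.
#' @return An `instrument_set`: list with `cpg`, `tissue`, `instruments`
#'   (tibble: `variant_id`, `gamma`, `se_gamma`, `p_gamma`, `r2_exposure`),
#'   `cumulative_F`, `n`, `screened`.
#' @export
instrument_set <- function(cpg, meqtl_assoc, clumps, n, tissue = "blood") {
  a <- as_tibble(meqtl_assoc)
  if ("probe_id" %in% names(a)) a <- dplyr::filter(a, .data$probe_id == cpg)
  if (!"variant_id" %in% names(a)) a$variant_id <- a$unit_id
  idx <- clumps$index_variant
  rows <- a[match(idx, a$variant_id), ]
  if (any(is.na(rows$beta))) abort("clump index missing from meQTL table")
  df <- if ("df" %in% names(rows)) rows$df else rows$n - 2
  tval <- rows$beta / rows$se
  inst <- tibble(variant_id = rows$variant_id, gamma = rows$beta,
                 se_gamma = rows$se, p_gamma = rows$p,
                 r2_exposure = tval^2 / (tval^2 + df))
  structure(list(cpg = cpg, tissue = tissue, instruments = inst,
                 cumulative_F = cumulative_f(inst$r2_exposure, n),
                 n = n, screened = FALSE),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> CpG %s (%s): %d instrument(s), cumulative F = %.2f%s\n",
              x$cpg, x$tissue, nrow(x$instruments), x$cumulative_F,
              if (x$screened) ", screened" else ""))
  invisible(x)
}

#' Confounder screen of MR instruments
#'
#' Tests each instrument's dosage against each candidate confounder (simple
#' linear regression for continuous confounders; logistic
#' confounder-on-dosage for binary ones) and excludes instruments with any
#' association p < `alpha`: an instrument tracking a confounder violates the
#' MR independence assumption. `relaxed = TRUE` screens on age and sex only,
#' the complementary less restrictive design.
#'
#' @param instruments an `instrument_set`.
#' @param G `geno_matrix` holding the instruments' dosages.
#' @param pheno phenotype tibble with the confounder columns.
#' @param confounders columns to screen (default age, sex, bmi, waist, hip,
#'   smoker, intersected with availability).
#' @param alpha exclusion threshold (default 0.05).
#' @param relaxed screen age/sex only.
#' @return List with `kept` (the screened `instrument_set`, F recomputed) and
#'   `excluded` (tibble: `variant_id`, `confounder`, `p`).
#' @export
screen_instruments <- function(instruments, G, pheno,
                               confounders = c("age", "sex", "bmi", "waist",
                                               "hip", "smoker"),
                               alpha = 0.05, relaxed = FALSE) {
  stopifnot(inherits(instruments, "instrument_set"), inherits(G, "geno_matrix"))
  if (relaxed) confounders <- c("age", "sex")
  confounders <- intersect(confounders, names(pheno))
  ids <- intersect(rownames(G$dosages), pheno$sample_id)
  ph <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  D <- G$dosages[ids, , drop = FALSE]
  excl <- list()
  keep <- rep(TRUE, nrow(instruments$instruments))
  for (i in seq_len(nrow(instruments$instruments))) {
    vid <- instruments$instruments$variant_id[i]
    x <- D[, vid]
    for (cf in confounders) {
      v <- ph[[cf]]
      if (is.character(v)) v <- factor(v)
      if (is.factor(v)) v <- as.numeric(v) - 1
      if (is.logical(v)) v <- as.numeric(v)
      ok <- !is.na(x) & !is.na(v)
      if (sum(ok) < 10) next
      binary <- all(v[ok] %in% c(0, 1))
      pval <- if (binary && length(unique(v[ok])) == 2) {
        fit <- suppressWarnings(stats::glm.fit(cbind(x = x[ok], 1), v[ok],
                                               family = binomial()))
        cm <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
        2 * pnorm(abs(fit$coefficients[["x"]] / sqrt(cm[1, 1])),
                  lower.tail = FALSE)
      } else {
        ff <- stats::lm.fit(cbind(x = x[ok], 1), v[ok])
        rss <- sum(ff$residuals^2); dfree <- sum(ok) - 2
        sxx <- sum((x[ok] - mean(x[ok]))^2)
        se <- sqrt(rss / dfree / sxx)
        2 * stats::pt(abs(ff$coefficients[["x"]] / se), dfree, lower.tail = FALSE)
      }
      if (!is.na(pval) && pval < alpha) {
        keep[i] <- FALSE
        excl[[length(excl) + 1]] <- tibble(variant_id = vid, confounder = cf,
                                           p = pval)
      }
    }
  }
  kept <- instruments
  kept$instruments <- instruments$instruments[keep, , drop = FALSE]
  kept$cumulative_F <- cumulative_f(kept$instruments$r2_exposure, kept$n)
  kept$screened <- TRUE
  list(kept = kept,
       excluded = if (length(excl)) dplyr::bind_rows(excl) else
         tibble(variant_id = character(), confounder = character(),
                p = numeric()))
}
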