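# Two-sample Mendelian randomisation per CpG: Wald ratio, fixed- and
# multiplicative-random-effects IVW, MR-Egger, Cochran's and Rucker's Q, and
# the Rucker model-selection decision tree. Exposure effects gamma (SNP ->
# methylation, M-units per alternate allele) come from the instrument sets;
# outcome effects Gamma (SNP -> disease log-odds per alternate allele) from a
# disjoint GWAS sample.

z975 <- stats::qnorm(0.975)

#' Construct a SNP-outcome association table
#'
#' @param x an [assoc_table()] on the log-odds scale (columns `unit_id`,
#'   `beta`, `se` are mapped to `variant_id`, `Gamma`, `se_Gamma`) or a data
#'   frame already holding `variant_id`, `Gamma`, `se_Gamma`.
#' @return Tibble of class `outcome_assoc`.
#' @export
outcome_assoc <- function(x) {
  x <- as_tibble(x)
  if (!"Gamma" %in% names(x) && "beta" %in% names(x)) {
    x <- dplyr::rename(x, Gamma = "beta", se_Gamma = "se")
    if ("unit_id" %in% names(x) && !"variant_id" %in% names(x)) {
      x$variant_id <- x$unit_id
    }
  }
  stopifnot(all(c("variant_id", "Gamma", "se_Gamma") %in% names(x)))
  if (any(x$se_Gamma <= 0, na.rm = TRUE)) abort("se_Gamma must be > 0")
  out <- x[, c("variant_id", "Gamma", "se_Gamma",
               intersect(c("effect_allele", "other_allele"), names(x)))]
  class(out) <- c("outcome_assoc", class(out))
  out
}

#' Harmonise exposure and outcome effects
#'
#' Pairs each instrument with its SNP-outcome association. When both sides
#' carry `effect_allele`/`other_allele` columns, swapped alleles are
#' reconciled by flipping the sign of Gamma and irreconcilable mismatches are
#' dropped with a warning; without allele columns both sides are assumed to
#' be on the alternate-allele scale. Finally every pair with gamma < 0 is
#' flipped (gamma -> -gamma, Gamma -> -Gamma) so all exposure effects are
#' positive — required by MR-Egger's orientation convention and without
#' effect on Wald/IVW estimates.
#'
#' @param instr an `instrument_set` (or tibble with `variant_id`, `gamma`,
#'   `se_gamma`).
#' @param outcome an [outcome_assoc()] (or coercible).
#' @return Tibble of pairs: `variant_id`, `gamma`, `se_gamma`, `Gamma`,
#'   `se_Gamma`, `flipped`. Instruments absent from the outcome table are
#'   dropped with a warning; zero remaining pairs is an error.
#' @export
harmonise <- function(instr, outcome) {
  inst <- if (inherits(instr, "instrument_set")) instr$instruments else as_tibble(instr)
  outcome <- outcome_assoc(outcome)
  hit <- match(inst$variant_id, outcome$variant_id)
  if (any(is.na(hit))) {
    warn(sprintf("instrument(s) absent from outcome table: %s",
                 paste(inst$variant_id[is.na(hit)], collapse = ", ")))
    inst <- inst[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  out <- outcome[hit, , drop = FALSE]
  Gam <- out$Gamma
  dropmask <- rep(FALSE, nrow(inst))
  if (all(c("effect_allele", "other_allele") %in% names(inst)) &&
      all(c("effect_allele", "other_allele") %in% names(out))) {
    same <- inst$effect_allele == out$effect_allele &
      inst$other_allele == out$other_allele
    swapped <- inst$effect_allele == out$other_allele &
      inst$other_allele == out$effect_allele
    Gam[swapped] <- -Gam[swapped]
    dropmask <- !(same | swapped)
    if (any(dropmask)) {
      warn(sprintf("dropping %d pair(s) with irreconcilable alleles",
                   sum(dropmask)))
    }
  }
  pairs <- tibble(variant_id = inst$variant_id, gamma = inst$gamma,
                  se_gamma = inst$se_gamma, Gamma = Gam,
                  se_Gamma = out$se_Gamma)[!dropmask, , drop = FALSE]
  if (nrow(pairs) == 0) abort("no harmonised instrument-outcome pairs remain")
  flip <- pairs$gamma < 0
  pairs$gamma[flip] <- -pairs$gamma[flip]
  pairs$Gamma[flip] <- -pairs$Gamma[flip]
  pairs$flipped <- flip
  pairs
}

mr_core_row <- function(method, theta, se, J) {
  tibble(method = method, theta = theta, se_theta = se,
         or_value = exp(theta), ci_low = exp(theta - z975 * se),
         ci_high = exp(theta + z975 * se),
         p = 2 * pnorm(abs(theta / se), lower.tail = FALSE),
         n_instruments = J)
}

#' Wald ratio estimator (single instrument)
#'
#' theta = Gamma / gamma. Default standard error is the first-order delta
#' approximation se_Gamma / |gamma|; `second_order = TRUE` adds the
#' exposure-uncertainty term: se^2 = se_Gamma^2/gamma^2 +
#' Gamma^2 se_gamma^2 / gamma^4.
#'
#' @param gamma,se_gamma SNP-exposure effect and SE.
#' @param Gamma,se_Gamma SNP-outcome effect and SE.
#' @param second_order use the second-order delta SE.
#' @return One-row tibble (`method`, `theta`, `se_theta`, `or_value`,
#'   `ci_low`, `ci_high`, `p`, `n_instruments`).
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma, second_order = FALSE) {
  if (gamma == 0) abort("Wald ratio undefined for gamma = 0")
  theta <- Gamma / gamma
  se <- if (second_order) {
    sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  } else {
    se_Gamma / abs(gamma)
  }
  mr_core_row("wald", theta, se, 1L)
}

ivw_weights <- function(pairs) pairs$gamma^2 / pairs$se_Gamma^2

#' Fixed-effects inverse-variance-weighted estimator
#'
#' theta = sum(w_j r_j) / sum(w_j) with ratio estimates r_j = Gamma_j/gamma_j
#' and weights w_j = gamma_j^2 / se_Gamma_j^2; se = sum(w_j)^(-1/2). This is
#' identical to zero-intercept weighted least squares of Gamma on gamma with
#' weights 1/se_Gamma^2. A single pair reduces exactly to the Wald ratio.
#'
#' @param pairs harmonised pairs from [harmonise()].
#' @return One-row tibble as in [wald_ratio()], `method = "ivw_fixed"`.
#' @export
ivw_fixed <- function(pairs) {
  J <- nrow(pairs)
  if (J == 0) abort("no instrument pairs")
  if (J == 1) {
    # exact reduction: one instrument is the Wald ratio, bit for bit
    return(wald_ratio(pairs$gamma, pairs$se_gamma, pairs$Gamma, pairs$se_Gamma))
  }
  w <- ivw_weights(pairs)
  theta <- sum(w * pairs$Gamma / pairs$gamma) / sum(w)
  se <- 1 / sqrt(sum(w))
  mr_core_row("ivw_fixed", theta, se, J)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum w_j (r_j - theta)^2 with the IVW weights; p from chi-squared with
#' J - 1 df. Excess heterogeneity signals invalid instruments (pleiotropy).
#'
#' @param pairs harmonised pairs.
#' @param theta_ivw the fixed-effects IVW estimate (computed if missing).
#' @return Tibble with `Q`, `df`, `p`.
#' @export
cochran_q <- function(pairs, theta_ivw = NULL) {
  if (is.null(theta_ivw)) theta_ivw <- ivw_fixed(pairs)$theta
  w <- ivw_weights(pairs)
  Q <- sum(w * (pairs$Gamma / pairs$gamma - theta_ivw)^2)
  df <- nrow(pairs) - 1
  tibble(Q = Q, df = df,
         p = if (df >= 1) pchisq(Q, df, lower.tail = FALSE) else NA_real_)
}

#' Multiplicative random-effects IVW estimator
#'
#' Point estimate equals the fixed-effects IVW; the standard error is
#' inflated by max(1, sqrt(Q / (J - 1))), i.e. never below the fixed-effects
#' SE.
#'
#' @param pairs harmonised pairs (J >= 2).
#' @return One-row tibble, `method = "ivw_random"`.
#' @export
ivw_random <- function(pairs) {
  J <- nrow(pairs)
  if (J < 2) abort("random-effects IVW needs at least 2 instruments")
  fixed <- ivw_fixed(pairs)
  q <- cochran_q(pairs, fixed$theta)
  infl <- max(1, sqrt(q$Q / q$df))
  out <- mr_core_row("ivw_random", fixed$theta, fixed$se_theta * infl, J)
  out
}

#' MR-Egger regression
#'
#' Weighted least squares of Gamma on gamma with a free intercept and weights
#' 1/se_Gamma^2 (exposure effects oriented positive by [harmonise()]). The
#' slope is the pleiotropy-robust causal estimate; a nonzero intercept
#' indicates directional pleiotropy. Q_egger is the weighted residual sum of
#' squares (df = J - 2); standard errors carry the multiplicative
#' overdispersion factor max(1, sqrt(Q_egger / (J - 2))).
#'
#' @param pairs harmonised pairs (J >= 3).
#' @return One-row tibble with the [wald_ratio()] columns
#'   (`method = "egger"`) plus `intercept`, `se_intercept`, `p_intercept`,
#'   `Q_egger`.
#' @export
egger <- function(pairs) {
  J <- nrow(pairs)
  if (J < 3) abort("MR-Egger needs at least 3 instruments")
  if (any(pairs$gamma < 0)) abort("Egger requires all-positive gamma; run harmonise()")
  w <- 1 / pairs$se_Gamma^2
  X <- cbind(1, pairs$gamma)
  XtWX <- crossprod(X, w * X)
  inv <- solve(XtWX)
  bhat <- inv %*% crossprod(X, w * pairs$Gamma)
  resid <- pairs$Gamma - X %*% bhat
  Q_egger <- sum(w * resid^2)
  infl <- max(1, sqrt(Q_egger / (J - 2)))
  se_int <- sqrt(inv[1, 1]) * infl
  se_slope <- sqrt(inv[2, 2]) * infl
  out <- mr_core_row("egger", bhat[2], se_slope, J)
  out$intercept <- bhat[1]
  out$se_intercept <- se_int
  out$p_intercept <- 2 * pnorm(abs(bhat[1] / se_int), lower.tail = FALSE)
  out$Q_egger <- Q_egger
  out
}

#' Rucker Q-difference test
#'
#' The drop in heterogeneity from the IVW fit (Q, df = J - 1) to the Egger
#' fit (Q', df = J - 2) is compared with chi-squared on 1 df; a significant
#' drop indicates that the Egger intercept absorbs real directional
#' pleiotropy and the Egger model should be preferred.
#'
#' @param q_ivw Cochran's Q from the IVW fit.
#' @param q_egger Q' from the Egger fit.
#' @return Tibble with `q_diff` and `p`.
#' @export
rucker_q_test <- function(q_ivw, q_egger) {
  d <- max(q_ivw - q_egger, 0)
  tibble(q_diff = d, p = pchisq(d, df = 1, lower.tail = FALSE))
}

#' Rucker-framework model selection for one CpG
#'
#' Decision tree: a single instrument gives the Wald ratio; otherwise the
#' fixed-effects IVW is fitted and kept when Cochran's Q is not significant
#' at `alpha`; with significant heterogeneity the multiplicative
#' random-effects IVW is fitted, and when at least three instruments are
#' available the Rucker Q-difference test decides whether to report MR-Egger
#' instead. All computed statistics are recorded regardless of the selected
#' method; with exactly two heterogeneous instruments the random-effects IVW
#' is reported and the Rucker p is marked unavailable.
#'
#' @param pairs harmonised pairs from [harmonise()].
#' @param alpha significance level of the Q and Q-difference steps.
#' @param cpg,tissue labels carried into the result.
#' @return An `mr_result` object (see [tidy.mr_result()] /
#'   [glance.mr_result()]).
#' @export
rucker_select <- function(pairs, alpha = 0.05, cpg = NA_character_,
                          tissue = NA_character_) {
  J <- nrow(pairs)
  if (J == 0) abort("no instrument pairs")
  estimates <- list()
  q <- tibble(Q = NA_real_, df = NA_integer_, p = NA_real_)
  rq <- tibble(q_diff = NA_real_, p = NA_real_)
  egg <- NULL
  if (J == 1) {
    sel <- wald_ratio(pairs$gamma, pairs$se_gamma, pairs$Gamma, pairs$se_Gamma)
    estimates$wald <- sel
  } else {
    fixed <- ivw_fixed(pairs)
    estimates$ivw_fixed <- fixed
    q <- cochran_q(pairs, fixed$theta)
    if (J >= 3) {
      egg <- egger(pairs)
      estimates$egger <- egg
      rq <- rucker_q_test(q$Q, egg$Q_egger)
    }
    if (is.na(q$p) || q$p >= alpha) {
      sel <- fixed
    } else {
      rand <- ivw_random(pairs)
      estimates$ivw_random <- rand
      sel <- if (J >= 3 && !is.na(rq$p) && rq$p < alpha) egg else rand
    }
  }
  structure(list(cpg = cpg, tissue = tissue, pairs = pairs,
                 method = sel$method, estimate = sel,
                 estimates = dplyr::bind_rows(estimates),
                 cochran_Q = q$Q, cochran_Q_df = q$df, cochran_Q_p = q$p,
                 rucker_Q_diff = rq$q_diff, rucker_p = rq$p,
                 egger_intercept = if (!is.null(egg)) {
                   c(value = egg$intercept, se = egg$se_intercept,
                     p = egg$p_intercept)
                 } else NULL),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("<mr_result> CpG %s (%s), %d instrument(s)\n", x$cpg, x$tissue,
              nrow(x$pairs)))
  cat(sprintf("  selected %s: OR = %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
              x$method, e$or_value, e$ci_low, e$ci_high, e$p))
  if (!is.na(x$cochran_Q)) {
    cat(sprintf("  Cochran Q = %.3f (df %d, p = %.3g)", x$cochran_Q,
                x$cochran_Q_df, x$cochran_Q_p))
    if (!is.na(x$rucker_Q_diff)) {
      cat(sprintf("; Rucker Q-diff = %.3f (p = %.3g)", x$rucker_Q_diff,
                  x$rucker_p))
    }
    cat("\n")
  }
  invisible(x)
}

#' Broom-style tidiers for MR fits
#'
#' `tidy()` returns one row per estimator computed on the instrument set
#' (Wald / IVW fixed / IVW random / Egger, as applicable); `glance()` returns
#' a one-row model summary for the method the Rucker framework selected,
#' including the heterogeneity statistics.
#'
#' @param x an `mr_result` from [rucker_select()].
#' @param ... unused.
#' @return A tibble.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  dplyr::mutate(x$estimates, cpg = x$cpg, tissue = x$tissue,
                selected = .data$method == x$method, .before = 1)
}

#' @rdname tidy.mr_result
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  e <- x$estimate
  tibble(cpg = x$cpg, tissue = x$tissue, method = x$method,
         theta = e$theta, se_theta = e$se_theta, or_value = e$or_value,
         ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
         n_instruments = nrow(x$pairs),
         cochran_Q = x$cochran_Q, cochran_Q_p = x$cochran_Q_p,
         rucker_Q_diff = x$rucker_Q_diff, rucker_p = x$rucker_p,
         egger_intercept = if (!is.null(x$egger_intercept)) {
           x$egger_intercept[["value"]]
         } else NA_real_,
         egger_intercept_p = if (!is.null(x$egger_intercept)) {
           x$egger_intercept[["p"]]
         } else NA_real_)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy
#' @export
generics::glance

#' Batch MR over instrument sets
#'
#' Harmonises each CpG's instrument set against the outcome table and runs
#' the Rucker selection; CpGs with no usable instruments are omitted with a
#' warning. MR p-values are reported nominally (the source design treats
#' p < 0.05 as suggestive evidence); a Benjamini-Hochberg `q` column is
#' included for transparency.
#'
#' @param instrument_sets list of `instrument_set` objects.
#' @param outcome an [outcome_assoc()] (or coercible).
#' @param alpha Rucker-framework significance level.
#' @return Tibble with one row per (CpG, tissue) in `glance()` format plus
#'   `q`; the underlying `mr_result` objects are attached as attribute
#'   `"results"`.
#' @export
mr_all_cpgs <- function(instrument_sets, outcome, alpha = 0.05) {
  outcome <- outcome_assoc(outcome)
  results <- list()
  for (is_ in instrument_sets) {
    if (nrow(is_$instruments) == 0) {
      warn(sprintf("CpG %s has no instruments; omitted", is_$cpg))
      next
    }
    pairs <- tryCatch(harmonise(is_, outcome), error = function(e) NULL)
    if (is.null(pairs)) {
      warn(sprintf("CpG %s could not be harmonised; omitted", is_$cpg))
      next
    }
    results[[paste(is_$cpg, is_$tissue, sep = ":")]] <-
      rucker_select(pairs, alpha = alpha, cpg = is_$cpg, tissue = is_$tissue)
  }
  tab <- purrr::map_dfr(results, glance)
  if (nrow(tab) > 0) tab$q <- bh_fdr(tab$p)
  attr(tab, "results") <- results
  tab
}
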