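#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange left_join inner_join bind_rows
#'   group_by summarise ungroup rename n across all_of
#' @importFrom stats lm glm coef pchisq pnorm qnorm qchisq median quantile sd var
#'   complete.cases rbinom rnorm runif rgamma plogis uniroot kruskal.test
#'   p.adjust binomial setNames ks.test
#' @importFrom utils head
NULL

# ---- Matrix containers -------------------------------------------------------
#
# Samples-by-unit numeric matrices (methylation, genotype dosage, expression)
# are kept as base matrices with sample ids in rownames and unit ids in
# colnames, plus a tibble of per-unit annotation carried alongside. Everything
# row-shaped (association results, instruments, MR fits) is a tibble.

check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0) {
    abort(sprintf("duplicated %s: %s", what, paste(head(d, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Methylation matrix container
#'
#' Wraps a samples x probes numeric matrix together with probe annotation
#' (chromosome and 1-based position of the interrogated cytosine). Values may
#' be on the beta scale (methylated fraction, in \[0,1\]) or the M scale
#' (log2(beta/(1-beta)), the modelling scale).
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   probes in columns (colnames = probe ids). `NA` marks missing values.
#' @param probes tibble with columns `probe_id`, `chrom`, `pos` and optionally
#'   `gene_label`; may be `NULL`, in which case a minimal annotation is built
#'   from the column names.
#' @param scale `"m_value"` or `"beta_value"`; beta values must lie in \[0,1\].
#' @param time_point integer label, e.g. 1 for baseline, 2 for follow-up.
#' @return An object of class `methyl_matrix`.
#' @export
methyl_matrix <- function(values, probes = NULL,
                          scale = c("m_value", "beta_value"),
                          time_point = 1L) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("methylation values must be numeric")
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    abort("values must carry sample ids (rownames) and probe ids (colnames)")
  }
  check_unique(rownames(values), "sample ids")
  check_unique(colnames(values), "probe ids")
  if (scale == "beta_value") {
    bad <- values < 0 | values > 1
    if (any(bad, na.rm = TRUE)) {
      abort("beta values outside [0,1] found; declared scale is beta_value")
    }
  }
  if (is.null(probes)) {
    probes <- tibble(probe_id = colnames(values) %||% character(0),
                     chrom = NA_character_, pos = NA_integer_,
                     gene_label = NA_character_)
  } else {
    probes <- validate_probe_annotation(probes)
    missing <- setdiff(colnames(values), probes$probe_id)
    if (length(missing) > 0) {
      abort(sprintf("probes missing from annotation: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    probes <- probes[match(colnames(values), probes$probe_id), ]
  }
  structure(list(values = values, probes = probes, scale = scale,
                 time_point = as.integer(time_point)),
            class = "methyl_matrix")
}

#' Genotype dosage matrix container
#'
#' Samples x variants matrix of alternate-allele dosages in \[0,2\] (fractional
#' for imputed genotypes), with per-variant annotation.
#'
#' @param dosages numeric matrix, rownames = sample ids, colnames = variant
#'   ids; all finite values must lie in \[0,2\].
#' @param variants tibble with `variant_id`, `chrom`, `pos` and optionally
#'   `ref_allele`, `alt_allele`, `info_score`; `NULL` builds a minimal one.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants = NULL) {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) abort("dosages must be numeric")
  if (is.null(rownames(dosages)) ||
      (ncol(dosages) > 0 && is.null(colnames(dosages)))) {
    abort("dosages must carry sample ids (rownames) and variant ids (colnames)")
  }
  check_unique(rownames(dosages), "sample ids")
  check_unique(colnames(dosages), "variant ids")
  bad <- dosages < 0 | dosages > 2
  if (any(bad, na.rm = TRUE)) {
    idx <- which(bad)[1]
    abort(sprintf("dosage out of [0,2]: value %.4g at sample '%s', variant '%s'",
                  dosages[idx],
                  rownames(dosages)[(idx - 1) %% nrow(dosages) + 1],
                  colnames(dosages)[(idx - 1) %/% nrow(dosages) + 1]))
  }
  if (is.null(variants)) {
    variants <- tibble(variant_id = colnames(dosages) %||% character(0),
                       chrom = NA_character_, pos = NA_integer_,
                       ref_allele = NA_character_, alt_allele = NA_character_,
                       info_score = NA_real_)
  } else {
    variants <- validate_variant_annotation(variants)
    missing <- setdiff(colnames(dosages), variants$variant_id)
    if (length(missing) > 0) {
      abort(sprintf("variants missing from annotation: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    variants <- variants[match(colnames(dosages), variants$variant_id), ]
  }
  structure(list(dosages = dosages, variants = variants),
            class = "geno_matrix")
}

#' Expression matrix container
#'
#' Samples x genes matrix of expression levels (e.g. log2 TPM) with gene
#' annotation anchored at the transcription start site for cis/trans calls.
#'
#' @param values numeric matrix, rownames = sample ids, colnames = gene ids.
#' @param genes tibble with `gene_id`, `chrom`, `tss` and optionally `strand`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, genes = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("expression values must be numeric")
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    abort("values must carry sample ids (rownames) and gene ids (colnames)")
  }
  check_unique(rownames(values), "sample ids")
  check_unique(colnames(values), "gene ids")
  if (is.null(genes)) {
    genes <- tibble(gene_id = colnames(values) %||% character(0),
                    chrom = NA_character_, tss = NA_integer_, strand = "+")
  } else {
    genes <- as_tibble(genes)
    if (!all(c("gene_id", "chrom", "tss") %in% names(genes))) {
      abort("gene annotation needs columns gene_id, chrom, tss")
    }
    if (!"strand" %in% names(genes)) genes$strand <- "+"
    check_unique(genes$gene_id, "gene ids")
    genes <- genes[match(colnames(values), genes$gene_id), ]
  }
  structure(list(values = values, genes = genes), class = "expr_matrix")
}

validate_probe_annotation <- function(probes) {
  probes <- as_tibble(probes)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(probes))) {
    abort("probe annotation needs columns probe_id, chrom, pos")
  }
  if (!"gene_label" %in% names(probes)) probes$gene_label <- NA_character_
  check_unique(probes$probe_id, "probe ids")
  if (any(probes$pos < 1, na.rm = TRUE)) abort("probe pos must be >= 1 (1-based)")
  probes
}

validate_variant_annotation <- function(variants) {
  variants <- as_tibble(variants)
  need <- c("variant_id", "chrom", "pos")
  if (!all(need %in% names(variants))) {
    abort("variant annotation needs columns variant_id, chrom, pos")
  }
  for (col in c("ref_allele", "alt_allele")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_character_
  }
  if (!"info_score" %in% names(variants)) variants$info_score <- NA_real_
  check_unique(variants$variant_id, "variant ids")
  if (any(variants$pos < 1, na.rm = TRUE)) abort("variant pos must be >= 1 (1-based)")
  same <- !is.na(variants$ref_allele) & !is.na(variants$alt_allele) &
    variants$ref_allele == variants$alt_allele
  if (any(same)) abort("ref_allele must differ from alt_allele")
  if (any(variants$info_score < 0 | variants$info_score > 1, na.rm = TRUE)) {
    abort("info_score must lie in [0,1]")
  }
  variants
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("<methyl_matrix> %d samples x %d probes, scale=%s, time_point=%d\n",
              nrow(x$values), ncol(x$values), x$scale, x$time_point))
  invisible(x)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.methyl_matrix <- function(x) dim(x$values)
#' @export
dim.geno_matrix <- function(x) dim(x$dosages)
#' @export
dim.expr_matrix <- function(x) dim(x$values)

sample_ids <- function(x) {
  switch(class(x)[1],
         methyl_matrix = rownames(x$values),
         geno_matrix = rownames(x$dosages),
         expr_matrix = rownames(x$values),
         abort("unsupported container"))
}

# ---- Association tables ------------------------------------------------------

assoc_cols <- c("unit_id", "beta", "se", "p", "n", "trait", "cohort")

#' Construct / validate an association summary table
#'
#' The common currency of every stage: one row per tested unit (probe, variant,
#' or variant:probe / probe:gene pair) holding effect size, standard error,
#' p-value, sample size, trait and cohort labels.
#'
#' @param x data frame with columns `unit_id`, `beta`, `se`, `p`, `n`,
#'   `trait`, `cohort` (extra columns are preserved).
#' @return A validated tibble (class `assoc_table`).
#' @export
assoc_table <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(assoc_cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("assoc table missing columns: %s", paste(missing, collapse = ", ")))
  }
  ok <- !is.na(x$se)
  if (any(x$se[ok] <= 0)) abort("assoc table se must be > 0")
  okp <- !is.na(x$p)
  if (any(x$p[okp] < 0 | x$p[okp] > 1)) abort("assoc table p must lie in [0,1]")
  if (any(x$n < 1, na.rm = TRUE)) abort("assoc table n must be >= 1")
  x <- x[, c(assoc_cols, setdiff(names(x), assoc_cols))]
  class(x) <- c("assoc_table", class(x))
  x
}
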