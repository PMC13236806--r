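# Tab-delimited readers/writers. Layout for matrices: header row of sample
# ids, first column of unit ids (probes/variants/genes in rows on disk, i.e.
# the transpose of the in-memory samples x units orientation, which keeps
# files readable when units vastly outnumber samples). Missing values are
# "NA". Numbers are written with 17 significant digits so that
# read(write(x)) == x exactly for doubles.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a samples-by-units matrix from a tab-delimited file
#'
#' Expects unit ids (probes, variants or genes) in the first column and sample
#' ids in the header. A sidecar annotation table may be joined on read.
#'
#' @param path path to a tab-delimited text file, or a VCF (`.vcf`) when
#'   `kind = "genotype"` (dosages taken from the `DS` FORMAT field, falling
#'   back to allele counts from `GT`; requires the vcfR package).
#' @param kind `"methylation"`, `"genotype"` or `"expression"`.
#' @param annotation optional tibble (or path to a tab-delimited file) of unit
#'   annotation: probe (`probe_id`, `chrom`, `pos`), variant
#'   (`variant_id`, `chrom`, `pos`, alleles) or gene (`gene_id`, `chrom`,
#'   `tss`).
#' @param scale for methylation, `"m_value"` or `"beta_value"`.
#' @param time_point for methylation, integer time-point label.
#' @return A `methyl_matrix`, `geno_matrix` or `expr_matrix`.
#' @export
read_matrix <- function(path, kind = c("methylation", "genotype", "expression"),
                        annotation = NULL,
                        scale = c("m_value", "beta_value"), time_point = 1L) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.character(annotation) && length(annotation) == 1) {
    annotation <- readr::read_tsv(annotation, show_col_types = FALSE,
                                  progress = FALSE)
  }
  if (kind == "genotype" && grepl("\\.vcf(\\.gz)?$", path)) {
    return(read_genotypes_vcf(path, annotation = annotation))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(raw) < 2) abort("matrix file needs a unit-id column plus samples")
  unit_ids <- raw[[1]]
  check_unique(unit_ids, "unit ids")
  check_unique(names(raw)[-1], "sample ids")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- is.na(num) & !(is.na(vals) | vals == "NA")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell '%s' at unit '%s', sample '%s'",
                  vals[idx[1], idx[2]], unit_ids[idx[1]], names(raw)[idx[2] + 1]))
  }
  m <- t(num)  # samples x units
  rownames(m) <- names(raw)[-1]
  colnames(m) <- unit_ids
  switch(kind,
         methylation = methyl_matrix(m, probes = annotation, scale = scale,
                                     time_point = time_point),
         genotype = geno_matrix(m, variants = annotation),
         expression = expr_matrix(m, genes = annotation))
}

#' Write a matrix container to a tab-delimited file
#'
#' Transposed on disk (units in rows); exact numeric round trip with
#' [read_matrix()].
#'
#' @param x a `methyl_matrix`, `geno_matrix` or `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  m <- switch(class(x)[1],
              methyl_matrix = x$values,
              geno_matrix = x$dosages,
              expr_matrix = x$values,
              abort("unsupported container"))
  unit_col <- switch(class(x)[1],
                     methyl_matrix = "probe_id",
                     geno_matrix = "variant_id",
                     expr_matrix = "gene_id")
  tm <- t(m)
  lines <- c(paste(c(unit_col, rownames(m)), collapse = "\t"),
             vapply(seq_len(nrow(tm)), function(i) {
               paste(c(rownames(tm)[i], fmt_num(tm[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

read_genotypes_vcf <- function(path, annotation = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  fmt <- rownames(v@gt) # unused; DS extraction below
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(col, function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.numeric(strsplit(gsub("\\|", "/", g), "/")[[1]]))
      }, numeric(1))
    })
  }
  rownames(ds) <- ids
  anno <- tibble(variant_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                 ref_allele = fix$REF, alt_allele = fix$ALT,
                 info_score = NA_real_)
  if (!is.null(annotation)) {
    annotation <- validate_variant_annotation(annotation)
    anno <- annotation[match(ids, annotation$variant_id), ]
  }
  geno_matrix(t(ds), variants = anno)
}

#' Write an association table to a tab-delimited file
#'
#' Fixed column order (`unit_id`, `beta`, `se`, `p`, `n`, `trait`, `cohort`,
#' then any extras); exact round trip with [read_assoc_table()], including
#' p-values near the double denormal range.
#'
#' @param table an [assoc_table()] (or coercible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assoc_table <- function(table, path) {
  table <- assoc_table(table)
  out <- as_tibble(table)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- fmt_num(out[[col]])
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an association table written by [write_assoc_table()]
#'
#' @param path path to the tab-delimited file.
#' @return An [assoc_table()] tibble.
#' @export
read_assoc_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         .default = readr::col_character()))
  # convert via strtod (correctly rounded) so written doubles round-trip
  # exactly; readr's fast parser loses ulps on extreme values
  for (col in setdiff(names(x), c("unit_id", "trait", "cohort", "direction"))) {
    v <- x[[col]]
    if (all(is.na(v) | v %in% c("TRUE", "FALSE"))) {
      x[[col]] <- as.logical(v)
    } else if (!any(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))) {
      num <- as.numeric(v)
      x[[col]] <- if (col == "n") as.integer(num) else num
    }
  }
  assoc_table(x)
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited, one row per sample, `sample_id` column required; "NA" marks
#' missing. Cell-proportion columns (`CD8T`, `CD4T`, `NK`, `B`, `Mono`,
#' `Neu`), if present, are checked to lie in \[0,1\].
#'
#' @param path path to the file.
#' @return A tibble.
#' @export
read_pheno_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(x)) abort("phenotype table needs a sample_id column")
  check_unique(x$sample_id, "sample ids")
  for (col in intersect(cell_prop_cols, names(x))) {
    if (any(x[[col]] < 0 | x[[col]] > 1, na.rm = TRUE)) {
      abort(sprintf("cell proportion column %s outside [0,1]", col))
    }
  }
  x
}

cell_prop_cols <- c("CD8T", "CD4T", "NK", "B", "Mono", "Neu")

#' Write a phenotype/covariate table
#'
#' @param pheno tibble with a `sample_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pheno_table <- function(pheno, path) {
  out <- as_tibble(pheno)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- fmt_num(out[[col]])
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
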