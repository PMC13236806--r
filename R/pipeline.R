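# Config-driven orchestration of the full workflow in discovery order:
# simulate -> ewas -> meta -> meqtl -> clump -> screen -> gwas -> mr ->
# posthoc. Every stage writes tab-delimited outputs plus a provenance record
# (config hash, forked seed, package version) so runs are reproducible and
# auditable; identical config + seed gives byte-identical outputs.

pipeline_stages <- c("simulate", "ewas", "meta", "meqtl", "clump", "screen",
                     "gwas", "mr", "posthoc")

#' Serialise instrument sets to a tab-delimited file
#'
#' One row per (CpG, instrument): `cpg`, `tissue`, `variant_id`, `gamma`,
#' `se_gamma`, `p_gamma`, `r2_exposure`, `cumulative_F`, `n`, `screened`.
#'
#' @param sets list of `instrument_set` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(sets, path) {
  rows <- purrr::map_dfr(sets, function(s) {
    if (nrow(s$instruments) == 0) return(NULL)
    dplyr::mutate(s$instruments, cpg = s$cpg, tissue = s$tissue,
                  cumulative_F = s$cumulative_F, n = s$n,
                  screened = s$screened, .before = 1)
  })
  if (nrow(rows) == 0) {
    rows <- tibble(cpg = character(), tissue = character(),
                   variant_id = character(), gamma = numeric(),
                   se_gamma = numeric(), p_gamma = numeric(),
                   r2_exposure = numeric(), cumulative_F = numeric(),
                   n = integer(), screened = logical())
  }
  for (col in names(rows)) {
    if (is.numeric(rows[[col]]) && !is.integer(rows[[col]])) {
      rows[[col]] <- fmt_num(rows[[col]])
    }
  }
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read instrument sets written by [write_instruments()]
#'
#' @param path path to the file.
#' @return List of `instrument_set` objects.
#' @export
read_instruments <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) return(list())
  split(x, paste(x$cpg, x$tissue, sep = ":")) |>
    purrr::map(function(g) {
      structure(list(cpg = g$cpg[1], tissue = g$tissue[1],
                     instruments = tibble(variant_id = g$variant_id,
                                          gamma = g$gamma,
                                          se_gamma = g$se_gamma,
                                          p_gamma = g$p_gamma,
                                          r2_exposure = g$r2_exposure),
                     cumulative_F = g$cumulative_F[1], n = g$n[1],
                     screened = isTRUE(g$screened[1])),
                class = "instrument_set")
    }) |>
    unname()
}

default_config <- function() {
  list(seed = 1L,
       stages = "all",
       sim = list(),
       thresholds = list(ewas_fdr = 0.05, meqtl_fdr = 0.05, clump_r2 = 0.1,
                         cis_window_bp = 2e6, screen_alpha = 0.05,
                         mr_alpha = 0.05, min_f = 10))
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  cfg$seed <- as.integer(cfg$seed)
  if (identical(cfg$stages, "all")) cfg$stages <- pipeline_stages
  unknown <- setdiff(cfg$stages, pipeline_stages)
  if (length(unknown) > 0) {
    abort(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg
}

need_files <- function(out_dir, files, stage, produced_by) {
  paths <- file.path(out_dir, files)
  miss <- files[!file.exists(paths)]
  if (length(miss) > 0) {
    abort(sprintf("stage '%s' requires %s (produced by stage '%s'); run that stage first",
                  stage, paste(miss, collapse = ", "), produced_by))
  }
}

write_provenance <- function(out_dir, stage, cfg, seed) {
  prov <- list(stage = stage,
               config_hash = rlang::hash(cfg),
               seed = seed,
               package_version = as.character(utils::packageVersion("meqtlmr")))
  jsonlite::write_json(prov, file.path(out_dir, paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in order, exchanging tab-delimited files in
#' `out_dir`. The single config seed is deterministically forked per stage,
#' so identical config + seed reproduces every output byte for byte, and
#' individual stages can be re-run in isolation against existing upstream
#' files. Each stage writes a provenance JSON (config hash, stage seed,
#' package version). A stage whose upstream files are missing fails naming
#' the dependency.
#'
#' @param config a list or path to a YAML file; recognised keys: `seed`
#'   (integer), `stages` (`"all"` or a subset of simulate, ewas, meta, meqtl,
#'   clump, screen, gwas, mr, posthoc), `sim` (arguments forwarded to
#'   [simulate_cohort()]), `thresholds` (ewas_fdr, meqtl_fdr, clump_r2,
#'   cis_window_bp, screen_alpha, mr_alpha, min_f).
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- read_config(config)
  th <- cfg$thresholds
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- setNames(fork_seeds(cfg$seed, length(pipeline_stages)),
                    pipeline_stages)
  fp <- function(f) file.path(out_dir, f)

  if ("simulate" %in% cfg$stages) {
    sim <- do.call(simulate_cohort, c(cfg$sim, list(seed = seeds[["simulate"]])))
    write_matrix(sim$discovery$meth_t1, fp("discovery_meth_t1.tsv"))
    write_matrix(sim$discovery$meth_t2, fp("discovery_meth_t2.tsv"))
    write_pheno_table(sim$discovery$pheno, fp("discovery_pheno.tsv"))
    write_matrix(sim$meqtl$geno, fp("meqtl_geno.tsv"))
    write_matrix(sim$meqtl$meth, fp("meqtl_meth.tsv"))
    write_pheno_table(sim$meqtl$pheno, fp("meqtl_pheno.tsv"))
    write_matrix(sim$gwas$geno, fp("gwas_geno.tsv"))
    write_pheno_table(sim$gwas$pheno, fp("gwas_pheno.tsv"))
    write_matrix(sim$expression$expr, fp("expression.tsv"))
    write_pheno_table(sim$expression$pheno, fp("expression_pheno.tsv"))
    readr::write_tsv(sim$probes, fp("probe_annotation.tsv"), progress = FALSE)
    readr::write_tsv(sim$meqtl$geno$variants, fp("variant_annotation.tsv"),
                     progress = FALSE)
    readr::write_tsv(sim$expression$expr$genes, fp("gene_annotation.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(theta = as.list(sim$truth$theta), meqtl = sim$truth$meqtl,
           pleiotropy = sim$truth$pleiotropy,
           prevalence = as.list(sim$truth$prevalence),
           drift = as.list(sim$truth$drift),
           lambda_follow = sim$truth$lambda_follow),
      fp("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_provenance(out_dir, "simulate", cfg, seeds[["simulate"]])
  }

  load_meth <- function(file, tp = 1L) {
    read_matrix(fp(file), "methylation",
                annotation = fp("probe_annotation.tsv"), time_point = tp)
  }
  load_geno <- function(file) {
    read_matrix(fp(file), "genotype", annotation = fp("variant_annotation.tsv"))
  }

  if ("ewas" %in% cfg$stages) {
    need_files(out_dir, c("discovery_meth_t1.tsv", "discovery_pheno.tsv",
                          "meqtl_meth.tsv", "meqtl_pheno.tsv",
                          "probe_annotation.tsv"), "ewas", "simulate")
    md <- load_meth("discovery_meth_t1.tsv")
    phd <- read_pheno_table(fp("discovery_pheno.tsv"))
    t2d <- run_ewas(md, phd, cohort = "discovery")
    write_assoc_table(t2d, fp("ewas_t2d_discovery.tsv"))
    hb_spec <- function(ph) {
      covs <- intersect(c("age", "sex", "site", cell_prop_cols, "bmi", "plate"),
                        names(ph))
      model_spec("hba1c", covariates = covs, family = "gaussian",
                 transform = "log")
    }
    hb1 <- run_ewas(md, phd, spec = hb_spec(phd), trait = "hba1c",
                    cohort = "discovery")
    write_assoc_table(hb1, fp("ewas_hba1c_discovery.tsv"))
    mm <- load_meth("meqtl_meth.tsv")
    phm <- read_pheno_table(fp("meqtl_pheno.tsv"))
    hb2 <- run_ewas(mm, phm, spec = hb_spec(phm), trait = "hba1c",
                    cohort = "meqtl")
    write_assoc_table(hb2, fp("ewas_hba1c_meqtl.tsv"))
    write_provenance(out_dir, "ewas", cfg, seeds[["ewas"]])
  }

  if ("meta" %in% cfg$stages) {
    need_files(out_dir, c("ewas_hba1c_discovery.tsv", "ewas_hba1c_meqtl.tsv"),
               "meta", "ewas")
    meta <- meta_fixed(list(read_assoc_table(fp("ewas_hba1c_discovery.tsv")),
                            read_assoc_table(fp("ewas_hba1c_meqtl.tsv"))))
    out <- meta
    for (col in names(out)) {
      if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
        out[[col]] <- fmt_num(out[[col]])
      }
    }
    readr::write_tsv(out, fp("meta_hba1c.tsv"), progress = FALSE)
    # Selection: union of discovery-EWAS and meta-analysis hits at FDR < 0.05
    t2d <- read_assoc_table(fp("ewas_t2d_discovery.tsv"))
    sel <- union(t2d$unit_id[t2d$q < th$ewas_fdr],
                 meta$unit_id[bh_fdr(meta$p_meta) < th$ewas_fdr])
    if (length(sel) == 0) {
      warn("no CpGs reached FDR < threshold; carrying the 5 smallest-p CpGs forward")
      sel <- t2d$unit_id[order(t2d$p)][seq_len(min(5, nrow(t2d)))]
    }
    writeLines(sort(sel), fp("selected_cpgs.txt"))
    write_provenance(out_dir, "meta", cfg, seeds[["meta"]])
  }

  if ("meqtl" %in% cfg$stages) {
    need_files(out_dir, c("meqtl_geno.tsv", "meqtl_meth.tsv",
                          "meqtl_pheno.tsv", "selected_cpgs.txt"),
               "meqtl", "simulate/meta")
    G <- qc_variants(load_geno("meqtl_geno.tsv"))
    mm <- load_meth("meqtl_meth.tsv")
    sel <- readLines(fp("selected_cpgs.txt"))
    keep <- intersect(colnames(mm$values), sel)
    mm <- methyl_matrix(mm$values[, keep, drop = FALSE],
                        probes = mm$probes[mm$probes$probe_id %in% keep, ],
                        scale = mm$scale)
    phm <- read_pheno_table(fp("meqtl_pheno.tsv"))
    mq <- map_cis_meqtls(G, mm, phm, window_bp = th$cis_window_bp)
    write_assoc_table(mq, fp("meqtl.tsv"))
    write_provenance(out_dir, "meqtl", cfg, seeds[["meqtl"]])
  }

  if ("clump" %in% cfg$stages) {
    need_files(out_dir, c("meqtl.tsv", "meqtl_geno.tsv", "meqtl_pheno.tsv"),
               "clump", "meqtl")
    mq <- read_assoc_table(fp("meqtl.tsv"))
    G <- load_geno("meqtl_geno.tsv")
    n_exp <- nrow(read_pheno_table(fp("meqtl_pheno.tsv")))
    sig <- dplyr::filter(as_tibble(mq), .data$q < th$meqtl_fdr)
    sets <- purrr::map(unique(sig$probe_id), function(cpg) {
      sub <- dplyr::filter(sig, .data$probe_id == cpg)
      cl <- clump(sub, G, r2_threshold = th$clump_r2)
      instrument_set(cpg, sub, cl, n = n_exp, tissue = "blood")
    })
    sets <- purrr::keep(sets, ~ .x$cumulative_F > th$min_f)
    write_instruments(sets, fp("instruments.tsv"))
    write_provenance(out_dir, "clump", cfg, seeds[["clump"]])
  }

  if ("screen" %in% cfg$stages) {
    need_files(out_dir, c("instruments.tsv", "meqtl_geno.tsv",
                          "meqtl_pheno.tsv"), "screen", "clump")
    sets <- read_instruments(fp("instruments.tsv"))
    G <- load_geno("meqtl_geno.tsv")
    phm <- read_pheno_table(fp("meqtl_pheno.tsv"))
    screened <- purrr::map(sets, function(s) {
      screen_instruments(s, G, phm, alpha = th$screen_alpha)$kept
    })
    screened <- purrr::keep(screened, ~ nrow(.x$instruments) > 0)
    write_instruments(screened, fp("instruments_screened.tsv"))
    write_provenance(out_dir, "screen", cfg, seeds[["screen"]])
  }

  if ("gwas" %in% cfg$stages) {
    need_files(out_dir, c("gwas_geno.tsv", "gwas_pheno.tsv",
                          "instruments_screened.tsv", "meqtl_pheno.tsv"),
               "gwas", "simulate/screen")
    G <- load_geno("gwas_geno.tsv")
    ph <- read_pheno_table(fp("gwas_pheno.tsv"))
    sets <- read_instruments(fp("instruments_screened.tsv"))
    vids <- unique(unlist(purrr::map(sets, ~ .x$instruments$variant_id)))
    exposure_ids <- read_pheno_table(fp("meqtl_pheno.tsv"))$sample_id
    if (length(vids) == 0) {
      warn("no instruments survive screening; GWAS output will be empty")
      gw <- assoc_table(tibble(unit_id = character(), beta = numeric(),
                               se = numeric(), p = numeric(), n = integer(),
                               trait = character(), cohort = character()))
    } else {
      Gsub <- geno_matrix(G$dosages[, vids, drop = FALSE],
                          variants = G$variants[G$variants$variant_id %in% vids, ])
      gw <- run_outcome_gwas(Gsub, ph, exposure_ids = exposure_ids)
    }
    write_assoc_table(gw, fp("gwas.tsv"))
    write_provenance(out_dir, "gwas", cfg, seeds[["gwas"]])
  }

  if ("mr" %in% cfg$stages) {
    need_files(out_dir, c("instruments_screened.tsv", "gwas.tsv"), "mr",
               "screen/gwas")
    sets <- read_instruments(fp("instruments_screened.tsv"))
    gw <- read_assoc_table(fp("gwas.tsv"))
    res <- mr_all_cpgs(sets, gw, alpha = th$mr_alpha)
    out <- res
    for (col in names(out)) {
      if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
        out[[col]] <- fmt_num(out[[col]])
      }
    }
    readr::write_tsv(out, fp("mr_results.tsv"), progress = FALSE)
    write_provenance(out_dir, "mr", cfg, seeds[["mr"]])
  }

  if ("posthoc" %in% cfg$stages) {
    need_files(out_dir, c("discovery_meth_t1.tsv", "discovery_meth_t2.tsv",
                          "meqtl_meth.tsv", "meqtl_pheno.tsv",
                          "expression.tsv", "expression_pheno.tsv",
                          "selected_cpgs.txt"), "posthoc", "simulate/meta")
    sel <- readLines(fp("selected_cpgs.txt"))
    st <- stability(load_meth("discovery_meth_t1.tsv"),
                    load_meth("discovery_meth_t2.tsv", 2L), probes = sel)
    tw <- function(x, f) {
      for (col in names(x)) {
        if (is.numeric(x[[col]]) && !is.integer(x[[col]])) {
          x[[col]] <- fmt_num(x[[col]])
        }
      }
      readr::write_tsv(x, fp(f), progress = FALSE)
    }
    tw(st, "stability.tsv")
    mm <- load_meth("meqtl_meth.tsv")
    phm <- read_pheno_table(fp("meqtl_pheno.tsv"))
    tert <- tertile_analysis(mm, phm, probes = intersect(sel, colnames(mm$values)))
    tw(tert, "tertiles.tsv")
    ex <- read_matrix(fp("expression.tsv"), "expression",
                      annotation = fp("gene_annotation.tsv"))
    phe <- read_pheno_table(fp("expression_pheno.tsv"))
    eq <- eqtm_map(mm, ex, phe, tissue = "blood",
                   probes = intersect(sel, colnames(mm$values)))
    tw(eq, "eqtm_blood.tsv")
    write_provenance(out_dir, "posthoc", cfg, seeds[["posthoc"]])
  }

  invisible(out_dir)
}
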