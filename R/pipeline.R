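.pipeline_defaults <- function() {
  list(
    out_dir = "results/pipeline",
    ped = NULL, map = NULL, traits = NULL,   # NULL: simulate instead
    n_animals = 500L, n_blocks = 40L, block_size_range = c(2L, 6L),
    alleles_per_block = 4L, allele_freq_concentration = 1,
    missing_rate = 0.02,
    reliability_range = c(0.70, 0.99), birth_year_range = c(1987L, 2003L),
    trait_name = "MY", heritability = 0.33, genetic_variance = 213490,
    error_variance = NULL,
    max_missing = 0.10, min_maf = 0.01,
    r2_threshold = 0.8, window_snps = 50L, contiguous = FALSE,
    freq_threshold = 0.25, freq_basis = "carrier",
    train_fraction = 0.875, variants = 1:4,
    use_weights = FALSE, seed = 1L)
}

#' Pipeline configuration
#'
#' Collects every threshold and switch of the end-to-end analysis in one
#' validated list. Unknown keys are rejected; every threshold is checked
#' against its documented range before any stage runs. With `ped`, `map`
#' and `traits` unset, the pipeline simulates its input population from
#' the simulation parameters; otherwise it reads the given files.
#'
#' @param ... Named overrides of the defaults (see
#'   `haploblup:::.pipeline_defaults()` for the full list: paths, QC
#'   thresholds `max_missing`/`min_maf`, LD settings
#'   `r2_threshold`/`window_snps`, haplotype `freq_threshold` and
#'   `freq_basis`, trait parameters, `train_fraction`, `variants`,
#'   `seed`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  cfg <- .pipeline_defaults()
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  with(cfg, {
    if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0, 1]")
    if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
    if (r2_threshold <= 0 || r2_threshold > 1) stop("r2_threshold must lie in (0, 1]")
    if (window_snps < 1) stop("window_snps must be >= 1")
    if (freq_threshold < 0 || freq_threshold >= 1) stop("freq_threshold must lie in [0, 1)")
    if (!freq_basis %in% c("carrier", "population")) {
      stop("freq_basis must be 'carrier' or 'population'")
    }
    if (train_fraction <= 0 || train_fraction >= 1) {
      stop("train_fraction must lie in (0, 1)")
    }
    if (!all(variants %in% 1:4)) stop("variants must be drawn from 1..4")
    if (heritability <= 0 || heritability > 1) stop("heritability must lie in (0, 1]")
    if (genetic_variance <= 0) stop("genetic_variance must be positive")
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  })
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file of `key: value` pairs matching
#'   [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full haplotype prediction pipeline
#'
#' Executes the stages in order — data (simulate or read), SNP QC, LD
#' block construction, EM phasing with the high-frequency haplotype
#' filter, deregression, model fitting for each requested variant, and
#' generational validation — writing each stage's artifact as
#' tab-delimited text under `config$out_dir` together with a structured
#' log (stage, key, value) that records every threshold and the
#' before/after counts of every filter. Any stage failure halts the run
#' with an error naming the stage. Runs with the same configuration
#' produce byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the validation `report`, the fitted
#'   models, the selected haplotype table and the artifact paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be created by pipeline_config()")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_rows <- list()
  note <- function(stage, key, value) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, key = key, value = as.character(value))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  art <- function(name) file.path(config$out_dir, name)

  # -- data ----------------------------------------------------------------
  dat <- run_stage("data", {
    if (is.null(config$ped)) {
      sim_cfg <- simulation_config(
        n_animals = config$n_animals, n_blocks = config$n_blocks,
        block_size_range = config$block_size_range,
        alleles_per_block = config$alleles_per_block,
        allele_freq_concentration = config$allele_freq_concentration,
        heritability = config$heritability,
        genetic_variance = config$genetic_variance,
        reliability_range = config$reliability_range,
        birth_year_range = config$birth_year_range,
        missing_rate = config$missing_rate, seed = config$seed)
      pop <- simulate_population(sim_cfg)
      write_ped_map(pop$genotypes, art("genotypes.ped"), art("genotypes.map"))
      write_trait_table(pop$proofs, art("traits.tsv"))
      note("data", "source", "simulated")
      note("data", "seed", config$seed)
      list(genotypes = pop$genotypes, proofs = pop$proofs)
    } else {
      note("data", "source", config$ped)
      list(genotypes = read_ped_map(config$ped, config$map),
           proofs = read_trait_table(config$traits))
    }
  })
  note("data", "n_animals", n_animals(dat$genotypes))
  note("data", "n_snps", n_snps(dat$genotypes))

  # -- qc -------------------------------------------------------------------
  qc <- run_stage("qc", {
    res <- apply_qc(dat$genotypes, max_missing = config$max_missing,
                    min_maf = config$min_maf)
    write_qc_report(res$report, art("qc_report.tsv"),
                    snp_ids = dat$genotypes$snp_ids)
    write_ped_map(res$genotypes, art("genotypes_qc.ped"),
                  art("genotypes_qc.map"))
    res
  })
  note("qc", "max_missing", config$max_missing)
  note("qc", "min_maf", config$min_maf)
  note("qc", "n_input_snps", qc$report$n_input_snps)
  note("qc", "n_after_geno", qc$report$n_after_geno)
  note("qc", "n_after_maf", qc$report$n_after_maf)

  # -- blocks ---------------------------------------------------------------
  blocks <- run_stage("blocks", {
    b <- build_blocks(qc$genotypes, r2_threshold = config$r2_threshold,
                      window_snps = config$window_snps,
                      contiguous = config$contiguous)
    if (length(b$blocks) == 0) stop("no LD blocks found at r2 >= ",
                                    config$r2_threshold)
    write_blocks(b, art("blocks.tsv"))
    b
  })
  note("blocks", "r2_threshold", config$r2_threshold)
  note("blocks", "window_snps", config$window_snps)
  note("blocks", "n_blocks", length(blocks$blocks))

  # -- phase ----------------------------------------------------------------
  phased <- run_stage("phase", {
    p <- phase_blocks(qc$genotypes, blocks)
    if (is.null(p$haplotypes)) stop("no block could be phased")
    p
  })
  selected <- run_stage("phase", {
    s <- select_frequent_haplotypes(phased$haplotypes,
                                    threshold = config$freq_threshold,
                                    basis = config$freq_basis)
    if (nrow(s) == 0) stop("no haplotype passed the frequency filter > ",
                           config$freq_threshold)
    write_phase_tables(phased, art("haplotypes.tsv"), art("posteriors.tsv"),
                       selected = s)
    s
  })
  note("phase", "freq_threshold", config$freq_threshold)
  note("phase", "freq_basis", config$freq_basis)
  note("phase", "n_haplotypes", nrow(phased$haplotypes))
  note("phase", "n_selected", nrow(selected))

  # -- deregress ------------------------------------------------------------
  proofs <- run_stage("deregress", {
    pr <- deregress(dat$proofs)
    write_trait_table(pr, art("traits_drp.tsv"))
    pr
  })
  note("deregress", "mean_ebv", format(mean(dat$proofs$ebv), digits = 10))

  # -- split ----------------------------------------------------------------
  split <- run_stage("validate", generational_split(proofs, config$train_fraction))
  note("validate", "train_fraction", config$train_fraction)
  note("validate", "n_train", length(split$train))
  note("validate", "n_validation", length(split$validation))

  # -- fit + validate per variant ------------------------------------------
  trait <- trait_spec(config$trait_name, config$heritability,
                      config$genetic_variance,
                      error_variance = config$error_variance)
  train_idx <- match(split$train, proofs$animal_id)
  fits <- list()
  report <- list()
  for (v in config$variants) {
    vdef <- model_variant(v)
    fit_v <- run_stage(paste0("fit_model", v), {
      Z <- build_design_matrix(phased$posteriors, selected,
                               animal_ids = proofs$animal_id,
                               z_kind = vdef$z_kind)
      s2h <- partition_variance(selected, trait$genetic_variance,
                                scheme = vdef$variance_scheme)
      w <- if (config$use_weights) proofs$weight[train_idx] else NULL
      fit <- solve_model(proofs$drp[train_idx], Z[train_idx, , drop = FALSE],
                         s2h, trait$error_variance, weights = w)
      dgv <- predict_dgv(Z, fit)
      utils::write.table(
        data.frame(haplotype = names(fit$effects), effect = fit$effects,
                   variance = s2h, row.names = NULL),
        art(paste0("effects_model", v, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(dgv, art(paste0("dgv_model", v, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(fit = fit, dgv = dgv)
    })
    fits[[paste0("model", v)]] <- fit_v$fit
    rep_v <- validation_report(proofs, fit_v$dgv, split)
    rep_v <- cbind(variant = v, trait = trait$name, rep_v)
    report[[length(report) + 1L]] <- rep_v
    note(paste0("fit_model", v), "z_kind", vdef$z_kind)
    note(paste0("fit_model", v), "variance_scheme", vdef$variance_scheme)
  }
  report <- do.call(rbind, report)
  utils::write.table(report, art("validation_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_df <- do.call(rbind, log_rows)
  utils::write.table(log_df, art("pipeline_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(report = report, fits = fits, selected = selected,
                 log = log_df, out_dir = config$out_dir))
}
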