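#' Pipeline run configuration
#'
#' A single flat configuration drives every pipeline stage; unknown keys are
#' rejected so typos fail loudly. Defaults bake in the analysis constants:
#' chip MAF filter 0.01, sequence MAF filter 0.05, DR2 filter 0.75, LD-score
#' window 50 kbp, LD-pair window 500 kbp with decay strata at 25 and
#' 120-500 kbp.
#'
#' @param ... Key-value overrides of the defaults (see
#'   `pipeline_config_defaults()`), including a nested `simulation` list of
#'   [sim_config()] arguments and a `seed`.
#' @param file Optional YAML file of overrides, applied before `...`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- pipeline_config_defaults()
  apply_overrides <- function(cfg, over, where) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      abort(sprintf("unknown config key(s) %s: %s", where,
                    paste(unknown, collapse = ", ")))
    }
    modifyList(cfg, over)
  }
  if (!is.null(file)) {
    cfg <- apply_overrides(cfg, yaml::read_yaml(file), sprintf("in '%s'", file))
  }
  cfg <- apply_overrides(cfg, list(...), "")
  stopifnot(cfg$maf_chip >= 0, cfg$maf_chip <= 0.5,
            cfg$maf_wgs >= 0, cfg$maf_wgs <= 0.5,
            cfg$dr2_min >= 0, cfg$dr2_min <= 1,
            cfg$ld_score_window > 0, cfg$ld_pair_window > 0,
            cfg$near > 0, cfg$far_lo > cfg$near,
            cfg$far_hi > cfg$far_lo,
            cfg$reml_tolerance > 0, cfg$reml_max_iterations >= 1)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_config_defaults <- function() {
  list(
    output_dir = "h2part-run",
    maf_chip = 0.01,
    maf_wgs = 0.05,
    dr2_min = 0.75,
    ld_score_window = 50000,
    ld_pair_window = 500000,
    near = 25000,
    far_lo = 120000,
    far_hi = 500000,
    reml_tolerance = 1e-8,
    reml_max_iterations = 100,
    reml_variance_floor = 1e-6,
    simulation = list(),
    seed = 1L
  )
}

#' Run the partitioned variance-component pipeline
#'
#' Executes the requested stage (or all stages in order) on simulated data:
#' `simulate` (genotypes + phenotypes, written in PLINK and phenotype-file
#' form), `grm` (subset and chip GRMs in the GCTA binary dialect),
#' `partition` (variant filter, LD scores, quartile subsets), `reml-uni` /
#' `reml-bi` (one- and two-GRM fits), `derived` (heritabilities,
#' correlations, relative covariances, per-variant summaries) and
#' `ldmetrics` (six LD parameters per subset plus their correlation with the
#' across-trait per-variant heritability). All tabular outputs are TSV under
#' `output_dir`, with a `manifest.yaml` recording the configuration, seed
#' and per-stage row counts; identical configurations reproduce identical
#' files.
#'
#' @param stage One of `"simulate"`, `"grm"`, `"partition"`, `"reml-uni"`,
#'   `"reml-bi"`, `"derived"`, `"ldmetrics"`, `"all"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(stage = "all", config = pipeline_config()) {
  stages <- c("simulate", "grm", "partition", "reml-uni", "reml-bi",
              "derived", "ldmetrics")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- paste0(config$output_dir, "/")
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   package_version = as.character(utils::packageVersion("h2part")),
                   stages = list())
  env <- new.env(parent = emptyenv())

  scfg <- do.call(sim_config, modifyList(list(seed = config$seed),
                                         config$simulation))

  ensure_sim <- function() {
    if (!exists("sim", env)) {
      env$sim <- simulate_genotypes(scfg)
      env$ph <- simulate_phenotypes(env$sim$genotypes, env$sim$variants,
                                    scfg, env$sim$subsets)
    }
  }

  tsv <- function(df, name) {
    write.table(df, paste0(out, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  for (st in todo) {
    inform(sprintf("stage %s", st))
    if (st == "simulate") {
      ensure_sim()
      write_plink(env$sim$genotypes, env$sim$variants, paste0(out, "geno"))
      write_phenotypes(env$ph$phenotypes, paste0(out, "pheno.txt"))
      tsv(env$sim$variants, "variants.tsv")
      tsv(env$sim$subsets, "subsets_simulated.tsv")
      tsv(env$ph$realized, "truth_realized.tsv")
      manifest$stages$simulate <- list(
        n_individuals = nrow(env$sim$genotypes),
        n_variants = ncol(env$sim$genotypes))
    } else if (st == "partition") {
      ensure_sim()
      env$filtered <- filter_variants(env$sim$variants,
                                      maf_min = config$maf_wgs,
                                      dr2_min = config$dr2_min)
      env$filtered <- compute_ld_scores(env$sim$genotypes, env$filtered,
                                        window_bp = config$ld_score_window)
      env$quartiles <- dplyr::bind_rows(
        quartile_subsets(env$filtered, "ld_score"),
        quartile_subsets(env$filtered, "snp_num"),
        quartile_subsets(env$filtered, "maf", drop_lowest = TRUE))
      tsv(env$filtered, "variants_filtered.tsv")
      tsv(env$quartiles, "subsets_quartile.tsv")
      manifest$stages$partition <- list(
        n_filtered = nrow(env$filtered),
        n_quartile_subsets = dplyr::n_distinct(env$quartiles$subset))
    } else if (st == "grm") {
      ensure_sim()
      set_ids <- subset_members(env$sim$subsets, scfg$causal_subset)
      chip_ids <- setdiff(colnames(env$sim$genotypes), set_ids)
      env$grm_set <- compute_grm(env$sim$genotypes, set_ids)
      env$grm_chip <- compute_grm(env$sim$genotypes, chip_ids)
      write_grm_gcta(env$grm_set, paste0(out, "grm_set"))
      write_grm_gcta(env$grm_chip, paste0(out, "grm_chip"))
      manifest$stages$grm <- list(
        n_variants_set = env$grm_set$n_variants,
        n_variants_chip = env$grm_chip$n_variants)
    } else if (st == "reml-uni") {
      ensure_grms(env, config, scfg, ensure_sim)
      env$fit_m1 <- fit_univariate(
        env$ph$phenotypes, list(chip = env$grm_chip), trait = "y1",
        max_iterations = config$reml_max_iterations,
        tolerance = config$reml_tolerance,
        variance_floor = config$reml_variance_floor)
      env$fit_m3 <- fit_univariate(
        env$ph$phenotypes, list(set = env$grm_set, chip = env$grm_chip),
        trait = "y1",
        max_iterations = config$reml_max_iterations,
        tolerance = config$reml_tolerance,
        variance_floor = config$reml_variance_floor)
      tsv(dplyr::bind_rows(dplyr::mutate(tidy(env$fit_m1), model = "M1"),
                           dplyr::mutate(tidy(env$fit_m3), model = "M3")),
          "reml_univariate.tsv")
      manifest$stages[["reml-uni"]] <- list(
        m1_converged = env$fit_m1$converged,
        m3_converged = env$fit_m3$converged)
    } else if (st == "reml-bi") {
      ensure_grms(env, config, scfg, ensure_sim)
      if (scfg$n_traits < 2) {
        inform("reml-bi skipped: simulation has a single trait")
        next
      }
      env$fit_m2 <- fit_bivariate(
        env$ph$phenotypes, list(chip = env$grm_chip),
        max_iterations = config$reml_max_iterations,
        tolerance = config$reml_tolerance,
        variance_floor = config$reml_variance_floor)
      env$fit_m4 <- fit_bivariate(
        env$ph$phenotypes, list(set = env$grm_set, chip = env$grm_chip),
        max_iterations = config$reml_max_iterations,
        tolerance = config$reml_tolerance,
        variance_floor = config$reml_variance_floor)
      tsv(dplyr::bind_rows(dplyr::mutate(tidy(env$fit_m2), model = "M2"),
                           dplyr::mutate(tidy(env$fit_m4), model = "M4")),
          "reml_bivariate.tsv")
      manifest$stages[["reml-bi"]] <- list(
        m2_converged = env$fit_m2$converged,
        m4_converged = env$fit_m4$converged)
    } else if (st == "derived") {
      if (is.null(env$fit_m3)) abort("stage 'derived' needs 'reml-uni' first")
      h2_m1 <- heritabilities(env$fit_m1)
      h2_m3 <- heritabilities(env$fit_m3)
      derived <- dplyr::bind_rows(
        dplyr::mutate(h2_m1, model = "M1"),
        dplyr::mutate(h2_m3, model = "M3"))
      if (!is.null(env$fit_m4)) {
        rg <- genetic_correlations(env$fit_m4)
        rc <- relative_covariances(env$fit_m4)
        rg$significant <- significance_flag(rg$estimate, rg$se)
        tsv(rg, "genetic_correlations.tsv")
        tsv(rc, "relative_covariances.tsv")
      }
      set_size <- length(subset_members(env$sim$subsets, scfg$causal_subset))
      pv <- per_variant_summary(
        h2 = tibble(subset = scfg$causal_subset, trait = "y1",
                    h2 = h2_m3$estimate[h2_m3$statistic == "h2_set"]),
        subset_sizes = setNames(set_size, scfg$causal_subset),
        n_traits = 1)
      tsv(derived, "heritabilities.tsv")
      tsv(pv, "per_variant.tsv")
      env$derived <- derived
      env$per_variant <- pv
      manifest$stages$derived <- list(n_statistics = nrow(derived))
    } else if (st == "ldmetrics") {
      ensure_sim()
      subset_names <- unique(env$sim$subsets$subset)
      metrics <- purrr::map_dfr(subset_names, function(nm) {
        ids <- subset_members(env$sim$subsets, nm)
        pr <- ld_pairs(env$sim$genotypes, env$sim$variants, ids,
                       window_bp = config$ld_pair_window)
        dplyr::mutate(
          ld_subset_metrics(pr, env$sim$variants, ids,
                            near_bp = config$near,
                            far_lo_bp = config$far_lo,
                            far_hi_bp = config$far_hi),
          subset = nm, .before = 1)
      })
      tsv(metrics, "ld_metrics.tsv")
      env$ld_metrics <- metrics
      manifest$stages$ldmetrics <- list(n_subsets = length(subset_names))
    }
  }
  yaml::write_yaml(manifest, paste0(out, "manifest.yaml"))
  invisible(list(results = as.list(env), manifest = manifest))
}

ensure_grms <- function(env, config, scfg, ensure_sim) {
  if (is.null(env$grm_set)) {
    ensure_sim()
    set_ids <- subset_members(env$sim$subsets, scfg$causal_subset)
    chip_ids <- setdiff(colnames(env$sim$genotypes), set_ids)
    env$grm_set <- compute_grm(env$sim$genotypes, set_ids)
    env$grm_chip <- compute_grm(env$sim$genotypes, chip_ids)
  }
  invisible(NULL)
}
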