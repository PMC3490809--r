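spp_config_defaults <- function() {
  list(
    # analysis thresholds (headline settings of the study design)
    percentile = 90, fdr = 0.1, delta = 0.2, min_width = 4, min_probes = 2,
    min_ratio = 1.2, margin = 8, permutations = 300, seed = 1,
    background = "rma", delta_rule = "sam", denominator = "plus",
    spread = "sd", direction = "lt1",
    # synthetic study scenario (simulate stage)
    n_unigenes = 8, unigene_length = 400, n_snps = 24, min_spacing = 50,
    genotype_a = "gA", genotype_b = "gB", replicate_count = 3,
    noise_sd = 0.1, probe_effect_sd = 0.8, dim_fraction = 0.05,
    ag_per_bin = 50)
}

#' Pipeline configuration
#'
#' All thresholds of the analysis with their defaults (AG percentile 90,
#' FDR 0.1, delta 0.2, minimum width 4 bp, minimum 2 probes, panel ratio
#' 1.2, validation margin 8 bp) plus the synthetic-study scenario
#' parameters. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `spp_config`.
#' @export
spp_config <- function(...) {
  defaults <- spp_config_defaults()
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == ""))) {
    abort("all configuration values must be named")
  }
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  structure(utils::modifyList(defaults, args), class = "spp_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file of configuration keys.
#' @param config An [spp_config()].
#' @return `read_spp_config()` returns an `spp_config`.
#' @export
read_spp_config <- function(path) {
  do.call(spp_config, yaml::read_yaml(path))
}

#' @rdname read_spp_config
#' @export
write_spp_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

need_file <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("stage '%s': required input '%s' is missing (run the producing stage first)",
                  stage, basename(path)))
  }
  path
}

random_unigenes <- function(n, length, seed) {
  with_seed(seed, {
    setNames(
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
              collapse = ""), character(1)),
      sprintf("u%03d", seq_len(n)))
  })
}

#' Run the SPP detection pipeline
#'
#' Orchestrates the stages `simulate` (synthetic study generation),
#' `preprocess`, `sppdev`, `msa`, `dp` and `validate` with plain-text
#' intermediates in `out_dir`. The configuration (echoed to
#' `config.yaml`) and seed fully determine every output: rerunning with
#' identical settings is bit-identical. A machine-readable run manifest
#' with the configuration hash and per-stage counts is written at the end;
#' progress is logged to stderr.
#'
#' @param config An [spp_config()].
#' @param stages Character subset of
#'   `c("simulate","preprocess","sppdev","msa","dp","validate")`, run in
#'   pipeline order.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = spp_config(),
                         stages = c("simulate", "preprocess", "sppdev",
                                    "msa", "dp", "validate"),
                         out_dir = "spp_run") {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_spp_config(config, file.path(out_dir, "config.yaml"))
  p <- function(...) file.path(out_dir, paste0(...))
  counts <- list()
  log <- function(fmt, ...) message(sprintf(paste0("[spptools] ", fmt), ...))

  if ("simulate" %in% stages) {
    log("simulate: %d unigenes x %d bp, %d planted SNPs",
        config$n_unigenes, config$unigene_length, config$n_snps)
    seqs <- random_unigenes(config$n_unigenes, config$unigene_length,
                            config$seed)
    layout <- tile_unigenes(seqs, ag_per_bin = config$ag_per_bin,
                            seed = config$seed)
    variants <- plant_pairwise_variants(unigene_lengths(layout),
                                        config$n_snps,
                                        genotype = config$genotype_b,
                                        min_spacing = config$min_spacing,
                                        seed = config$seed)
    panel <- tibble(genotype = c(config$genotype_a, config$genotype_b))
    params <- spp_sim_params(noise_sd = config$noise_sd,
                             probe_effect_sd = config$probe_effect_sd,
                             replicate_count = config$replicate_count,
                             dim_fraction = config$dim_fraction,
                             seed = config$seed)
    sim <- simulate_panel(layout, panel, variants, params)
    write_layout(layout, p("layout.tsv"))
    write_intensity(sim$intensity, p("intensity_raw.tsv"))
    readr::write_csv(sim$samples, p("samples.csv"), progress = FALSE)
    write_truth(variants, panel, p("truth.vcf"))
    writeLines(paste0(">", names(seqs), "\n", seqs), p("unigenes.fasta"))
    counts$simulate <- list(probes = nrow(layout), arrays = nrow(sim$samples),
                            variants = nrow(variants))
  }

  if ("preprocess" %in% stages) {
    log("preprocess: background '%s', quantile normalization, AG percentile %g",
        config$background, config$percentile)
    raw <- read_intensity(need_file(p("intensity_raw.tsv"), "preprocess"),
                          state = "raw")
    layout <- read_layout(need_file(p("layout.tsv"), "preprocess"))
    norm <- raw %>%
      background_correct(method = config$background) %>%
      quantile_normalize()
    thresholds <- ag_percentile(norm, layout, percentile = config$percentile)
    mask <- informative_mask(norm, layout, thresholds)
    write_intensity(norm, p("intensity_norm.tsv"))
    readr::write_tsv(thresholds, p("thresholds.tsv"), progress = FALSE)
    write_mask(mask, p("mask.tsv"))
    counts$preprocess <- list(
      informative = sum(vapply(mask[array_ids(mask)], sum, numeric(1))))
  }

  load_core <- function(stage) {
    list(
      norm = read_intensity(need_file(p("intensity_norm.tsv"), stage),
                            state = "normalized"),
      mask = read_mask(need_file(p("mask.tsv"), stage)),
      layout = read_layout(need_file(p("layout.tsv"), stage)),
      samples = readr::read_csv(need_file(p("samples.csv"), stage),
                                col_types = readr::cols(), progress = FALSE))
  }

  if ("sppdev" %in% stages) {
    log("sppdev: permutation test (B = %d), FDR cutoff %g",
        config$permutations, config$fdr)
    core <- load_core("sppdev")
    dev <- compute_sfpdev(core$norm, core$mask, core$layout)
    windows <- sppdev_windows(dev, core$layout)
    test <- permutation_pvalues(windows, core$samples, config$genotype_a,
                                config$genotype_b, B = config$permutations,
                                seed = config$seed)
    calls <- call_spps(test, fdr_cutoff = config$fdr,
                       min_width = config$min_width,
                       min_probes = config$min_probes,
                       direction = config$direction)
    readr::write_tsv(test, p("sppdev_test.tsv"), progress = FALSE)
    write_calls(calls, p("sppdev_calls.bed"))
    counts$sppdev <- list(windows = nrow(test), calls = nrow(calls))
  }

  if ("msa" %in% stages) {
    log("msa: delta %g (%s rule), %d permutations", config$delta,
        config$delta_rule, config$permutations)
    core <- load_core("msa")
    lm <- position_log_means(core$norm, core$mask, core$layout)
    calls <- msa_call(lm, core$samples, config$genotype_a, config$genotype_b,
                      delta = config$delta,
                      permutations = min(config$permutations, 200),
                      seed = config$seed, min_width = config$min_width,
                      min_probes = config$min_probes,
                      delta_rule = config$delta_rule,
                      denominator = config$denominator,
                      spread = config$spread)
    write_calls(calls, p("msa_calls.bed"))
    counts$msa <- list(calls = nrow(calls),
                       fdr_estimate = attr(calls, "fdr_estimate"))
  }

  if ("dp" %in% stages) {
    log("dp: bimodal genotyping (min ratio %g)", config$min_ratio)
    core <- load_core("dp")
    dev <- compute_sfpdev(core$norm, core$mask, core$layout)
    windows <- sppdev_windows(dev, core$layout)
    markers <- dp_genotype(windows, core$samples,
                           min_ratio = config$min_ratio)
    filtered <- filter_panel_markers(markers, min_probes = config$min_probes,
                                     min_width = config$min_width,
                                     min_ratio = config$min_ratio)
    haps <- collapse_haplotypes(filtered)
    readr::write_tsv(filtered, p("dp_markers.tsv"), progress = FALSE)
    readr::write_tsv(haps, p("dp_haplotypes.tsv"), progress = FALSE)
    export_binary_markers(filtered, p("dp_binary.tsv"))
    counts$dp <- list(markers = nrow(filtered), haplotypes = nrow(haps))
  }

  if ("validate" %in% stages) {
    truth <- read_truth_vcf(need_file(p("truth.vcf"), "validate"))
    unigenes <- read_unigenes(need_file(p("unigenes.fasta"), "validate"))
    for (m in c("sppdev", "msa")) {
      tsv <- p(m, "_calls.tsv")
      if (!file.exists(tsv)) next
      calls <- read_calls(tsv)
      screened <- duplicate_locus_screen(calls, unigenes,
                                         margin = config$margin)
      kept <- filter(screened, !.data$duplicated)
      scored <- score_calls(kept, truth, margin = config$margin)
      readr::write_tsv(scored, p("validation_", m, ".tsv"), progress = FALSE)
      counts[[paste0("validate_", m)]] <- list(
        calls = nrow(scored),
        observed_fdr = attr(scored, "observed_fdr"),
        sensitivity = call_sensitivity(kept, truth, margin = config$margin))
      log("validate(%s): observed FDR %.3f, sensitivity %.3f", m,
          attr(scored, "observed_fdr"),
          counts[[paste0("validate_", m)]]$sensitivity)
    }
  }

  manifest <- list(package = "spptools",
                   version = as.character(utils::packageVersion("spptools")),
                   config = unclass(config),
                   config_hash = rlang::hash(unclass(config)),
                   stages = stages, counts = counts)
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
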