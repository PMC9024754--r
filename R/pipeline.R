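# Pipeline wiring: one configuration object, one global seed fanned out to
# per-stage seeds, JSON/CSV artifacts. This is the engine behind the
# command-line interface in inst/cli/tmsri.

#' Assemble a pipeline run configuration
#'
#' @param library_path Path to a library table (CSV/TSV/SDF); may be the
#'   output path of the `synth generate` stage.
#' @param spectra_path Optional MSP path (EI candidate simulation).
#' @param output_dir Directory where stage artifacts are written.
#' @param seed Global integer seed; every stage derives its own seed from it
#'   so stages can be re-run independently yet reproducibly.
#' @param fp_class,n_bits Fingerprint configuration.
#' @param backend Backend kind for model stages.
#' @param n_repeats,train_fraction Split-plan settings.
#' @param n_base Synthetic-library size for `synth generate`.
#' @param mode,n_seeds,ppm_tol,sim_threshold,candidate_repeats Candidate
#'   simulation settings.
#' @param threshold Filtering threshold (percent) for the confusion report.
#' @param shift_low Lower TMS level for `tms-shift fit`.
#' @param similarity,query_threshold `cpf query` inputs.
#' @return A `run_config` list.
#' @export
run_config <- function(library_path = NULL, spectra_path = NULL,
                       output_dir = ".", seed = 1L,
                       fp_class = "ecfp4", n_bits = 1024L,
                       backend = "svm_linear", n_repeats = 20L,
                       train_fraction = 0.75, n_base = 250L,
                       mode = "ci", n_seeds = NULL, ppm_tol = 10,
                       sim_threshold = 0.8, candidate_repeats = 20L,
                       threshold = 3, shift_low = 1L,
                       similarity = NULL, query_threshold = NULL) {
  structure(list(library_path = library_path, spectra_path = spectra_path,
                 output_dir = output_dir, seed = as.integer(seed),
                 fp_class = fp_class, n_bits = as.integer(n_bits),
                 backend = backend, n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction,
                 n_base = as.integer(n_base), mode = mode,
                 n_seeds = n_seeds, ppm_tol = ppm_tol,
                 sim_threshold = sim_threshold,
                 candidate_repeats = as.integer(candidate_repeats),
                 threshold = threshold, shift_low = as.integer(shift_low),
                 similarity = similarity, query_threshold = query_threshold),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take the [run_config()] defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

config_hash <- function(config) {
  # hash the scientific settings only, not filesystem locations
  keep <- setdiff(names(config),
                  c("library_path", "spectra_path", "output_dir"))
  s <- paste(vapply(config[keep],
                    function(v) paste(format(v), collapse = ","),
                    character(1)),
             collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

write_artifact <- function(obj, config, path) {
  obj$config_hash <- config_hash(config)
  obj$seed <- config$seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

load_library_for <- function(config) {
  if (is.null(config$library_path))
    stop("config does not name a library path")
  if (!file.exists(config$library_path))
    stop("library path does not exist: ", config$library_path)
  fmt <- tolower(tools::file_ext(config$library_path))
  if (!fmt %in% c("csv", "tsv", "sdf")) fmt <- "csv"
  read_library(config$library_path, fmt)
}

#' Run one pipeline stage
#'
#' Stages: `"synth generate"`, `"library validate"`, `"fp compute"`,
#' `"model train"`, `"model evaluate"`, `"tms-shift fit"`, `"cpf build"`,
#' `"cpf query"`, `"candidates simulate"`. Every JSON artifact embeds the
#' configuration hash and the global seed.
#'
#' @param config A [run_config()] or a YAML path.
#' @param command Stage name (see above).
#' @return Named list of artifact paths (or values for query commands),
#'   invisibly.
#' @export
run_pipeline <- function(config, command) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)

  stage_seed <- function(stage) derive_seed(config$seed, stage)

  switch(command,
    "synth generate" = {
      gen <- generate_library(generator_params(
        n_base_metabolites = config$n_base,
        rng_seed = stage_seed("synth")))
      lib_path <- config$library_path %||% out("library.csv")
      write_library(gen$library, lib_path, "csv")
      spectra <- generate_spectra(gen$library, gen$truth)
      msp_path <- config$spectra_path %||% out("library.msp")
      write_msp(spectra, msp_path)
      truth_path <- out("truth.json")
      write_artifact(list(truth = gen$truth), config, truth_path)
      invisible(list(library = lib_path, spectra = msp_path,
                     truth = truth_path))
    },
    "library validate" = {
      lib <- load_library_for(config)
      path <- out("library_report.json")
      write_artifact(list(
        n_records = nrow(lib),
        n_bases = length(unique(lib$base_id)),
        provenance = attr(lib, "provenance"),
        discards = attr(lib, "discards")), config, path)
      invisible(list(report = path))
    },
    "fp compute" = {
      lib <- load_library_for(config)
      fps <- compute_fingerprints(
        lib$smiles, fingerprint_config(config$fp_class, config$n_bits))
      path <- out("fingerprints.csv")
      export_fingerprints(fps, lib$record_id, path)
      hex_path <- out("fingerprints_hex.csv")
      utils::write.table(
        data.frame(record_id = lib$record_id, fp_hex = fingerprint_hex(fps)),
        hex_path, sep = ",", row.names = FALSE, quote = FALSE)
      invisible(list(fingerprints = path, hex = hex_path))
    },
    "model train" = {
      lib <- load_library_for(config)
      fps <- compute_fingerprints(
        lib$smiles, fingerprint_config(config$fp_class, config$n_bits))
      fit <- with_seed(stage_seed("train"),
                       ri_model(fps, lib$ri, backend = config$backend))
      model_path <- out("model.rds")
      saveRDS(fit, model_path)
      meta_path <- out("model.json")
      write_artifact(list(backend = config$backend,
                          n_records = nrow(lib),
                          fp_class = config$fp_class,
                          n_bits = config$n_bits), config, meta_path)
      invisible(list(model = model_path, meta = meta_path))
    },
    "model evaluate" = {
      lib <- load_library_for(config)
      proto <- run_protocol(
        lib, fingerprint_config(config$fp_class, config$n_bits),
        specs = list(config$backend),
        plan = split_plan(config$n_repeats, config$train_fraction,
                          stage_seed("protocol")))
      res <- proto$results[[config$backend]]
      csv_path <- out("predictions.csv")
      utils::write.table(res, csv_path, sep = ",", row.names = FALSE,
                         quote = FALSE)
      s <- error_summary(res)
      json_path <- out("evaluation.json")
      write_artifact(list(backend = config$backend, n = s$n, mae = s$mae,
                          mdae = s$mdae, mape = s$mape, mdape = s$mdape),
                     config, json_path)
      invisible(list(predictions = csv_path, summary = json_path))
    },
    "tms-shift fit" = {
      lib <- load_library_for(config)
      pairs <- pair_counterparts(lib, config$shift_low)
      model <- tms_shift(pairs)
      inc <- mean_ri_increase(pairs)
      loo <- loo_shift_errors(pairs)
      path <- out("tms_shift.json")
      write_artifact(list(
        n_low = config$shift_low, slope = model$slope,
        intercept = model$intercept, n_pairs = model$n_pairs,
        mean_increase_pct = as.numeric(inc),
        median_increase_pct = attr(inc, "median_increase_pct"),
        loo = list(mae = loo$mae, mdae = loo$mdae, mape = loo$mape,
                   mdape = loo$mdape)), config, path)
      invisible(list(shift = path))
    },
    "cpf build" = {
      lib <- load_library_for(config)
      proto <- run_protocol(
        lib, fingerprint_config(config$fp_class, config$n_bits),
        specs = list(config$backend),
        plan = split_plan(config$n_repeats, config$train_fraction,
                          stage_seed("protocol")),
        with_similarity = TRUE)
      cpf <- build_cpf(proto$results[[config$backend]])
      path <- out("cpf.json")
      write_artifact(list(bins = cpf$bins, errors = cpf$errors),
                     config, path)
      invisible(list(cpf = path))
    },
    "cpf query" = {
      if (is.null(config$similarity) || is.null(config$query_threshold))
        stop("cpf query requires 'similarity' and 'query_threshold'")
      art <- jsonlite::read_json(out("cpf.json"), simplifyVector = TRUE)
      cpf <- structure(list(bins = art$bins,
                            errors = lapply(art$errors, as.numeric),
                            sizes = vapply(art$errors, length, integer(1))),
                       class = "error_cpf")
      p <- error_probability(cpf, config$similarity, config$query_threshold)
      cat(sprintf("P(error < %g%% | similarity %.3f) = %.4f\n",
                  config$query_threshold, config$similarity, p))
      invisible(list(probability = p))
    },
    "candidates simulate" = {
      lib <- load_library_for(config)
      spectra <- if (config$mode == "ei") {
        if (is.null(config$spectra_path))
          stop("EI simulation requires a spectra path")
        read_spectra(config$spectra_path)
      }
      fps <- compute_fingerprints(
        lib$smiles, fingerprint_config(config$fp_class, config$n_bits))
      rownames(fps) <- lib$record_id
      ri <- setNames(lib$ri, lib$record_id)
      # synthetic spectral clusters run larger than curated-library ones,
      # so the EI default stays well inside the 80% training-coverage floor
      n_seeds <- config$n_seeds %||% if (config$mode == "ei") 20L else 20L
      ranked_all <- list()
      for (rep in seq_len(config$candidate_repeats)) {
        cs <- build_candidate_sets(
          lib, config$mode, n_seeds = n_seeds,
          rng_seed = stage_seed(paste0("cand", rep)),
          ppm_tol = config$ppm_tol, sim_threshold = config$sim_threshold,
          spectra = spectra)
        fit <- with_seed(stage_seed(paste0("candfit", rep)),
                         ri_model(fps[cs$train_ids, , drop = FALSE],
                                  ri[cs$train_ids],
                                  backend = config$backend))
        eval_ids <- setdiff(lib$record_id, cs$train_ids)
        pred <- setNames(
          predict(fit, fps[eval_ids, , drop = FALSE]), eval_ids)
        ranked_all <- c(ranked_all,
                        lapply(cs$sets, rank_candidates,
                               predicted_ri = pred))
      }
      topk <- topk_summary(ranked_all)
      conf <- classify_at_threshold(ranked_all, config$threshold)
      roc <- roc_curve(ranked_all)
      roc_path <- out(sprintf("roc_%s.csv", config$mode))
      utils::write.table(
        data.frame(threshold_pct = roc$thresholds, tpr = roc$tpr,
                   fpr = roc$fpr),
        roc_path, sep = ",", row.names = FALSE, quote = FALSE)
      json_path <- out(sprintf("candidates_%s.json", config$mode))
      write_artifact(list(
        mode = config$mode, repeats = config$candidate_repeats,
        n_sets = length(ranked_all), topk = topk,
        confusion = list(threshold = conf$threshold, tp = conf$tp,
                         fp = conf$fp, tn = conf$tn, fn = conf$fn),
        auc = roc$auc), config, json_path)
      invisible(list(summary = json_path, roc = roc_path))
    },
    stop("unknown pipeline command: ", command)
  )
}
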