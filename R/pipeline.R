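# 32-bit FNV-1a over the serialized config (minus the output location, so
# reruns of the same analysis hash identically); stamped into every output
config_hash <- function(config) {
  config$output_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    b <- b %% 256
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay in double range
    lo <- h %% 2^16
    hi <- h %/% 2^16
    h <- (lo * 16777619 + ((hi * 16777619) %% 2^16) * 2^16) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

write_csv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Pipeline configuration
#'
#' Structured, fully serializable description of one end-to-end run. The
#' resolved configuration is written verbatim (YAML) into the run directory.
#'
#' @param input either `list(type = "synth", spec = synth_spec(...))` or
#'   `list(type = "dir", path = <cohort directory>)`.
#' @param output_dir run directory (created; must not contain a previous run).
#' @param mse an [mse_params()].
#' @param classify list with `feature_sets` (list of [feature_set_spec()]),
#'   `repeats`, `folds`, `seed`.
#' @param bands band definitions (default [eeg_bands()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(type = "synth", spec = synth_spec()),
                            output_dir,
                            mse = mse_params(max_scale = 5L),
                            classify = list(
                              feature_sets = list(
                                feature_set_spec("c1", "c1"),
                                feature_set_spec("NS_alpha", "NS_alpha"),
                                feature_set_spec("c1+NS_alpha",
                                                 c("c1", "NS_alpha"))
                              ),
                              repeats = 20L, folds = 5L, seed = 1L
                            ),
                            bands = eeg_bands()) {
  if (!input$type %in% c("synth", "dir")) {
    stop("input$type must be 'synth' or 'dir'")
  }
  structure(
    list(input = input, output_dir = output_dir, mse = mse,
         classify = classify, bands = bands),
    class = "pipeline_config"
  )
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] %s done in %.1f s", format(Sys.time(), "%H:%M:%S"),
                  stage, as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Stage order: acquire cohort (generate or read) -> per-subject features
#' (multifractal, entropy, connectivity, gamma power) -> group statistics
#' (mixed ANOVA with GG correction, ANCOVA with the gamma-power covariate,
#' BH-corrected post-hoc t-tests, Spearman NS-complexity correlations) ->
#' classification (repeated-CV AUC per feature set). Writes tidy CSVs, the
#' verbatim config (YAML) and a JSON run summary into `output_dir`; every
#' CSV carries the config hash as a leading comment line.
#'
#' @param config a [pipeline_config()].
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$output_dir
  if (is.null(dir)) stop("output_dir is required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  yaml::write_yaml(serialize_config(config), file.path(dir, "config.yaml"))

  t0 <- as.numeric(Sys.time())
  if (config$input$type == "synth") {
    cohort <- generate_cohort(config$input$spec)
  } else {
    if (!dir.exists(config$input$path)) {
      stop("input directory does not exist: ", config$input$path)
    }
    cohort <- read_cohort(config$input$path)
  }
  stage_log("cohort", t0)

  t0 <- as.numeric(Sys.time())
  features <- feature_table(cohort, bands = config$bands,
                            mse_scales = config$mse$max_scale)
  write_csv_stamped(features, file.path(dir, "features.csv"), hash)
  stage_log("features", t0)

  t0 <- as.numeric(Sys.time())
  channels <- montage_16()[seq_len(nrow(cohort[[1]]$samples))]
  block <- function(prefix) {
    as.matrix(features[, paste0(prefix, "_", channels)])
  }
  gamma_cov <- rowMeans(block("gammapow"))
  anova_rows <- list()
  posthoc_rows <- list()
  for (measure in c("c1", "absc2", "entropy",
                    paste0("ns_", config$bands$name))) {
    Y <- block(measure)
    an <- mixed_anova(Y, features$group, list(node = ncol(Y)))
    an$measure <- measure
    an$covariate <- "none"
    anova_rows[[length(anova_rows) + 1]] <- an
    ph <- posthoc_ttests(Y, features$group)
    posthoc_rows[[length(posthoc_rows) + 1]] <- data.frame(
      measure = measure, channel = channels,
      t = ph$t_values, p = ph$raw_p, significant = ph$significant
    )
  }
  for (measure in c("c1", "absc2")) {
    an <- ancova_covariate(block(measure), features$group,
                           list(node = length(channels)), gamma_cov)
    an$measure <- measure
    an$covariate <- "gamma_relative_power"
    anova_rows[[length(anova_rows) + 1]] <- an
  }
  write_csv_stamped(do.call(rbind, anova_rows),
                    file.path(dir, "anova.csv"), hash)
  write_csv_stamped(do.call(rbind, posthoc_rows),
                    file.path(dir, "posthoc.csv"), hash)

  spearman_rows <- list()
  for (band in config$bands$name) {
    for (index in c("c1", "absc2")) {
      for (grp in unique(features$group)) {
        sel <- features$group == grp
        if (sum(sel) < 4) next
        sp <- spearman_ns_complexity(block(paste0("ns_", band))[sel, ],
                                     block(index)[sel, ])
        spearman_rows[[length(spearman_rows) + 1]] <- data.frame(
          band = band, index = index, group = grp, channel = channels,
          R = sp$R, p = sp$raw_p, significant = sp$significant
        )
      }
    }
  }
  write_csv_stamped(do.call(rbind, spearman_rows),
                    file.path(dir, "spearman.csv"), hash)
  stage_log("stats", t0)

  t0 <- as.numeric(Sys.time())
  roc_rows <- lapply(config$classify$feature_sets, function(fs) {
    af <- assemble_features(features, fs)
    r <- cv_auc(af$x, af$y, n_components = fs$n_components,
                repeats = config$classify$repeats,
                folds = config$classify$folds,
                seed = config$classify$seed, name = fs$name)
    data.frame(feature_set = fs$name, auc_mean = r$auc_mean,
               auc_sd = r$auc_sd, repeats = r$repeats, folds = r$folds,
               seed = r$seed)
  })
  write_csv_stamped(do.call(rbind, roc_rows), file.path(dir, "roc.csv"), hash)
  stage_log("classify", t0)

  summary <- list(
    config_hash = hash,
    n_subjects = length(cohort),
    n_younger = sum(features$group == "younger"),
    n_older = sum(features$group == "older"),
    outputs = c("features.csv", "anova.csv", "posthoc.csv",
                "spearman.csv", "roc.csv")
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# flatten config into plain lists for YAML round-tripping
serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  strip(unclass(config))
}
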