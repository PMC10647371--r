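# Orchestration: a serializable run configuration and the full experiment
# (dataset -> cross-validated comparison of the eight classifier variants
# with a Wilcoxon column against the fused CNN).

.run_defaults <- function() {
  list(n_per_class = 50L, originals_per_class = 5L, delta = 1,
       bands = 120L, scene_dims = c(200L, 300L), fish_scale = 0.5,
       noise_sd = 0.02, lc_prime = 100L, k = 5L, seed = 1L,
       epochs = 10L, patience = 5L,
       models = c("cnn-fused", "cnn-spectral", "cnn-spatial",
                  "svm-spectral", "svm-pixels", "svm-pixels+spectral",
                  "svm-hog", "svm-hog+spectral"),
       group_by_source = FALSE, learning_curve_sizes = NULL,
       version = "pelagiscan-0.1.0")
}

#' Build a run configuration
#'
#' Named arguments override the defaults; unknown keys are rejected. The
#' configuration round-trips through JSON ([write_run_config()],
#' [read_run_config()]) so every number in a report is reproducible from
#' the manifest and seed alone.
#'
#' @param ... overrides of the default fields.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- .run_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a run configuration to JSON
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.model_spec_for <- function(name, cfg) {
  tc <- train_config(epochs = cfg$epochs, patience = cfg$patience,
                     seed = cfg$seed)
  switch(name,
         `cnn-fused` = model_spec_cnn("fused", tc),
         `cnn-spectral` = model_spec_cnn("spectral", tc),
         `cnn-spatial` = model_spec_cnn("spatial", tc),
         `svm-spectral` = model_spec_svm("spectral"),
         `svm-pixels` = model_spec_svm("pixels"),
         `svm-pixels+spectral` = model_spec_svm("pixels+spectral"),
         `svm-hog` = model_spec_svm("hog"),
         `svm-hog+spectral` = model_spec_svm("hog+spectral"),
         stop("unknown model ", name))
}

#' Run the full synthetic classification experiment
#'
#' Builds the balanced dataset, cross-validates every requested classifier
#' variant, and assembles the comparison table (Accuracy, Precision,
#' Recall, F1 in percent) with a per-model Wilcoxon signed-rank p-value of
#' its pooled per-sample zero-one losses against the fused CNN.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional output directory (`report.json`,
#'   `comparison_table.csv`, `manifest.json`, optional
#'   `learning_curves.csv`).
#' @param dataset optional pre-built [fish_dataset()] (skips generation).
#' @return List with `table` (data frame), `cv` (named list of
#'   [kfold_cv()] reports), `dataset`, `config`.
#' @export
run_full_experiment <- function(cfg = run_config(), out_dir = NULL,
                                dataset = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(dataset)) {
    sc <- scene_spec(dims = cfg$scene_dims, bands = cfg$bands,
                     delta = cfg$delta, fish_scale = cfg$fish_scale,
                     noise_sd = cfg$noise_sd)
    dataset <- generate_experiment(
      n_per_class = cfg$n_per_class,
      originals_per_class = cfg$originals_per_class, scene = sc,
      lc_prime = cfg$lc_prime, seed = cfg$seed)
  }
  cv <- list()
  for (nm in cfg$models) {
    cv[[nm]] <- kfold_cv(dataset, k = cfg$k, .model_spec_for(nm, cfg),
                         seed = cfg$seed,
                         group_by_source = isTRUE(cfg$group_by_source))
  }
  ref <- cv[["cnn-fused"]]
  tab <- do.call(rbind, lapply(cfg$models, function(nm) {
    r <- cv[[nm]]
    p <- NA_real_
    if (!is.null(ref) && nm != "cnn-fused") {
      a <- ref$pooled[order(ref$pooled$id), "loss"]
      b <- r$pooled[order(r$pooled$id), "loss"]
      p <- wilcoxon_compare(a, b)$p.value
    }
    data.frame(Classifier = r$label,
               Accuracy = r$mean_metrics[["Accuracy"]],
               Precision = r$mean_metrics[["Precision"]],
               Recall = r$mean_metrics[["Recall"]],
               F1 = r$mean_metrics[["F1"]],
               p_vs_fused = p,
               significant = !is.na(p) & p < 0.05,
               stringsAsFactors = FALSE)
  }))
  curves <- NULL
  if (length(cfg$learning_curve_sizes)) {
    curves <- learning_curve(.model_spec_for(cfg$models[1], cfg), dataset,
                             cfg$learning_curve_sizes, seed = cfg$seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "comparison_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(cfg), table = tab,
           per_fold = lapply(cv, function(r)
             lapply(r$per_fold, function(m)
               c(Accuracy = m$accuracy, m$weighted)))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write_run_config(cfg, file.path(out_dir, "manifest.json"))
    if (!is.null(curves))
      utils::write.csv(curves, file.path(out_dir, "learning_curves.csv"),
                       row.names = FALSE)
  }
  list(table = tab, cv = cv, dataset = dataset, config = cfg,
       learning_curves = curves)
}
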