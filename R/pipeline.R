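#' Apply any qsarpipe model to a table of inputs
#'
#' Uniform prediction front-end: accepts a fitted `hm_linear_model`,
#' `gep_model`, `comsia_model`, or the strings `"ref_linear"` /
#' `"ref_gep"` for the built-in reference quinazoline models (which
#' expect columns `avg_erc`, `hdsa2_tmsa`, `min_nro` or `x`, `y`, `z`).
#'
#' @param model model object or reference-model name.
#' @param newdata data.frame of descriptor values (or list of
#'   molecules for a `comsia_model`).
#' @return data.frame with an `id` column (row names or `newdata$id`)
#'   and a `prediction` column; empty input yields an empty frame with
#'   the same header.
#' @export
predict_table <- function(model, newdata) {
  ids <- if (is.data.frame(newdata) && !is.null(newdata$id)) {
    as.character(newdata$id)
  } else if (is.data.frame(newdata)) {
    as.character(seq_len(nrow(newdata)))
  } else {
    names(newdata)
  }
  if (is.data.frame(newdata)) newdata$id <- NULL
  grab <- function(df, main, alt) {
    if (main %in% names(df)) df[[main]]
    else if (alt %in% names(df)) df[[alt]]
    else stop("missing input column: ", main, call. = FALSE)
  }
  pred <- if (identical(model, "ref_linear")) {
    if (nrow(newdata) == 0) numeric(0) else
      ref_linear_model(grab(newdata, "avg_erc", "x"),
                       grab(newdata, "hdsa2_tmsa", "y"),
                       grab(newdata, "min_nro", "z"))
  } else if (identical(model, "ref_gep")) {
    if (nrow(newdata) == 0) numeric(0) else
      ref_gep_model(grab(newdata, "x", "avg_erc"),
                    grab(newdata, "y", "hdsa2_tmsa"),
                    grab(newdata, "z", "min_nro"))
  } else if (inherits(model, c("hm_linear_model", "gep_model",
                               "comsia_model", "pls_model"))) {
    if (is.data.frame(newdata) && nrow(newdata) == 0) numeric(0) else
      stats::predict(model, newdata)
  } else {
    stop("unsupported model type", call. = FALSE)
  }
  data.frame(id = ids, prediction = as.numeric(pred),
             stringsAsFactors = FALSE)
}

# serialise a fitted model to a plain list for JSON output
model_to_list <- function(model) {
  if (inherits(model, "hm_linear_model")) {
    list(type = "linear",
         descriptor_names = model$descriptor_names,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept,
         stats = list(r2 = model$r2, f = model$f_stat, s2 = model$s2,
                      t_values = as.list(model$t_values),
                      r2_cv = model$r2_cv))
  } else if (inherits(model, "gep_model")) {
    list(type = "gep",
         expression = model$expression,
         chromosome = unclass(model$chromosome),
         stats = list(fitness = model$fitness, rmse = model$rmse,
                      r2 = model$r2))
  } else stop("unsupported model type", call. = FALSE)
}

write_stable_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the QSAR pipeline end to end
#'
#' Orchestrates the study workflow on synthetic or user-supplied data:
#' `simulate` (planted-signal descriptor set) -> `split` (train/test)
#' -> `hm` (heuristic linear-model selection) -> `gep` (symbolic
#' regression whose terminal set is the descriptors selected by the HM
#' stage, mirroring the 2D-QSAR hand-off) -> `validate` (external
#' validation of both models on the held-out set).  Every artefact is
#' written to `out_dir` as CSV/JSON together with a manifest recording
#' the seed, stage summaries, and md5 checksums of the inputs; reruns
#' with identical config produce byte-identical files.
#'
#' @param config named list (or path to a JSON file) with optional
#'   blocks `simulate` (arguments of [gen_descriptor_set()]), `split`
#'   (`ratio_train`), `hm` (arguments of [hm_config()]), `gep`
#'   (`head_length`, `n_genes`, `population_size`, `max_generations`,
#'   `target_r2`, `rates`), plus top-level `stages` (default all),
#'   `seed`, and `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return The manifest, invisibly a list; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stages <- config$stages %||% c("simulate", "split", "hm", "gep", "validate")
  seed <- config$seed %||% 1
  out_dir <- out_dir %||% config$out_dir %||% stop("`out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list(),
                   package_version = as.character(utils::packageVersion("qsarpipe")))
  inputs <- character()

  fail <- function(stage, e) {
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  }

  D <- NULL; y <- NULL
  if ("simulate" %in% stages) {
    sim <- tryCatch(
      do.call(gen_descriptor_set,
              utils::modifyList(list(seed = seed),
                                as.list(config$simulate %||% list()))),
      error = function(e) fail("simulate", e))
    D <- sim$descriptors; y <- sim$activity
    write_descriptors(D, file.path(out_dir, "descriptors.csv"))
    utils::write.csv(data.frame(id = rownames(D), activity = y),
                     file.path(out_dir, "activity.csv"), row.names = FALSE,
                     quote = FALSE)
    inputs <- c(inputs, file.path(out_dir, c("descriptors.csv", "activity.csv")))
    manifest$stages$simulate <- list(
      n_compounds = nrow(D), n_descriptors = ncol(D),
      informative = sim$truth$informative)
  } else {
    if (is.null(config$descriptors) || is.null(config$activity)) {
      stop("without the simulate stage, `config$descriptors` and ",
           "`config$activity` file paths are required", call. = FALSE)
    }
    D <- read_descriptors(config$descriptors)
    act <- utils::read.csv(config$activity)
    y <- act$activity
    inputs <- c(inputs, config$descriptors, config$activity)
  }

  train_idx <- seq_len(nrow(D))
  test_idx <- integer()
  if ("split" %in% stages) {
    ratio <- config$split$ratio_train %||% 0.8
    tab <- compound_table(rownames(D), rep(1, nrow(D)))
    tab <- tryCatch(split_table(tab, ratio, seed = seed),
                    error = function(e) fail("split", e))
    train_idx <- which(tab$split == "train")
    test_idx <- which(tab$split == "test")
    utils::write.csv(data.frame(id = rownames(D), split = tab$split),
                     file.path(out_dir, "split.csv"), row.names = FALSE,
                     quote = FALSE)
    manifest$stages$split <- list(n_train = length(train_idx),
                                  n_test = length(test_idx))
  }

  hm_model <- NULL
  if ("hm" %in% stages) {
    cfg <- do.call(hm_config, as.list(config$hm %||% list()))
    res <- tryCatch(hm_search(D[train_idx, , drop = FALSE], y[train_idx], cfg),
                    error = function(e) fail("hm", e))
    hm_model <- best_model(res)
    write_stable_json(model_to_list(hm_model),
                      file.path(out_dir, "hm_model.json"))
    manifest$stages$hm <- list(
      selected = hm_model$descriptor_names,
      r2 = hm_model$r2, r2_cv = hm_model$r2_cv)
  }

  gep_model <- NULL
  if ("gep" %in% stages) {
    terms <- if (!is.null(hm_model)) hm_model$descriptor_names else colnames(D)
    gcfg_args <- utils::modifyList(
      list(terminals = terms, seed = seed),
      as.list(config$gep %||% list()))
    gcfg <- do.call(gep_config, gcfg_args)
    Xg <- D[train_idx, terms, drop = FALSE]
    gep_model <- tryCatch(gep_evolve(Xg, y[train_idx], gcfg),
                          error = function(e) fail("gep", e))
    write_stable_json(model_to_list(gep_model),
                      file.path(out_dir, "gep_model.json"))
    utils::write.csv(gep_model$log, file.path(out_dir, "gep_log.csv"),
                     row.names = FALSE)
    manifest$stages$gep <- list(expression = gep_model$expression,
                                r2 = gep_model$r2, rmse = gep_model$rmse)
  }

  if ("validate" %in% stages && length(test_idx)) {
    reports <- list()
    ytr_mean <- mean(y[train_idx])
    for (nm in c("hm", "gep")) {
      model <- switch(nm, hm = hm_model, gep = gep_model)
      if (is.null(model)) next
      pred <- tryCatch(
        stats::predict(model,
                       as.data.frame(D[test_idx, , drop = FALSE])),
        error = function(e) fail("validate", e))
      ok <- is.finite(pred)
      if (sum(ok) >= 2) {
        rep_ <- validation_report(y[test_idx][ok], pred[ok], ytr_mean)
        reports[[nm]] <- unclass(rep_)
      }
    }
    write_stable_json(reports, file.path(out_dir, "validation.json"))
    manifest$stages$validate <- lapply(reports, function(r) {
      r[c("r2_ext", "rmse", "pass_robust")]
    })
  }

  sums <- tools::md5sum(unique(inputs))
  manifest$input_checksums <- as.list(stats::setNames(sums, basename(names(sums))))
  write_stable_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
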