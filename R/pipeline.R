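#' Pipeline run configuration
#'
#' One key tree holding every stage's parameters; defaults equal the
#' method's stated values where one exists (band-pass 0.5--40 Hz order 4,
#' 250-sample windows, learning rate 0.001, batch 32, up to 100 epochs,
#' patience 10, dropout 0.2, 60/20/20 split, 5 folds) and the package's
#' documented defaults elsewhere.  All randomness funnels through
#' `seed`, expanded per stage by [stage_seed()].
#'
#' @param seed global base seed.
#' @param n_beats synthetic beats to simulate.
#' @param synth a [synth_config()] template (its `n_beats`/`seed` are
#'   managed by the pipeline).
#' @param architecture a [beat_cnn_architecture()].
#' @param control a [beat_cnn_control()].
#' @param split train/validation/test fractions.
#' @param segment_mode `"annotations"` or `"detected"`.
#' @param n_representative calibration subsample size.
#' @param folds folds for the evaluate stage's cross-validation summary
#'   (`0` to skip CV and only evaluate the held-out test set).
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_beats = 3000L, synth = synth_config(),
                       architecture = beat_cnn_architecture(),
                       control = beat_cnn_control(),
                       split = c(0.6, 0.2, 0.2),
                       segment_mode = "annotations",
                       n_representative = 200L, folds = 0L) {
  structure(list(seed = as.integer(seed), n_beats = as.integer(n_beats),
                 synth = synth, architecture = architecture,
                 control = control, split = split,
                 segment_mode = segment_mode,
                 n_representative = as.integer(n_representative),
                 folds = as.integer(folds)),
            class = "run_config")
}

pipeline_paths <- function(out) {
  list(records = file.path(out, "records.rds"),
       dataset = file.path(out, "dataset.tbd"),
       model = file.path(out, "model.rds"),
       qmodel = file.path(out, "model.tbq"),
       header = file.path(out, "model.h"),
       predictions = file.path(out, "predictions.csv"),
       metrics = file.path(out, "metrics.json"),
       footprint = file.path(out, "footprint.json"),
       manifest = file.path(out, "manifest.json"))
}

require_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path))
    tb_stop("stage '%s' requires the output of stage '%s' (%s); run it first",
            needed_by, stage, path, class = "tinybeat_dependency_error")
  path
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order, each reading its inputs from
#' the output directory (or from earlier stages in the same call) and
#' writing versioned artifacts plus a JSON manifest recording inputs,
#' outputs, seeds and parameter digests.  Rerunning with an identical
#' configuration and seed reproduces identical artifacts and manifest.
#'
#' @param cfg a [run_config()].
#' @param stages subset of `c("simulate", "segment", "train", "quantize",
#'   "infer", "evaluate", "footprint")`.
#' @param out output directory.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(cfg = run_config(),
                         stages = c("simulate", "segment", "train",
                                    "quantize", "evaluate", "footprint"),
                         out = "tinybeat_run") {
  stopifnot(inherits(cfg, "run_config"))
  known <- c("simulate", "segment", "train", "quantize", "infer",
             "evaluate", "footprint")
  stages <- match.arg(stages, known, several.ok = TRUE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_paths(out)
  manifest <- if (file.exists(p$manifest))
    jsonlite::read_json(p$manifest, simplifyVector = FALSE) else list()
  digest <- function(obj) unname(tools::md5sum(files = {
    f <- tempfile(); saveRDS(obj, f, compress = FALSE); f
  }))
  record_stage <- function(name, inputs, outputs, params) {
    manifest[[name]] <<- list(
      stage = name, seed = stage_seed(cfg$seed, name),
      inputs = as.list(inputs),
      outputs = lapply(outputs, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))),
      params_md5 = digest(params))
    jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  for (st in stages) {
    if (st == "simulate") {
      chunk <- 200L
      seed <- stage_seed(cfg$seed, "simulate")
      n_rec <- ceiling(cfg$n_beats / chunk)
      left <- cfg$n_beats
      recs <- vector("list", n_rec)
      for (i in seq_len(n_rec)) {
        ci <- cfg$synth
        ci$n_beats <- as.integer(min(chunk, left))
        ci$seed <- as.integer((seed + i * 131) %% 2147483647)
        left <- left - ci$n_beats
        recs[[i]] <- generate_record(ci, sprintf("synth%03d", i))$record
      }
      saveRDS(list(version = 1L, records = recs), p$records)
      record_stage("simulate", character(0), list(p$records), cfg$synth)
    } else if (st == "segment") {
      require_artifact(p$records, "simulate", "segment")
      recs <- readRDS(p$records)$records
      spec <- design_bandpass(fs = recs[[1L]]$fs)
      recs <- lapply(recs, function(r) {
        r$signal <- filter_zero_phase(r$signal, spec)
        r
      })
      ds <- build_dataset(recs, mode = cfg$segment_mode)
      ds$provenance <- "synthetic"
      ds$seed <- cfg$seed
      save_dataset(ds, p$dataset)
      record_stage("segment", list(p$records), list(p$dataset),
                   list(mode = cfg$segment_mode, filter = spec[c("order",
                        "low_cut", "high_cut", "fs")]))
    } else if (st == "train") {
      require_artifact(p$dataset, "segment", "train")
      ds <- load_dataset(p$dataset)
      sp <- stratified_split(ds, cfg$split,
                             seed = stage_seed(cfg$seed, "split"))
      model <- beat_cnn(sp$train, validation = sp$validation,
                        architecture = cfg$architecture,
                        control = cfg$control,
                        seed = stage_seed(cfg$seed, "train"))
      saveRDS(list(version = 1L, model = model), p$model)
      record_stage("train", list(p$dataset), list(p$model),
                   list(control = cfg$control, split = cfg$split,
                        arch = cfg$architecture$preset))
    } else if (st == "quantize") {
      require_artifact(p$model, "train", "quantize")
      require_artifact(p$dataset, "segment", "quantize")
      model <- readRDS(p$model)$model
      ds <- load_dataset(p$dataset)
      sp <- stratified_split(ds, cfg$split,
                             seed = stage_seed(cfg$seed, "split"))
      qm <- quantize(model, representative = sp$train,
                     n_representative = cfg$n_representative,
                     seed = stage_seed(cfg$seed, "quantize"))
      save_quant_model(qm, p$qmodel)
      export_c_header(qm, p$header)
      record_stage("quantize", list(p$model, p$dataset),
                   list(p$qmodel, p$header),
                   list(n_representative = cfg$n_representative))
    } else if (st == "infer") {
      require_artifact(p$qmodel, "quantize", "infer")
      require_artifact(p$dataset, "segment", "infer")
      qm <- load_quant_model(p$qmodel)
      ds <- load_dataset(p$dataset)
      pred <- predict(qm, ds, type = "class")
      write.csv(data.frame(record_id = ds$record_id, r_index = ds$r_index,
                           predicted = pred), p$predictions,
                row.names = FALSE)
      record_stage("infer", list(p$qmodel, p$dataset), list(p$predictions),
                   list())
    } else if (st == "evaluate") {
      require_artifact(p$model, "train", "evaluate")
      require_artifact(p$qmodel, "quantize", "evaluate")
      require_artifact(p$dataset, "segment", "evaluate")
      model <- readRDS(p$model)$model
      qm <- load_quant_model(p$qmodel)
      ds <- load_dataset(p$dataset)
      sp <- stratified_split(ds, cfg$split,
                             seed = stage_seed(cfg$seed, "split"))
      P <- predict(model, sp$test, type = "prob")
      rep_f <- metric_report(sp$test$labels, model$classes[max.col(P)], P)
      agree <- agreement_report(model, qm, sp$test)
      res <- list(
        float = list(accuracy = rep_f$accuracy,
                     weighted = as.list(rep_f$weighted), auc = rep_f$auc),
        agreement = unclass(agree))
      if (cfg$folds > 0L) {
        cv <- crossval_beat_cnn(ds, folds = cfg$folds,
                                architecture = cfg$architecture,
                                control = cfg$control,
                                seed = stage_seed(cfg$seed, "evaluate"))
        res$crossval <- cv$summary
      }
      jsonlite::write_json(res, p$metrics, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      record_stage("evaluate", list(p$model, p$qmodel, p$dataset),
                   list(p$metrics), list(folds = cfg$folds))
    } else if (st == "footprint") {
      require_artifact(p$qmodel, "quantize", "footprint")
      qm <- load_quant_model(p$qmodel)
      fp <- footprint(qm)
      jsonlite::write_json(list(flash_bytes = fp$flash_bytes,
                                sram_bytes = fp$sram_bytes,
                                per_layer = fp$per_layer),
                           p$footprint, auto_unbox = TRUE, pretty = TRUE)
      record_stage("footprint", list(p$qmodel), list(p$footprint), list())
    }
  }
  invisible(manifest)
}
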