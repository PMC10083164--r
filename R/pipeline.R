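# ---------------------------------------------------------------------------
# End-to-end orchestration: phantom data -> two translation models ->
# conversion at every checkpoint -> quality scoring -> checkpoint selection
# -> automatic separability test.
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the settings of every stage. The `"desk"` preset is sized for a
#' single CPU (64 x 64 phantoms, 100 images per preset, the reduced
#' generator of [desk_training_config()]); `"full"` mirrors the full-scale
#' recipe of [training_config()] (286/256 pipeline, width-64 generator with
#' nine residual blocks, 400 epochs) and is practical only with serious
#' compute. The two training configurations cover the two conversion
#' directions; their source/target presets are opposite by construction.
#'
#' @param preset `"desk"` or `"full"`.
#' @param out_dir output root directory.
#' @param seed master seed; every stage derives its seed from it.
#' @param n_per_preset images generated per preset.
#' @param epochs,checkpoint_interval training schedule overrides.
#' @param n_eval images per direction used for checkpoint scoring.
#' @param classifier_epochs epochs for the separability classifier.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("desk", "full"), out_dir,
                            seed = 1L, n_per_preset = NULL, epochs = NULL,
                            checkpoint_interval = NULL, n_eval = 25L,
                            classifier_epochs = 16L) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    n_per_preset <- n_per_preset %||% 100L
    size <- c(64L, 64L)
    mk_cfg <- function(s) desk_training_config(
      epochs = epochs %||% 10L,
      checkpoint_interval = checkpoint_interval %||% 3L, seed = s)
  } else {
    n_per_preset <- n_per_preset %||% 517L
    size <- c(286L, 286L)
    mk_cfg <- function(s) training_config(
      epochs = epochs %||% 400L,
      checkpoint_interval = checkpoint_interval %||% 20L, seed = s)
  }
  structure(list(preset = preset, out_dir = out_dir, seed = as.integer(seed),
                 n_per_preset = as.integer(n_per_preset), size = size,
                 cfg_cube_to_seven = mk_cfg(seed + 101L),
                 cfg_seven_to_cube = mk_cfg(seed + 202L),
                 n_eval = as.integer(n_eval),
                 classifier = classifier_config(
                   epochs = as.integer(classifier_epochs),
                   seed = seed + 303L)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_record <- function(name, inputs, outputs, seed, t0) {
  list(stage = name, inputs = inputs, outputs = outputs, seed = seed,
       duration_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
}

#' Run the full conversion pipeline
#'
#' Executes the six stages in order -- phantom generation, training of the
#' two conversion models, conversion of every original image at every
#' checkpoint, quality scoring of the converted sets with checkpoint
#' selection (lowest mean score for the Seven-Lines-generating model,
#' highest for the Macular-Cube-generating one), and the automatic
#' separability experiment -- writing every artifact under the output root
#' together with a run-level JSON manifest. Fully seeded: re-running with
#' the same configuration and seed reproduces the same artifacts (the
#' manifest's duration fields aside).
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return the run manifest (named list), invisibly written to
#'   `run_manifest.json`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  root <- config$out_dir
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  # -- stage 1: phantom dataset ---------------------------------------------
  t0 <- Sys.time()
  phantom_dir <- file.path(root, "phantom")
  say("[phantom] generating %d images/preset", config$n_per_preset)
  generate_dataset(config$n_per_preset, phantom_dir, seed = config$seed,
                   size = config$size)
  cube <- load_dataset(phantom_dir, "macular_cube")
  seven <- load_dataset(phantom_dir, "seven_lines")
  ann <- jsonlite::read_json(file.path(phantom_dir, "annotations.json"),
                             simplifyVector = TRUE)
  stages$phantom <- stage_record("phantom", list(), "phantom/", config$seed,
                                 t0)

  # -- stages 2-3: train both conversion models -----------------------------
  t0 <- Sys.time()
  say("[train] macular_cube -> seven_lines")
  dir_c2s <- file.path(root, "train_cube_to_seven")
  m_c2s <- cut_train(cube, seven, config$cfg_cube_to_seven, dir_c2s)
  stages$train_cube_to_seven <- stage_record(
    "train_cube_to_seven", "phantom/", "train_cube_to_seven/",
    config$cfg_cube_to_seven$seed, t0)

  t0 <- Sys.time()
  say("[train] seven_lines -> macular_cube")
  dir_s2c <- file.path(root, "train_seven_to_cube")
  m_s2c <- cut_train(seven, cube, config$cfg_seven_to_cube, dir_s2c)
  stages$train_seven_to_cube <- stage_record(
    "train_seven_to_cube", "phantom/", "train_seven_to_cube/",
    config$cfg_seven_to_cube$seed, t0)

  # -- stage 4: convert with every checkpoint -------------------------------
  t0 <- Sys.time()
  say("[convert] all originals at every checkpoint")
  conv_dir <- file.path(root, "converted")
  conv <- list()
  for (dirn in c("cube_to_seven", "seven_to_cube")) {
    model <- if (dirn == "cube_to_seven") m_c2s else m_s2c
    sources <- if (dirn == "cube_to_seven") cube else seven
    conv[[dirn]] <- list()
    for (j in seq_len(nrow(model$checkpoints))) {
      gen <- load_checkpoint(model$checkpoints$path[j])
      outs <- lapply(sources, function(im) convert_bscan(gen, im))
      sub <- file.path(conv_dir, dirn, sprintf("ckpt_e%04d", gen$epoch))
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      for (im in outs)
        png::writePNG(im$pixels, file.path(sub, paste0(im$source_id,
                                                       ".png")))
      conv[[dirn]][[sprintf("e%04d", gen$epoch)]] <- outs
    }
  }
  stages$convert <- stage_record(
    "convert", c("phantom/", "train_cube_to_seven/", "train_seven_to_cube/"),
    "converted/", config$seed, t0)

  # -- stage 5: quality scoring + checkpoint selection ----------------------
  t0 <- Sys.time()
  say("[quality] scoring converted sets per checkpoint")
  # quality axis anchored by the two original sets: clean Seven Lines low,
  # noisy Macular Cube high
  scorer <- fit_brisque_scorer(seven, cube)
  n_eval <- min(config$n_eval, config$n_per_preset)
  score_tab <- function(sets) {
    do.call(rbind, lapply(names(sets), function(e) {
      scores <- vapply(sets[[e]][seq_len(n_eval)],
                       function(im) brisque_score(im, scorer), numeric(1))
      data.frame(epoch = as.integer(sub("^e", "", e)),
                 mean = mean(scores), sd = stats::sd(scores), n = n_eval)
    }))
  }
  tab_c2s <- score_tab(conv$cube_to_seven)
  tab_s2c <- score_tab(conv$seven_to_cube)
  sel_c2s <- select_checkpoint(tab_c2s, "lowest")   # seven-generating model
  sel_s2c <- select_checkpoint(tab_s2c, "highest")  # cube-generating model
  qdir <- file.path(root, "quality")
  dir.create(qdir, showWarnings = FALSE)
  utils::write.csv(tab_c2s, file.path(qdir, "checkpoint_scores_c2s.csv"),
                   row.names = FALSE)
  utils::write.csv(tab_s2c, file.path(qdir, "checkpoint_scores_s2c.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(selected_epoch_cube_to_seven = sel_c2s,
         selected_epoch_seven_to_cube = sel_s2c),
    file.path(qdir, "selection.json"), auto_unbox = TRUE, digits = NA)
  stages$quality <- stage_record("quality", "converted/", "quality/",
                                 config$seed, t0)

  # -- stage 6: separability ------------------------------------------------
  t0 <- Sys.time()
  say("[separability] classifier on originals, test on conversions")
  originals <- c(cube, seven)
  labels <- vapply(originals, function(b) b$preset, character(1))
  sp <- split_dataset(length(originals), seed = config$seed + 404L,
                      labels = labels)
  fit <- train_classifier(originals[sp$train], originals[sp$val],
                          config$classifier)
  test_acc <- classifier_accuracy(fit$classifier, originals[sp$test])
  rep_c2s <- synthetic_separability_test(
    fit$classifier, conv$cube_to_seven[[sprintf("e%04d", sel_c2s)]],
    target_preset = "seven_lines")
  rep_s2c <- synthetic_separability_test(
    fit$classifier, conv$seven_to_cube[[sprintf("e%04d", sel_s2c)]],
    target_preset = "macular_cube")
  sdir <- file.path(root, "separability")
  dir.create(sdir, showWarnings = FALSE)
  utils::write.csv(fit$curves, file.path(sdir, "classifier_curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(test_accuracy_originals = test_acc,
         best_epoch = fit$best_epoch,
         synthetic_seven_lines = list(
           accuracy = rep_c2s$accuracy, counts = as.list(rep_c2s$counts)),
         synthetic_macular_cube = list(
           accuracy = rep_s2c$accuracy, counts = as.list(rep_s2c$counts))),
    file.path(sdir, "separability.json"), auto_unbox = TRUE, digits = NA)
  stages$separability <- stage_record(
    "separability", c("phantom/", "converted/", "quality/"),
    "separability/", config$seed + 404L, t0)

  manifest <- list(
    preset = config$preset, seed = config$seed,
    n_per_preset = config$n_per_preset, stages = stages,
    selection = list(cube_to_seven = sel_c2s, seven_to_cube = sel_s2c),
    results = list(
      classifier_test_accuracy = test_acc,
      separability_synthetic_seven_lines = rep_c2s$accuracy,
      separability_synthetic_macular_cube = rep_s2c$accuracy))
  jsonlite::write_json(manifest, file.path(root, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
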