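# Desk-scale end-to-end experiment, run once and shared by the tests that
# inspect it: 64 x 64 phantoms, 100 images per preset, the reduced
# generator, 10 epochs per direction, fixed seed.

.desk_cache <- new.env(parent = emptyenv())

desk_run <- function() {
  if (!is.null(.desk_cache$res)) return(.desk_cache$res)
  root <- file.path(tempdir(), "desk-e2e")
  cfg <- pipeline_config("desk", out_dir = root, seed = 42L,
                         n_per_preset = 100L, epochs = 10L,
                         checkpoint_interval = 3L, n_eval = 25L,
                         classifier_epochs = 16L)
  man <- run_pipeline(cfg)

  phantom_dir <- file.path(root, "phantom")
  ann <- jsonlite::read_json(file.path(phantom_dir, "annotations.json"),
                             simplifyVector = TRUE)
  load_converted <- function(direction, epoch, preset) {
    sub <- file.path(root, "converted", direction,
                     sprintf("ckpt_e%04d", epoch))
    lapply(list.files(sub, full.names = TRUE, pattern = "\\.png$"),
           function(p) load_bscan(p, preset, provenance = "synthetic",
                                  source_id = sub("\\.png$", "",
                                                  basename(p))))
  }
  res <- list(
    root = root, manifest = man, annotations = ann,
    cube = load_dataset(phantom_dir, "macular_cube"),
    seven = load_dataset(phantom_dir, "seven_lines"),
    conv_c2s = load_converted("cube_to_seven",
                              man$selection$cube_to_seven, "seven_lines"),
    conv_s2c = load_converted("seven_to_cube",
                              man$selection$seven_to_cube, "macular_cube"),
    scores_c2s = utils::read.csv(file.path(root, "quality",
                                           "checkpoint_scores_c2s.csv")),
    scores_s2c = utils::read.csv(file.path(root, "quality",
                                           "checkpoint_scores_s2c.csv")))
  .desk_cache$res <- res
  res
}

# mean background ENL over a set of images, using the per-image phantom
# annotations (keyed by source id)
mean_bg_enl <- function(images, annotations) {
  mean(vapply(images, function(im) {
    enl(im, annotations[[im$source_id]]$bg)
  }, numeric(1)))
}
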