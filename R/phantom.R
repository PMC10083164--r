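# ---------------------------------------------------------------------------
# Layered speckled phantom: synthetic OCT B-scans with the statistical
# structure of the two scanning presets (same tissue reflectivity model,
# different numbers of averaged speckle looks).
# ---------------------------------------------------------------------------

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards; every seeded operation in the package funnels through
#' this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scanning-preset profile
#'
#' Describes an OCT acquisition preset: how many B-scans are averaged per
#' tomogram (`looks`), how many tomograms one volume holds, and the angular
#' field swept. The two shipped profiles follow the two most common clinical
#' presets: the fast *Macular Cube* (9 averages, 25 slices, 20x20 degrees)
#' and the intensive *Seven Lines* (25 averages, 7 slices, 30x5 degrees).
#' Averaging N independent speckle realisations divides the speckle variance
#' by N, so the two presets differ visibly in noise.
#'
#' @param name preset name, `"macular_cube"` or `"seven_lines"`.
#' @param looks number of averaged B-scans per tomogram (>= 1).
#' @param slices tomograms per volume (metadata only; conversion operates on
#'   single B-scans).
#' @param field_deg numeric length-2, horizontal and vertical field in
#'   degrees (metadata only).
#' @param log_compress logical; whether display images from this preset are
#'   log-compressed after averaging.
#' @return an object of class `preset_profile`.
#' @export
preset_profile <- function(name, looks, slices, field_deg,
                           log_compress = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (looks < 1L) stop("looks must be >= 1")
  if (slices < 1L) stop("slices must be >= 1")
  structure(list(name = name, looks = as.integer(looks),
                 slices = as.integer(slices),
                 field_deg = as.numeric(field_deg),
                 log_compress = isTRUE(log_compress)),
            class = "preset_profile")
}

#' @rdname preset_profile
#' @export
preset_macular_cube <- function() {
  preset_profile("macular_cube", looks = 9L, slices = 25L,
                 field_deg = c(20, 20))
}

#' @rdname preset_profile
#' @export
preset_seven_lines <- function() {
  preset_profile("seven_lines", looks = 25L, slices = 7L,
                 field_deg = c(30, 5))
}

#' B-scan image container
#'
#' A single grayscale B-scan: a numeric matrix with values in [0, 1], depth
#' along rows, origin top-left, labelled with its scanning preset and
#' provenance (acquired/simulated `"original"` versus GAN-converted
#' `"synthetic"`).
#'
#' @param pixels numeric matrix in [0, 1].
#' @param preset preset name string.
#' @param provenance `"original"` or `"synthetic"`.
#' @param source_id free-form identifier.
#' @return an object of class `bscan`.
#' @export
bscan <- function(pixels, preset, provenance = c("original", "synthetic"),
                  source_id = "") {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1)
    stop("bscan pixels must be finite and within [0, 1]")
  if (!nzchar(preset)) stop("preset must be populated")
  structure(list(pixels = pixels, preset = preset, provenance = provenance,
                 source_id = source_id), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan %dx%d preset=%s provenance=%s id=%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$preset, x$provenance,
              x$source_id))
  invisible(x)
}

#' Phantom specification
#'
#' Geometry and optics of one synthetic retina-like phantom: smooth layer
#' interface curves (pixels from the top, one per anatomical boundary
#' analogue such as the inner limiting membrane or the choroid transition)
#' and mean backscatter reflectivities. Layer `i` occupies the band between
#' boundary `i` and boundary `i + 1` (the last layer extends to the bottom);
#' everything above the first boundary is tissue-free background.
#'
#' @param height,width image size in pixels.
#' @param layer_boundaries list of numeric vectors (length `width`), strictly
#'   ordered in depth at every column.
#' @param layer_reflectivities mean backscatter per layer, in (0, 1]; same
#'   length as `layer_boundaries`.
#' @param background_reflectivity backscatter of the tissue-free background;
#'   must be below every layer reflectivity.
#' @param seed integer recorded with the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height, width, layer_boundaries,
                         layer_reflectivities,
                         background_reflectivity = 0.03, seed = 0L) {
  stopifnot(height >= 4, width >= 4, is.list(layer_boundaries),
            length(layer_boundaries) >= 1L,
            length(layer_reflectivities) == length(layer_boundaries))
  for (b in layer_boundaries)
    if (length(b) != width) stop("each boundary must have one depth per column")
  if (length(layer_boundaries) > 1L) {
    for (i in seq_len(length(layer_boundaries) - 1L)) {
      if (!all(layer_boundaries[[i + 1L]] > layer_boundaries[[i]]))
        stop("layer boundaries cross: boundaries must be strictly ordered ",
             "in depth at every column")
    }
  }
  if (any(layer_reflectivities <= 0) || any(layer_reflectivities > 1))
    stop("layer reflectivities must lie in (0, 1]")
  if (background_reflectivity <= 0 ||
      background_reflectivity >= min(layer_reflectivities))
    stop("background_reflectivity must be positive and below every layer")
  structure(list(height = as.integer(height), width = as.integer(width),
                 layer_boundaries = layer_boundaries,
                 layer_reflectivities = as.numeric(layer_reflectivities),
                 background_reflectivity = background_reflectivity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Sample a random phantom specification
#'
#' Draws smooth sinusoid-plus-tilt interface curves with per-image random
#' amplitude, frequency, phase and tilt. The first interface is kept below
#' 22% depth (leaving a clean background band for quality-metric regions)
#' and the first tissue layer at least 12% of the height thick (a homogeneous
#' region-of-interest analogue). Four layers emulate the bright superficial
#' retina, a darker plexiform band, a brighter outer band and an attenuated
#' choroid-like bottom.
#'
#' @param height,width image size in pixels.
#' @param seed integer seed; the spec is deterministic given the seed.
#' @return a [phantom_spec()].
#' @export
sample_phantom_spec <- function(height = 128L, width = 128L, seed = 1L) {
  with_seed(seed, {
    h <- height
    x <- seq_len(width) / width
    amp <- stats::runif(1, 0.01, 0.025) * h
    freq <- stats::runif(1, 0.5, 1.3)
    phase <- stats::runif(1, 0, 2 * pi)
    tilt <- stats::runif(1, -0.025, 0.025) * h
    shape <- amp * sin(2 * pi * freq * x + phase) + tilt * (x - 0.5)
    base <- c(stats::runif(1, 0.26, 0.32),
              stats::runif(1, 0.48, 0.54),
              stats::runif(1, 0.62, 0.68),
              stats::runif(1, 0.78, 0.84)) * h
    bounds <- lapply(seq_along(base), function(i) {
      jit <- stats::runif(1, 0.97, 1.03)  # near-parallel interfaces
      b <- base[i] + jit * shape
      pmin(pmax(b, 0.24 * h + (i - 1) * 3), 0.95 * h)
    })
    # enforce a minimal inter-boundary gap so bands never pinch off
    for (i in seq_len(length(bounds) - 1L))
      bounds[[i + 1L]] <- pmax(bounds[[i + 1L]], bounds[[i]] + 0.02 * h)
    refl <- c(stats::runif(1, 0.45, 0.60), stats::runif(1, 0.15, 0.22),
              stats::runif(1, 0.30, 0.42), stats::runif(1, 0.08, 0.14))
    phantom_spec(height, width, bounds, refl,
                 background_reflectivity = 0.03, seed = seed)
  })
}

#' Noiseless reflectivity map of a phantom
#'
#' Rasterises a [phantom_spec()]: each pixel takes the mean backscatter of
#' the layer containing it. Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return numeric matrix `height x width` of reflectivities.
#' @export
make_reflectivity_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  cnt <- matrix(0L, H, W)
  rows <- seq_len(H)
  for (b in spec$layer_boundaries)
    cnt <- cnt + outer(rows, b, ">")   # 1-based row r is below depth d if r > d
  vals <- c(spec$background_reflectivity, spec$layer_reflectivities)
  matrix(vals[cnt + 1L], H, W)
}

#' Multi-look speckle intensity
#'
#' The physical (pre-compression) intensity model: each of `looks` frames is
#' the reflectivity map multiplied by i.i.d. unit-mean exponential speckle
#' (fully developed speckle), and the output is the per-pixel mean over
#' frames. The expected value equals the map and, on a homogeneous region,
#' the equivalent number of looks mean^2/var recovers `looks`.
#'
#' @param map positive numeric matrix of reflectivities.
#' @param looks number of averaged frames (>= 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return numeric matrix of averaged intensities (unbounded above).
#' @export
speckle_intensity <- function(map, looks, seed = 1L) {
  stopifnot(is.matrix(map))
  if (any(map <= 0)) stop("reflectivity map must be strictly positive")
  if (looks < 1L) stop("looks must be >= 1")
  looks <- as.integer(looks)
  with_seed(seed, {
    acc <- matrix(0, nrow(map), ncol(map))
    for (i in seq_len(looks))
      acc <- acc + map * matrix(stats::rexp(length(map)), nrow(map))
    acc / looks
  })
}

# Display mapping from linear intensity to [0, 1] pixels. Log compression
# mirrors OCT display processing; the linear branch divides by a fixed
# dynamic ceiling. Both clip the (rare) speckle tail above the ceiling.
display_compress <- function(intensity, log_compress = TRUE, c_log = 100,
                             ceiling_lin = 1.5) {
  v <- if (log_compress) log1p(c_log * intensity) / log1p(c_log)
       else intensity / ceiling_lin
  pmin(pmax(v, 0), 1)
}

#' Simulate one B-scan from a reflectivity map
#'
#' Applies the multi-look speckle model of [speckle_intensity()] with the
#' preset's look count, then maps intensities to display pixels (log
#' compression by default, as OCT images are displayed log-compressed).
#' Quantitative speckle statistics (ENL = looks) hold on the pre-compression
#' intensities; use [speckle_intensity()] directly for those.
#'
#' @param map positive numeric reflectivity matrix.
#' @param preset a [preset_profile()].
#' @param seed integer seed.
#' @param log_compress override the preset's `log_compress` flag.
#' @param source_id identifier stored on the image.
#' @return a [bscan()] with `provenance = "original"`.
#' @export
simulate_bscan <- function(map, preset, seed = 1L, log_compress = NULL,
                           source_id = "") {
  stopifnot(inherits(preset, "preset_profile"))
  if (is.null(log_compress)) log_compress <- preset$log_compress
  intensity <- speckle_intensity(map, preset$looks, seed)
  bscan(display_compress(intensity, log_compress), preset = preset$name,
        provenance = "original", source_id = source_id)
}

#' Background / region-of-interest annotation derived from a phantom spec
#'
#' Rectangles are `(row, col, height, width)`, 1-based. The background
#' rectangle sits in the tissue-free band above the first interface; the ROI
#' rectangle inside the first (homogeneous) tissue layer, between the
#' deepest excursion of boundary 1 and the shallowest of boundary 2.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `bg` and `roi`.
#' @export
auto_annotation <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  c0 <- max(1L, floor(0.1 * W)); c1 <- ceiling(0.9 * W)
  bg_top <- 2L
  bg_bot <- floor(min(spec$layer_boundaries[[1L]])) - 2L
  if (bg_bot - bg_top < 3L) stop("phantom has no usable background band")
  roi_top <- ceiling(max(spec$layer_boundaries[[1L]])) + 1L
  roi_bot <- floor(min(spec$layer_boundaries[[2L]])) - 1L
  if (roi_bot - roi_top < 3L) stop("first tissue layer too thin for a ROI")
  list(bg = c(bg_top, c0, bg_bot - bg_top + 1L, c1 - c0 + 1L),
       roi = c(roi_top, c0, roi_bot - roi_top + 1L, c1 - c0 + 1L))
}

#' Generate a synthetic two-preset dataset on disk
#'
#' Writes `n_per_preset` 8-bit grayscale PNG B-scans per preset plus a CSV
#' manifest (`manifest.csv`: path, preset, provenance, seed), a JSON mirror
#' (`manifest.json`) and per-image background/ROI annotations
#' (`annotations.json`). By default each image gets an independent phantom
#' (unpaired classes); `paired = TRUE` reuses the same anatomy for both
#' presets. Paths in the manifest are relative to `out_dir`, so identical
#' seeds give byte-identical manifests.
#'
#' @param n_per_preset images per preset (>= 1).
#' @param out_dir output directory (created if missing).
#' @param seed master seed; fans out to per-image seeds.
#' @param size `c(height, width)` of generated images.
#' @param presets list of [preset_profile()] objects.
#' @param paired logical; share anatomy across presets.
#' @param log_compress display-style log compression flag.
#' @return the manifest as a data.frame (invisibly also written to disk).
#' @export
generate_dataset <- function(n_per_preset, out_dir, seed = 1L,
                             size = c(128L, 128L),
                             presets = list(preset_macular_cube(),
                                            preset_seven_lines()),
                             paired = FALSE, log_compress = TRUE) {
  if (n_per_preset < 1L) stop("n_per_preset must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  n_presets <- length(presets)
  seeds <- with_seed(seed,
    matrix(sample.int(2^31 - 2L, 2L * n_per_preset * n_presets),
           nrow = n_per_preset))
  rows <- list()
  annotations <- list()
  for (p in seq_len(n_presets)) {
    preset <- presets[[p]]
    for (i in seq_len(n_per_preset)) {
      spec_seed <- if (paired) seeds[i, 1L] else seeds[i, 2L * p - 1L]
      noise_seed <- seeds[i, 2L * p]
      spec <- sample_phantom_spec(size[1L], size[2L], seed = spec_seed)
      id <- sprintf("%s_%04d", preset$name, i)
      img <- simulate_bscan(make_reflectivity_map(spec), preset,
                            seed = noise_seed, log_compress = log_compress,
                            source_id = id)
      rel <- paste0(id, ".png")
      png::writePNG(img$pixels, file.path(out_dir, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        path = rel, preset = preset$name, provenance = "original",
        seed = noise_seed, stringsAsFactors = FALSE)
      ann <- auto_annotation(spec)
      annotations[[id]] <- ann
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(annotations, file.path(out_dir, "annotations.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param dir directory written by [generate_dataset()].
#' @return data.frame with columns path, preset, provenance, seed.
#' @export
read_manifest <- function(dir) {
  utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
}

#' Load one B-scan from a PNG file
#'
#' @param path PNG file path.
#' @param preset,provenance,source_id labels for the returned [bscan()].
#' @return a [bscan()].
#' @export
load_bscan <- function(path, preset, provenance = "original",
                       source_id = basename(path)) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  bscan(px, preset = preset, provenance = provenance, source_id = source_id)
}

#' Load every image referenced by a manifest
#'
#' @param dir dataset directory.
#' @param preset optional preset filter.
#' @return list of [bscan()] objects.
#' @export
load_dataset <- function(dir, preset = NULL) {
  man <- read_manifest(dir)
  if (!is.null(preset)) man <- man[man$preset == preset, , drop = FALSE]
  lapply(seq_len(nrow(man)), function(i) {
    load_bscan(file.path(dir, man$path[i]), preset = man$preset[i],
               provenance = man$provenance[i],
               source_id = sub("\\.png$", "", man$path[i]))
  })
}
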