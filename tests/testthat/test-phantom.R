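test_that("reflectivity map rasterises layers by construction", {
  W <- 6L
  one <- phantom_spec(8L, W, list(rep(0, W)), 0.5)
  m <- make_reflectivity_map(one)
  expect_equal(m, matrix(0.5, 8L, W))
  expect_identical(make_reflectivity_map(one), make_reflectivity_map(one))

  two <- phantom_spec(16L, W, list(rep(0, W), rep(10, W)), c(0.6, 0.2))
  m2 <- make_reflectivity_map(two)
  expect_true(all(m2[1:10, ] == 0.6))   # 0-based rows 0..9
  expect_true(all(m2[11:16, ] == 0.2))  # 0-based rows >= 10
})

test_that("crossing or invalid boundaries are rejected", {
  W <- 4L
  expect_error(phantom_spec(10L, W, list(rep(5, W), rep(4, W)), c(0.5, 0.3)),
               "cross")
  expect_error(phantom_spec(10L, W, list(rep(3, W)), 1.5), "reflectivities")
  expect_error(phantom_spec(10L, W, list(rep(3, W)), 0.5,
                            background_reflectivity = 0.6), "background")
})

test_that("speckle simulation recovers the closed-form speckle statistics", {
  map <- matrix(0.4, 120L, 120L)
  one_look <- speckle_intensity(map, looks = 1L, seed = 7L)
  # unit-mean exponential: mean = map value, mean^2/var = 1
  expect_equal(mean(one_look), 0.4, tolerance = 0.02)
  e <- mean(one_look)^2 / stats::var(as.numeric(one_look))
  expect_lt(abs(e - 1), 3 * sqrt(20 / length(map)))  # ~3 SE of the ENL

  # mean preservation for multi-look averages
  nine <- speckle_intensity(map, looks = 9L, seed = 8L)
  expect_equal(mean(nine), 0.4, tolerance = 0.01)

  # variance shrinks monotonically with the look count
  v <- vapply(c(1L, 9L, 25L), function(L)
    stats::var(as.numeric(speckle_intensity(map, L, seed = 99L))),
    numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("speckle simulation is deterministic and validates inputs", {
  map <- matrix(0.3, 20L, 20L)
  expect_identical(speckle_intensity(map, 9L, seed = 5L),
                   speckle_intensity(map, 9L, seed = 5L))
  expect_error(speckle_intensity(map, 0L, seed = 1L), "looks")
  expect_error(speckle_intensity(map - 0.3, 1L, seed = 1L), "positive")
  img <- simulate_bscan(map, preset_macular_cube(), seed = 3L)
  expect_s3_class(img, "bscan")
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  expect_identical(simulate_bscan(map, preset_macular_cube(), seed = 3L),
                   img)
})

test_that("preset profiles carry the two shipped acquisition settings", {
  mc <- preset_macular_cube()
  sl <- preset_seven_lines()
  expect_equal(mc$looks, 9L)
  expect_equal(mc$slices, 25L)
  expect_equal(mc$field_deg, c(20, 20))
  expect_equal(sl$looks, 25L)
  expect_equal(sl$slices, 7L)
  expect_equal(sl$field_deg, c(30, 5))
  expect_error(preset_profile("x", looks = 0L, slices = 1L, c(1, 1)),
               "looks")
})

test_that("generated datasets count, round-trip and reproduce exactly", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- generate_dataset(3L, d1, seed = 42L, size = c(48L, 48L))
  expect_equal(nrow(man), 6L)
  expect_equal(sum(man$preset == "macular_cube"), 3L)
  expect_length(list.files(d1, pattern = "\\.png$"), 6L)

  reread <- read_manifest(d1)
  expect_equal(reread, man)

  generate_dataset(3L, d2, seed = 42L, size = c(48L, 48L))
  for (f in c("manifest.csv", "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }

  imgs <- load_dataset(d1, "seven_lines")
  expect_length(imgs, 3L)
  expect_true(all(vapply(imgs, function(b) b$preset, "") == "seven_lines"))
})

test_that("the noisy preset has higher background variance than the clean one", {
  # identical anatomy, different look counts: the defining class difference
  vars <- sapply(1:10, function(i) {
    spec <- sample_phantom_spec(64L, 64L, seed = i)
    map <- make_reflectivity_map(spec)
    ann <- auto_annotation(spec)
    bg <- function(img) {
      r <- ann$bg
      stats::var(as.numeric(
        img$pixels[r[1]:(r[1] + r[3] - 1), r[2]:(r[2] + r[4] - 1)]))
    }
    c(cube = bg(simulate_bscan(map, preset_macular_cube(), seed = 100 + i)),
      seven = bg(simulate_bscan(map, preset_seven_lines(), seed = 200 + i)))
  })
  expect_gt(mean(vars["cube", ]), mean(vars["seven", ]))
})
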