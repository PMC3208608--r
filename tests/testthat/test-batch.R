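# one small shared plate on disk for the batch tests, built once per run
plate_dir <- file.path(tempdir(), "ns_batch_plate")
if (!dir.exists(plate_dir)) {
  layout <- tibble::tibble(
    well = c("A01", "A02", "B01", "B02"),
    condition = c("differentiated", "differentiated",
                  "undifferentiated", "undifferentiated"),
    dose = c(1, 1, 0, 0),
    n_neurons = 4,
    length_scale = c(1, 1, 0.3, 0.3))
  generate_plate(layout, dir = plate_dir, seed = 11, n_fields = 1,
                 width = 192, height = 192,
                 neurite_length_range = c(40, 80))
}

batch_cfg <- function(out, ...) {
  run_config(plate_dir, out,
             channels = list(TuJ1 = pipeline_config()),
             annotation = file.path(plate_dir, "annotation.tsv"), ...)
}

test_that("filename discovery parses the naming convention", {
  dir <- withr::local_tempdir()
  file.create(file.path(dir, c("P1_A01_f1_TuJ1.tif", "P1_A01_f1_MAP2.tif",
                               "readme.txt", "odd_name.tif")))
  cfg <- run_config(dir, file.path(dir, "out"),
                    channels = list(TuJ1 = pipeline_config(),
                                    MAP2 = pipeline_config()))
  keys <- discover_fields(cfg)
  expect_equal(nrow(keys), 2)
  expect_equal(keys$plate, c("P1", "P1"))
  expect_equal(keys$well, c("A01", "A01"))
  expect_equal(keys$field, c(1L, 1L))
  expect_setequal(keys$channel, c("TuJ1", "MAP2"))
  expect_equal(attr(keys, "unmatched"), "odd_name.tif")
  # an empty directory is an error naming the pattern
  empty <- withr::local_tempdir()
  cfg2 <- run_config(empty, file.path(empty, "out"))
  expect_error(discover_fields(cfg2), "no files matched pattern")
})

test_that("discovery round-trips the generated plate manifest", {
  cfg <- batch_cfg(withr::local_tempdir())
  keys <- discover_fields(cfg)
  manifest <- readr::read_tsv(file.path(plate_dir, "truth_manifest.tsv"),
                              show_col_types = FALSE)
  expect_equal(nrow(keys), nrow(manifest))
  expect_setequal(keys$file, manifest$file)
})

test_that("run_plate separates conditions in the direction of the design", {
  out <- withr::local_tempdir()
  res <- run_plate(batch_cfg(out))
  expect_s3_class(res$fields, "tbl_df")
  expect_equal(nrow(res$fields), 4)
  expect_equal(nrow(res$failures), 0)
  s <- res$conditions
  tl <- s[s$measurement == "total_neurite_length", ]
  expect_gt(tl$mean[tl$condition == "differentiated"],
            tl$mean[tl$condition == "undifferentiated"])
  # outputs on disk
  expect_true(all(file.exists(file.path(out, c("fields.tsv",
                                               "conditions.tsv",
                                               "failures.tsv")))))
  expect_equal(length(list.files(file.path(out, "overlays"))), 4)
  # conservation: measured + failed = discovered
  expect_equal(nrow(res$fields) + nrow(res$failures),
               nrow(discover_fields(batch_cfg(out))))
  # broom-style accessors
  expect_identical(tidy(res), res$fields)
  g <- glance(res)
  expect_equal(g$n_fields, 4L)
  expect_equal(g$n_conditions, 2L)
})

test_that("per-field failures are isolated and logged, not fatal", {
  dir <- withr::local_tempdir()
  file.copy(list.files(plate_dir, pattern = "\\.tif$", full.names = TRUE), dir)
  writeLines("not a tiff", file.path(dir, "P1_C01_f1_TuJ1.tif"))
  cfg <- run_config(dir, file.path(dir, "out"),
                    channels = list(TuJ1 = pipeline_config()),
                    annotation = file.path(plate_dir, "annotation.tsv"))
  res <- run_plate(cfg)
  expect_equal(nrow(res$failures), 1)
  expect_match(res$failures$error, "unreadable image")
  expect_equal(res$failures$well, "C01")
  expect_equal(nrow(res$fields), 4)
  expect_equal(nrow(res$fields) + nrow(res$failures), 5)
  # unknown channels fail the same soft way
  cfg2 <- run_config(dir, file.path(dir, "out2"),
                     channels = list(MAP2 = pipeline_config()))
  res2 <- run_plate(cfg2)
  expect_equal(nrow(res2$fields), 0)
  expect_true(all(grepl("no pipeline_config", res2$failures$error)))
})

test_that("wells without annotation are measured under 'unannotated'", {
  out <- withr::local_tempdir()
  cfg <- run_config(plate_dir, out, channels = list(TuJ1 = pipeline_config()),
                    annotation = tibble::tibble(well = "A01",
                                                condition = "treated"))
  res <- run_plate(cfg)
  expect_equal(sort(unique(res$fields$condition)),
               c("treated", "unannotated"))
  expect_equal(nrow(res$fields), 4)
})

test_that("identical runs produce byte-identical tables", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_plate(batch_cfg(out1))
  run_plate(batch_cfg(out2))
  for (f in c("fields.tsv", "conditions.tsv", "failures.tsv")) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
  ov <- list.files(file.path(out1, "overlays"))
  expect_identical(readBin(file.path(out1, "overlays", ov[1]), "raw", 1e7),
                   readBin(file.path(out2, "overlays", ov[1]), "raw", 1e7))
})

test_that("written tables re-parse to the in-memory result", {
  out <- withr::local_tempdir()
  res <- run_plate(batch_cfg(out))
  back <- readr::read_tsv(file.path(out, "fields.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(res$fields))
  expect_equal(back$well, res$fields$well)
  for (col in c("total_neurite_length", "endpoint_count", "branch_density",
                "mean_intensity")) {
    expect_equal(back[[col]], res$fields[[col]], tolerance = 1e-9)
  }
  cback <- readr::read_tsv(file.path(out, "conditions.tsv"),
                           show_col_types = FALSE)
  expect_equal(cback$mean, res$conditions$mean, tolerance = 1e-9)
})

test_that("16-bit TIFF and PNG inputs read back at native scale", {
  dir <- withr::local_tempdir()
  img <- matrix(as.integer(c(0, 300, 65535, 1200)), 2, 2)
  tiff::writeTIFF(img / 65535, file.path(dir, "x_A01_f1_C1.tif"),
                  bits.per.sample = 16L)
  got <- read_field_image(file.path(dir, "x_A01_f1_C1.tif"))
  expect_equal(as.vector(got), as.vector(img))
  expect_equal(attr(got, "bit_depth"), 16L)
  png::writePNG(matrix(c(0, 0.5, 1, 0.25), 2, 2),
                file.path(dir, "y_A01_f1_C1.png"))
  gp <- read_field_image(file.path(dir, "y_A01_f1_C1.png"))
  expect_equal(as.vector(gp), c(0, 128, 255, 64))
})
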