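# shared mini-run for the reporting tests
rep_plate_dir <- file.path(tempdir(), "ns_report_plate")
rep_out_dir <- file.path(tempdir(), "ns_report_out")
if (!dir.exists(rep_out_dir)) {
  layout <- tibble::tibble(
    well = c("A01", "A02", "B01", "B02"),
    condition = c("hi", "hi", "lo", "lo"),
    n_neurons = 4, length_scale = c(1, 1, 0.4, 0.4))
  generate_plate(layout, dir = rep_plate_dir, seed = 23, n_fields = 1,
                 width = 192, height = 192,
                 neurite_length_range = c(40, 80))
  run_plate(run_config(rep_plate_dir, rep_out_dir,
                       channels = list(TuJ1 = pipeline_config()),
                       annotation = file.path(rep_plate_dir,
                                              "annotation.tsv")))
}
rep_result <- function() {
  run_plate(run_config(rep_plate_dir, file.path(tempdir(), "ns_report_out"),
                       channels = list(TuJ1 = pipeline_config()),
                       annotation = file.path(rep_plate_dir,
                                              "annotation.tsv")))
}

test_that("plate-mean normalization hits its three anchors exactly", {
  expect_identical(normalize_channel_value(0, 10), 0L)
  expect_identical(normalize_channel_value(10, 10), 128L)
  expect_identical(normalize_channel_value(20, 10), 255L)    # 2x mean caps
  expect_identical(normalize_channel_value(30, 10), 255L)    # clamp above
  # monotone non-decreasing
  v <- sort(runif(100, 0, 40))
  out <- normalize_channel_value(v, 10)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= 0 & out <= 255))
  expect_error(normalize_channel_value(5, 0), "positive")
  expect_error(normalize_channel_value(5, -3), "positive")
})

test_that("heatmap colours re-derive exactly from the audit table", {
  res <- rep_result()
  hm <- render_heatmap(res, heatmap_spec())
  tab <- hm$table
  expect_false(any(tab$missing))
  # audit values recompute the normalization
  per_well <- dplyr::summarize(
    dplyr::group_by(res$fields, well),
    v = mean(total_neurite_length), .groups = "drop")
  expect_equal(
    tab$norm_red[match(per_well$well, tab$well)],
    normalize_channel_value(per_well$v, mean(per_well$v)))
  # rendered pixels equal table values
  cp <- 24
  for (j in seq_len(nrow(tab))) {
    px <- hm$image[(tab$row[j] - 1) * cp + 1, (tab$col[j] - 1) * cp + 1, ]
    expect_equal(round(px * 255), c(tab$norm_red[j], tab$norm_green[j],
                                    tab$norm_blue[j]))
  }
  expect_identical(tidy(hm), tab)
})

test_that("a plate where every well equals the mean renders uniform grey 128", {
  fields <- tidyr::expand_grid(well = c("A01", "A02", "B01"), field = 1:2)
  fields$plate <- "P1"; fields$channel <- "C1"; fields$condition <- "c"
  fields$m1 <- 7; fields$m2 <- 3; fields$m3 <- 11
  res <- structure(list(fields = fields), class = "plate_result")
  hm <- render_heatmap(res, heatmap_spec("m1", "m2", "m3", channel = "C1"))
  tab <- hm$table[!hm$table$missing, ]
  expect_true(all(tab$norm_red == 128))
  expect_true(all(tab$norm_green == 128))
  expect_true(all(tab$norm_blue == 128))
  # single well: its own mean, grey 128 again
  res1 <- structure(list(fields = fields[fields$well == "A01", ]),
                    class = "plate_result")
  hm1 <- render_heatmap(res1, heatmap_spec("m1", "m2", "m3", channel = "C1"))
  expect_true(all(hm1$table$norm_red[!hm1$table$missing] == 128))
})

test_that("heatmaps flag unknown measurements and mark missing wells", {
  res <- rep_result()
  expect_error(render_heatmap(res, heatmap_spec(red = "nope")),
               "valid names")
  expect_error(render_heatmap(res, heatmap_spec(channel = "MAP2")),
               "not present")
  # drop one well: sentinel colour appears at its position
  res$fields <- res$fields[res$fields$well != "B02", ]
  hm <- render_heatmap(res, heatmap_spec())
  miss <- hm$table[hm$table$missing, ]
  expect_equal(nrow(miss), 1)
  expect_equal(c(miss$norm_red, miss$norm_green, miss$norm_blue),
               c(255L, 0L, 255L))
})

test_that("rising neurite length at flat soma area shifts hue along the dose axis", {
  # emulate a dose response: red channel monotone, green flat
  fields <- tibble::tibble(
    plate = "P1", well = sprintf("A%02d", 1:6), field = 1L, channel = "C1",
    condition = sprintf("d%d", 1:6),
    total_neurite_length = seq(100, 600, by = 100),
    total_soma_area = 300, mean_intensity = 30)
  res <- structure(list(fields = fields), class = "plate_result")
  hm <- render_heatmap(res, heatmap_spec("total_neurite_length",
                                         "total_soma_area",
                                         "mean_intensity", channel = "C1"))
  tab <- dplyr::arrange(hm$table[!hm$table$missing, ], col)
  expect_true(all(diff(tab$norm_red) > 0))
  expect_equal(length(unique(tab$norm_green)), 1)
})

test_that("the static browser is self-contained with resolving links", {
  res <- rep_result()
  bm <- build_browser(res)
  idx <- file.path(bm$dir, "index.html")
  expect_true(file.exists(idx))
  doc <- xml2::read_html(idx)
  hrefs <- c(xml2::xml_attr(xml2::xml_find_all(doc, "//a"), "href"),
             xml2::xml_attr(xml2::xml_find_all(doc, "//img"), "src"))
  expect_true(length(hrefs) > 5)
  # no absolute paths or external URLs
  expect_false(any(grepl("^(/|[A-Za-z]+:)", hrefs)))
  for (h in hrefs) {
    expect_true(file.exists(file.path(bm$dir, h)), info = h)
  }
  # every well page exists and links resolve too
  for (w in unique(res$fields$well)) {
    wp <- file.path(bm$dir, sprintf("well_%s.html", w))
    expect_true(file.exists(wp))
    wdoc <- xml2::read_html(wp)
    srcs <- xml2::xml_attr(xml2::xml_find_all(wdoc, "//img"), "src")
    for (s in srcs) expect_true(file.exists(file.path(bm$dir, s)), info = s)
  }
  expect_true(file.exists(file.path(bm$dir, "scatter.html")))
  sv <- readLines(file.path(bm$dir, "scatter.html"), warn = FALSE)
  expect_true(any(grepl("<svg", sv)))
  expect_true(any(grepl("<title>", sv)))   # client-side tooltips
})

test_that("a failed field surfaces as a note on its well page", {
  dir <- withr::local_tempdir()
  file.copy(list.files(rep_plate_dir, pattern = "\\.tif$", full.names = TRUE),
            dir)
  writeLines("broken", file.path(dir, "P1_A01_f2_TuJ1.tif"))
  res <- run_plate(run_config(dir, file.path(dir, "out"),
                              channels = list(TuJ1 = pipeline_config())))
  expect_equal(nrow(res$failures), 1)
  bm <- build_browser(res)
  page <- readLines(file.path(bm$dir, "well_A01.html"), warn = FALSE)
  expect_true(any(grepl("Failures", page)))
  expect_true(any(grepl("unreadable image", page)))
})

test_that("rebuilding the browser without reanalysis is byte-identical", {
  res <- rep_result()
  d1 <- file.path(withr::local_tempdir(), "r1")
  d2 <- file.path(withr::local_tempdir(), "r2")
  build_browser(res, dir = d1)
  build_browser(res, dir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("ggplot accessors return well-formed plots", {
  res <- rep_result()
  hm <- render_heatmap(res, heatmap_spec())
  p1 <- ggplot2::autoplot(hm)
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(res)
  expect_s3_class(p2, "ggplot")
})
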