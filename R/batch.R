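#' Configure a batch (plate) analysis run
#'
#' Describes where the images live, how filenames map to plate / well /
#' field / channel keys, which [pipeline_config()] to use per stain channel,
#' and the well annotation table.
#'
#' @param input_dir Directory containing the field images.
#' @param output_dir Directory for tables, overlays and reports (created on
#'   demand).
#' @param channels Named list of [pipeline_config()] objects, one per channel
#'   label appearing in filenames (e.g. `list(TuJ1 = ..., MAP2 = ...)`);
#'   channels may use different configurations (a dendrite-only marker is
#'   typically thresholded independently of a pan-neurite marker).
#' @param pattern Filename convention with placeholders `{plate}`, `{well}`,
#'   `{field}`, `{channel}`; must include at least `{well}` and `{channel}`.
#'   The image extension (tif/tiff/png) is appended automatically.
#' @param annotation Well annotation: a data frame or TSV path with columns
#'   `well`, `condition` and optionally `dose`. Wells without annotation fall
#'   into condition `"unannotated"` but are still measured.
#' @param write_overlays Write a colour-coded overlay PNG per field.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input_dir, output_dir,
                       channels = list(TuJ1 = pipeline_config()),
                       pattern = "{plate}_{well}_f{field}_{channel}",
                       annotation = NULL,
                       write_overlays = TRUE) {
  if (!dir.exists(input_dir)) {
    stop("input directory does not exist: ", input_dir, call. = FALSE)
  }
  if (is.null(names(channels)) || any(names(channels) == "") ||
      !all(vapply(channels, inherits, logical(1), "pipeline_config"))) {
    stop("`channels` must be a named list of pipeline_config objects",
         call. = FALSE)
  }
  if (!grepl("{well}", pattern, fixed = TRUE) ||
      !grepl("{channel}", pattern, fixed = TRUE)) {
    stop("`pattern` must capture at least {well} and {channel}", call. = FALSE)
  }
  if (is.character(annotation) && length(annotation) == 1) {
    annotation <- readr::read_tsv(annotation, show_col_types = FALSE)
  }
  if (!is.null(annotation)) {
    annotation <- tibble::as_tibble(annotation)
    if (!all(c("well", "condition") %in% names(annotation))) {
      stop("`annotation` needs `well` and `condition` columns", call. = FALSE)
    }
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 channels = channels, pattern = pattern,
                 annotation = annotation,
                 write_overlays = isTRUE(write_overlays)),
            class = "run_config")
}

# filename pattern with {placeholders} -> PCRE with named capture groups
pattern_to_regex <- function(pattern) {
  # escape regex metacharacters but leave the {placeholder} braces alone
  rx <- gsub("([.^$*+?()\\[\\]|\\\\])", "\\\\\\1", pattern)
  for (ph in c("plate", "well", "field", "channel")) {
    rx <- sub(paste0("\\{", ph, "\\}"), sprintf("(?<%s>[A-Za-z0-9]+)", ph), rx)
  }
  paste0("^", rx, "\\.(tif|tiff|png)$")
}

#' Discover field images for a run
#'
#' Lists the input directory, parses filenames against the run's naming
#' convention and returns one row per recognized field image in deterministic
#' (lexicographic, then key-sorted) order. Files that do not match the
#' pattern are returned in the `unmatched` attribute, never silently dropped.
#'
#' @param cfg A [run_config()].
#' @return Tibble with columns `file`, `path`, `plate`, `well`, `field`,
#'   `channel`; attribute `unmatched` holds non-matching filenames.
#' @export
discover_fields <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  files <- sort(list.files(cfg$input_dir))
  files <- files[!dir.exists(file.path(cfg$input_dir, files))]
  img_like <- grepl("\\.(tif|tiff|png)$", files, ignore.case = TRUE)
  rx <- pattern_to_regex(cfg$pattern)
  m <- regexpr(rx, files, perl = TRUE)
  hit <- m > 0 & img_like
  if (!any(hit)) {
    stop("no files matched pattern '", cfg$pattern, "' in ", cfg$input_dir,
         call. = FALSE)
  }
  grab <- function(name) {
    st <- attr(m, "capture.start")[, name]
    ln <- attr(m, "capture.length")[, name]
    out <- rep(NA_character_, length(files))
    ok <- hit & st > 0
    out[ok] <- substr(files[ok], st[ok], st[ok] + ln[ok] - 1)
    out
  }
  has <- function(name) name %in% colnames(attr(m, "capture.start"))
  keys <- tibble::tibble(
    file = files,
    path = file.path(cfg$input_dir, files),
    plate = if (has("plate")) grab("plate") else "plate1",
    well = grab("well"),
    field = if (has("field")) suppressWarnings(as.integer(grab("field"))) else 1L,
    channel = grab("channel")
  )[hit, ]
  keys <- dplyr::arrange(keys, .data$plate, .data$well, .data$field,
                         .data$channel)
  if (anyDuplicated(keys[, c("plate", "well", "field", "channel")])) {
    stop("duplicate plate/well/field/channel keys in input set", call. = FALSE)
  }
  attr(keys, "unmatched") <- files[img_like & m < 0]
  keys
}

#' Read one greyscale field image
#'
#' Reads TIFF (8/16-bit, via raw sample values) or PNG (assumed 8-bit)
#' images; multi-plane images are reduced to their first plane. Errors carry
#' the file path so batch logs can attribute failures.
#'
#' @param path Image file path.
#' @return Numeric intensity matrix with attribute `bit_depth`.
#' @export
read_field_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      x <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(x)) == 3) x <- x[, , 1]
      storage.mode(x) <- "double"
      x
    } else if (ext == "png") {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3) x <- x[, , 1]
      round(x * 255)
    } else {
      stop("unsupported image type: ", ext)
    }
  }, error = function(e) {
    stop("unreadable image [", path, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  if (length(img) == 0) stop("empty image [", path, "]", call. = FALSE)
  attr(img, "bit_depth") <- if (max(img) > 255) 16L else 8L
  img
}

#' Run the full pipeline over a plate of images
#'
#' Discovers fields, analyzes every channel with its own [pipeline_config()],
#' isolates per-field failures (logged, never aborting the plate), derives
#' secondary statistics, summarizes per condition and writes `fields.tsv`,
#' `conditions.tsv`, `failures.tsv` and overlay PNGs under the output
#' directory. Output is a pure function of the input images and
#' configuration: rerunning produces byte-identical tables.
#'
#' @param cfg A [run_config()].
#' @return A list of class `"plate_result"`: tibbles `fields`, `conditions`,
#'   `failures`, character vector `unmatched`, plus `output_dir` and the
#'   `config` used.
#' @export
run_plate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  keys <- discover_fields(cfg)
  ok <- dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$output_dir)) {
    stop("cannot create output directory: ", cfg$output_dir, call. = FALSE)
  }
  if (file.access(cfg$output_dir, 2) != 0) {
    stop("output directory is not writable: ", cfg$output_dir, call. = FALSE)
  }
  if (cfg$write_overlays) {
    dir.create(file.path(cfg$output_dir, "overlays"), showWarnings = FALSE)
  }
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    fid <- sprintf("%s_%s_f%s_%s", k$plate, k$well, k$field, k$channel)
    res <- tryCatch({
      pc <- cfg$channels[[k$channel]]
      if (is.null(pc)) stop("no pipeline_config for channel '", k$channel, "'")
      img <- read_field_image(k$path)
      fr <- measure_field(img, pc, field_id = fid)
      if (cfg$write_overlays) {
        png::writePNG(render_overlay(fr, img),
                      file.path(cfg$output_dir, "overlays",
                                paste0(fid, ".png")))
      }
      dplyr::bind_cols(k[, c("plate", "well", "field", "channel")],
                       derive_measurements(fr$measurements[, -1], pc))
    }, error = function(e) {
      fails[[length(fails) + 1]] <<- dplyr::bind_cols(
        k[, c("file", "plate", "well", "field", "channel")],
        tibble::tibble(error = conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  fields <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  failures <- if (length(fails)) dplyr::bind_rows(fails) else
    tibble::tibble(file = character(0), plate = character(0),
                   well = character(0), field = integer(0),
                   channel = character(0), error = character(0))
  # annotate wells
  if (nrow(fields)) {
    ann <- cfg$annotation
    if (!is.null(ann)) {
      fields <- dplyr::left_join(fields, ann, by = "well")
      fields$condition[is.na(fields$condition)] <- "unannotated"
    } else {
      fields$condition <- "unannotated"
    }
    if (!"dose" %in% names(fields)) fields$dose <- NA_real_
    fields <- dplyr::arrange(fields, .data$plate, .data$well, .data$field,
                             .data$channel)
  }
  conditions <- if (nrow(fields)) {
    dplyr::bind_rows(lapply(split(fields, fields$channel), function(ch) {
      out <- summarize_condition(ch)
      out$channel <- ch$channel[1]
      out[, c("channel", setdiff(names(out), "channel"))]
    }))
  } else {
    tibble::tibble()
  }
  readr::write_tsv(fields, file.path(cfg$output_dir, "fields.tsv"))
  readr::write_tsv(conditions, file.path(cfg$output_dir, "conditions.tsv"))
  readr::write_tsv(failures, file.path(cfg$output_dir, "failures.tsv"))
  if (length(attr(keys, "unmatched"))) {
    writeLines(attr(keys, "unmatched"),
               file.path(cfg$output_dir, "unmatched_files.txt"))
  }
  structure(list(fields = fields, conditions = conditions,
                 failures = failures, unmatched = attr(keys, "unmatched"),
                 output_dir = cfg$output_dir, config = cfg),
            class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf("<plate_result: %d fields measured, %d failed, %d unmatched>\n",
              nrow(x$fields), nrow(x$failures), length(x$unmatched)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-field measurements of a plate run
#'
#' @param x A `"plate_result"`.
#' @param ... Unused.
#' @return The per-field tibble (primary + derived measurements, one row per
#'   field and channel).
#' @export
tidy.plate_result <- function(x, ...) x$fields

#' One-row summary of a plate run
#'
#' @param x A `"plate_result"`.
#' @param ... Unused.
#' @return Tibble with one row: field, failure, well, channel and condition
#'   counts.
#' @export
glance.plate_result <- function(x, ...) {
  tibble::tibble(
    n_fields = nrow(x$fields),
    n_failed = nrow(x$failures),
    n_unmatched = length(x$unmatched),
    n_wells = length(unique(x$fields$well)),
    n_channels = length(unique(x$fields$channel)),
    n_conditions = length(unique(x$fields$condition))
  )
}
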