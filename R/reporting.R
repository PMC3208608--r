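#' Normalize a measurement against the plate mean (heatmap colour rule)
#'
#' Maps a measurement value to an 8-bit colour component with the plate-mean
#' anchoring used by the review heatmaps: black (0) is no signal, grey (128)
#' is exactly the plate average, white (255) is twice the plate average or
#' more. `round(128 * v / plate_mean)` clamped to `[0, 255]`; monotone
#' non-decreasing in `v`.
#'
#' @param v Numeric vector of measurement values (>= 0).
#' @param plate_mean Plate average of the measurement (> 0).
#' @return Integer vector in `[0, 255]`.
#' @examples
#' normalize_channel_value(c(0, 5, 10, 30), plate_mean = 10)  # 0 64 128 255
#' @export
normalize_channel_value <- function(v, plate_mean) {
  if (!is.numeric(plate_mean) || length(plate_mean) != 1 ||
      !is.finite(plate_mean) || plate_mean <= 0) {
    stop("`plate_mean` must be a single positive number", call. = FALSE)
  }
  as.integer(pmin(pmax(round(128 * v / plate_mean), 0), 255))
}

#' Specify a three-measurement plate heatmap
#'
#' @param red,green,blue Measurement column names mapped to the three colour
#'   components (repeats allowed), e.g. total neurite length in red, soma
#'   area in green, mean marker intensity in blue.
#' @param channel Stain channel whose measurements are displayed.
#' @return A list of class `"heatmap_spec"`.
#' @export
heatmap_spec <- function(red = "total_neurite_length",
                         green = "total_soma_area",
                         blue = "mean_intensity",
                         channel = "TuJ1") {
  structure(list(red = red, green = green, blue = blue, channel = channel),
            class = "heatmap_spec")
}

well_row_col <- function(well) {
  m <- regmatches(well, regexec("^([A-Za-z]+)([0-9]+)$", well))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop("unparseable well name(s): ", paste(well[bad], collapse = ", "),
         call. = FALSE)
  }
  row_letter <- toupper(vapply(m, `[`, character(1), 2))
  list(row = match(row_letter, LETTERS),
       col = as.integer(vapply(m, `[`, character(1), 3)))
}

#' Render a plate heatmap with per-cell audit table
#'
#' One cell per well in plate geometry; each cell's RGB encodes three
#' measurements, each averaged over the well's fields and normalized so the
#' plate mean maps to grey 128 ([normalize_channel_value()]). The plate mean
#' is computed over annotated, non-failed wells (falling back to all measured
#' wells, with a flag, when nothing is annotated). Missing wells are drawn in
#' a magenta sentinel. The audit table stores raw and normalized values so
#' rendered pixel colours can be re-derived exactly.
#'
#' @param result A `"plate_result"` from [run_plate()].
#' @param spec A [heatmap_spec()].
#' @param file Optional path to write the heatmap PNG.
#' @param cell_px Cell edge length in pixels for the rendered image.
#' @return A list of class `"plate_heatmap"`: `table` (audit tibble), `image`
#'   (RGB array in `[0, 1]`), `plate_means`, `spec`.
#' @export
render_heatmap <- function(result, spec, file = NULL, cell_px = 24) {
  stopifnot(inherits(result, "plate_result"), inherits(spec, "heatmap_spec"))
  fields <- result$fields[result$fields$channel == spec$channel, ]
  if (nrow(fields) == 0) {
    stop("channel '", spec$channel, "' not present in run", call. = FALSE)
  }
  meas <- unique(c(spec$red, spec$green, spec$blue))
  bad <- setdiff(meas, names(fields))
  if (length(bad)) {
    valid <- names(fields)[vapply(fields, is.numeric, logical(1))]
    stop("unknown measurement(s) ", paste(bad, collapse = ", "),
         "; valid names: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  per_well <- dplyr::summarize(
    dplyr::group_by(fields, .data$well, .data$condition),
    dplyr::across(dplyr::all_of(meas), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  annotated <- per_well[per_well$condition != "unannotated", ]
  mean_basis <- if (nrow(annotated) > 0) annotated else per_well
  fallback <- nrow(annotated) == 0
  plate_means <- vapply(meas, function(mm) mean(mean_basis[[mm]], na.rm = TRUE),
                        numeric(1))
  rc <- well_row_col(per_well$well)
  nr <- max(rc$row); nc <- max(rc$col)
  sentinel <- c(255L, 0L, 255L)
  chan <- function(mm) {
    if (plate_means[[mm]] <= 0) {
      warning("plate mean of ", mm, " is not positive; channel rendered black",
              call. = FALSE)
      return(rep(0L, nrow(per_well)))
    }
    normalize_channel_value(per_well[[mm]], plate_means[[mm]])
  }
  tab <- tibble::tibble(
    well = per_well$well, row = rc$row, col = rc$col,
    condition = per_well$condition,
    raw_red = per_well[[spec$red]], raw_green = per_well[[spec$green]],
    raw_blue = per_well[[spec$blue]],
    norm_red = chan(spec$red), norm_green = chan(spec$green),
    norm_blue = chan(spec$blue), missing = FALSE)
  # fill plate geometry with sentinel cells for absent wells
  grid <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  grid$well <- paste0(LETTERS[grid$row], sprintf("%02d", grid$col))
  miss <- !paste(grid$row, grid$col) %in% paste(tab$row, tab$col)
  if (any(miss)) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(
      well = grid$well[miss], row = grid$row[miss], col = grid$col[miss],
      condition = NA_character_, raw_red = NA_real_, raw_green = NA_real_,
      raw_blue = NA_real_, norm_red = sentinel[1], norm_green = sentinel[2],
      norm_blue = sentinel[3], missing = TRUE))
  }
  tab <- dplyr::arrange(tab, .data$row, .data$col)
  img <- array(0, c(nr * cell_px, nc * cell_px, 3))
  ones <- matrix(1, cell_px, cell_px)
  small <- function(vals) {
    m <- matrix(0L, nr, nc)
    m[cbind(tab$row, tab$col)] <- vals
    m
  }
  img[, , 1] <- kronecker(small(tab$norm_red), ones) / 255
  img[, , 2] <- kronecker(small(tab$norm_green), ones) / 255
  img[, , 3] <- kronecker(small(tab$norm_blue), ones) / 255
  if (!is.null(file)) png::writePNG(img, file)
  structure(list(table = tab, image = img, plate_means = plate_means,
                 spec = spec, mean_fallback = fallback),
            class = "plate_heatmap")
}

#' @export
print.plate_heatmap <- function(x, ...) {
  cat(sprintf("<plate_heatmap %s: R=%s G=%s B=%s, %d wells>\n",
              x$spec$channel, x$spec$red, x$spec$green, x$spec$blue,
              sum(!x$table$missing)))
  invisible(x)
}

#' Tidy the audit table of a plate heatmap
#'
#' @param x A `"plate_heatmap"`.
#' @param ... Unused.
#' @return The audit tibble (well, plate position, raw and normalized values).
#' @export
tidy.plate_heatmap <- function(x, ...) x$table

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a plate heatmap with ggplot2
#'
#' @param object A `"plate_heatmap"` from [render_heatmap()].
#' @param ... Unused.
#' @return A ggplot object (one tile per well, exact heatmap colours).
#' @export
autoplot.plate_heatmap <- function(object, ...) {
  tab <- object$table
  tab$fill <- grDevices::rgb(tab$norm_red, tab$norm_green, tab$norm_blue,
                             maxColorValue = 255)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill), colour = "grey30") +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse(breaks = unique(tab$row),
                             labels = LETTERS[unique(tab$row)]) +
    ggplot2::scale_x_continuous(breaks = unique(tab$col)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("%s: R=%s, G=%s, B=%s (grey 128 = plate mean)",
                      object$spec$channel, object$spec$red,
                      object$spec$green, object$spec$blue)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of two per-field measurements
#'
#' @param object A `"plate_result"`.
#' @param x,y Measurement column names.
#' @param ... Unused.
#' @return A ggplot object, per-field points coloured by condition.
#' @export
autoplot.plate_result <- function(object, x = "total_soma_area",
                                  y = "total_neurite_length", ...) {
  ggplot2::ggplot(object$fields,
                  ggplot2::aes(x = .data[[x]], y = .data[[y]],
                               colour = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = x, y = y, colour = "condition") +
    ggplot2::theme_minimal()
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_page <- function(title, body) {
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">\n<title>",
         html_escape(title), "</title>\n<style>body{font-family:sans-serif;",
         "margin:2em}table{border-collapse:collapse}td,th{border:1px solid ",
         "#999;padding:3px 8px}img{image-rendering:pixelated}</style>\n",
         "</head><body>\n", body, "\n</body></html>\n")
}

html_table <- function(df, digits = 4) {
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "NA", formatC(v, digits = digits,
                                                      format = "g")) else
      html_escape(as.character(v))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  paste0("<table><tr>",
         paste0("<th>", html_escape(names(df)), "</th>", collapse = ""),
         "</tr>\n",
         paste(apply(cells, 1, function(r) {
           paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
         }), collapse = "\n"),
         "</table>")
}

# inline SVG scatter with per-point <title> tooltips (no graphics device,
# no external assets: deterministic and self-contained)
scatter_svg <- function(fields, x, y, w = 640, h = 480, pad = 50) {
  v <- fields[!is.na(fields[[x]]) & !is.na(fields[[y]]), ]
  if (nrow(v) == 0) return("<p>no data for scatter plot</p>")
  conds <- sort(unique(v$condition))
  pal <- grDevices::hcl(h = seq(15, 375, length.out = length(conds) + 1)[-1],
                        l = 55, c = 90)
  xr <- range(v[[x]]); yr <- range(v[[y]])
  if (diff(xr) == 0) xr <- xr + c(-1, 1)
  if (diff(yr) == 0) yr <- yr + c(-1, 1)
  px <- pad + (v[[x]] - xr[1]) / diff(xr) * (w - 2 * pad)
  py <- h - pad - (v[[y]] - yr[1]) / diff(yr) * (h - 2 * pad)
  pts <- sprintf(
    "<circle cx=\"%.1f\" cy=\"%.1f\" r=\"4\" fill=\"%s\" fill-opacity=\"0.7\"><title>%s</title></circle>",
    px, py, pal[match(v$condition, conds)],
    html_escape(sprintf("%s %s f%s: %s=%.4g, %s=%.4g", v$well, v$condition,
                        v$field, x, v[[x]], y, v[[y]])))
  leg <- sprintf(
    "<circle cx=\"%d\" cy=\"%d\" r=\"4\" fill=\"%s\"/><text x=\"%d\" y=\"%d\" font-size=\"11\">%s</text>",
    w - pad - 120, pad + seq_along(conds) * 16, pal,
    w - pad - 110, pad + seq_along(conds) * 16 + 4, html_escape(conds))
  axes <- sprintf(paste0(
    "<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"black\"/>",
    "<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"black\"/>",
    "<text x=\"%d\" y=\"%d\" font-size=\"12\">%s</text>",
    "<text x=\"14\" y=\"%d\" font-size=\"12\" transform=\"rotate(-90 14 %d)\">%s</text>"),
    pad, h - pad, w - pad, h - pad, pad, pad, pad, h - pad,
    as.integer((w - pad) / 2), h - 12, html_escape(x),
    as.integer(h / 2), as.integer(h / 2), html_escape(y))
  paste0("<svg width=\"", w, "\" height=\"", h,
         "\" xmlns=\"http://www.w3.org/2000/svg\">\n", axes, "\n",
         paste(pts, collapse = "\n"), "\n", paste(leg, collapse = "\n"),
         "\n</svg>")
}

# nearest-neighbour downscale to a maximum edge length
thumbnail <- function(img, max_dim = 512) {
  f <- ceiling(max(dim(img)) / max_dim)
  if (f > 1) img <- img[seq(1, nrow(img), by = f), seq(1, ncol(img), by = f)]
  img / max(img, 1)
}

#' Build a static HTML review browser for a plate run
#'
#' Writes a self-contained site under `dir`: an index page with every
#' heatmap (each populated well cell hyperlinked to its well page), per-well
#' pages showing downscaled raw images and overlay tracings side by side with
#' the measurement rows, a 2-D scatter page (inline SVG with hover tooltips),
#' and links to the tab-delimited tables. All links are relative; no server
#' is required. Missing overlays produce a placeholder note, never an abort.
#'
#' @param result A `"plate_result"` from [run_plate()].
#' @param specs List of [heatmap_spec()]s (default: one per channel).
#' @param dir Site directory (default `report/` inside the run output).
#' @param scatter Character pair of measurement names for the scatter page.
#' @return A list of class `"browser_manifest"`: tibble of pages written and
#'   the site root.
#' @export
build_browser <- function(result, specs = NULL,
                          dir = file.path(result$output_dir, "report"),
                          scatter = c("total_soma_area",
                                      "total_neurite_length")) {
  stopifnot(inherits(result, "plate_result"))
  if (nrow(result$fields) == 0) stop("no measured fields to browse",
                                     call. = FALSE)
  if (is.null(specs)) {
    specs <- lapply(unique(result$fields$channel),
                    function(ch) heatmap_spec(channel = ch))
  }
  dir.create(file.path(dir, "thumbs"), recursive = TRUE, showWarnings = FALSE)
  pages <- list()
  # --- heatmaps -------------------------------------------------------------
  hm_html <- character(0)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    hm <- render_heatmap(result, sp,
                         file = file.path(dir, sprintf("heatmap_%d.png", i)))
    readr::write_tsv(hm$table, file.path(dir, sprintf("heatmap_%d.tsv", i)))
    tab <- hm$table
    cells <- vapply(seq_len(nrow(tab)), function(j) {
      colr <- grDevices::rgb(tab$norm_red[j], tab$norm_green[j],
                             tab$norm_blue[j], maxColorValue = 255)
      inner <- html_escape(tab$well[j])
      if (!tab$missing[j]) {
        inner <- sprintf("<a href=\"well_%s.html\" style=\"color:#fff\">%s</a>",
                         tab$well[j], inner)
      }
      sprintf("<td style=\"background:%s;width:34px;text-align:center\">%s</td>",
              colr, inner)
    }, character(1))
    grid <- split(cells, tab$row)
    hm_html <- c(hm_html, sprintf(
      "<h2>%s &mdash; R: %s, G: %s, B: %s</h2>\n<p><img src=\"heatmap_%d.png\" alt=\"heatmap\"> <a href=\"heatmap_%d.tsv\">audit table</a></p>\n<table>%s</table>",
      html_escape(sp$channel), html_escape(sp$red), html_escape(sp$green),
      html_escape(sp$blue), i, i,
      paste(vapply(grid, function(r) paste0("<tr>", paste(r, collapse = ""),
                                            "</tr>"), character(1)),
            collapse = "\n")))
    pages[[length(pages) + 1]] <- sprintf("heatmap_%d.png", i)
    pages[[length(pages) + 1]] <- sprintf("heatmap_%d.tsv", i)
  }
  # --- per-well pages -------------------------------------------------------
  wells <- sort(unique(result$fields$well))
  for (w in wells) {
    fw <- result$fields[result$fields$well == w, ]
    blocks <- character(0)
    for (j in seq_len(nrow(fw))) {
      fid <- sprintf("%s_%s_f%s_%s", fw$plate[j], fw$well[j], fw$field[j],
                     fw$channel[j])
      src <- file.path(result$config$input_dir,
                       sprintf("%s.tif", fid))
      thumb_rel <- sprintf("thumbs/%s.png", fid)
      thumb_path <- file.path(dir, thumb_rel)
      if (file.exists(src) && !file.exists(thumb_path)) {
        png::writePNG(thumbnail(read_field_image(src)), thumb_path)
      }
      ov_src <- file.path(result$output_dir, "overlays",
                          paste0(fid, ".png"))
      ov_rel <- sprintf("thumbs/%s_overlay.png", fid)
      ov_html <- if (file.exists(ov_src)) {
        if (!file.exists(file.path(dir, ov_rel))) {
          file.copy(ov_src, file.path(dir, ov_rel))
        }
        sprintf("<img src=\"%s\" width=\"320\" alt=\"overlay\">", ov_rel)
      } else {
        "<em>overlay missing</em>"
      }
      raw_html <- if (file.exists(thumb_path)) {
        sprintf("<img src=\"%s\" width=\"320\" alt=\"raw\">", thumb_rel)
      } else {
        "<em>raw image unavailable</em>"
      }
      blocks <- c(blocks, sprintf("<h3>%s</h3>\n<p>%s %s</p>\n%s",
                                  html_escape(fid), raw_html, ov_html,
                                  html_table(fw[j, ])))
    }
    fl <- result$failures[result$failures$well == w, ]
    if (nrow(fl)) {
      blocks <- c(blocks, "<h3>Failures</h3>", html_table(fl))
    }
    page <- sprintf("well_%s.html", w)
    writeLines(html_page(paste("Well", w),
                         paste0("<p><a href=\"index.html\">&larr; index</a></p>\n",
                                paste(blocks, collapse = "\n"))),
               file.path(dir, page))
    pages[[length(pages) + 1]] <- page
  }
  # --- scatter --------------------------------------------------------------
  writeLines(html_page(
    "Scatter", paste0("<p><a href=\"index.html\">&larr; index</a></p>\n",
                      scatter_svg(result$fields, scatter[1], scatter[2]))),
    file.path(dir, "scatter.html"))
  pages[[length(pages) + 1]] <- "scatter.html"
  # --- index ----------------------------------------------------------------
  idx <- paste0(
    "<h1>Plate review</h1>\n",
    html_table(glance(result)), "\n",
    paste(hm_html, collapse = "\n"), "\n",
    "<h2>Pages</h2><ul>",
    "<li><a href=\"scatter.html\">2-D scatter</a></li>",
    "<li><a href=\"../fields.tsv\">fields.tsv</a></li>",
    "<li><a href=\"../conditions.tsv\">conditions.tsv</a></li>",
    "<li><a href=\"../failures.tsv\">failures.tsv</a></li></ul>")
  writeLines(html_page("Plate review", idx), file.path(dir, "index.html"))
  pages[[length(pages) + 1]] <- "index.html"
  structure(list(pages = tibble::tibble(page = unlist(pages)), dir = dir),
            class = "browser_manifest")
}

#' @export
print.browser_manifest <- function(x, ...) {
  cat(sprintf("<browser_manifest: %d pages under %s>\n", nrow(x$pages), x$dir))
  invisible(x)
}
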