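#' Configuration of the per-field segmentation pipeline
#'
#' Bundles every tunable of the morphological pipeline for one stain channel.
#' Intensity thresholds are in raw intensity units of the input bit depth;
#' radii and areas are in pixels at the acquisition magnification (defaults
#' assume ~10x, where somata are roughly 18-28 px across).
#'
#' @param soma_open_radius Radius (px) of the disk SE for the greyscale
#'   opening that isolates cell bodies; must be large enough to erase
#'   neurites but comfortably smaller than the smallest soma radius, or the
#'   top-hat retains rim residue around cell bodies. Default 6.
#' @param soma_open_shape SE shape for the opening, `"disk"` or `"square"`.
#' @param soma_threshold Intensity threshold applied to the opened image to
#'   binarize cell bodies.
#' @param neurite_threshold Intensity threshold applied to the top-hat
#'   (original minus opened) image to binarize neurites. The two thresholds
#'   are independent; they default to values suited to the bundled synthetic
#'   renderer and should be set once per experimental image set (see
#'   [suggest_thresholds()]).
#' @param soma_min_area Minimum soma component area (px); smaller opened
#'   blobs are treated as debris. Kept conservatively low by default.
#' @param neurite_min_area Minimum neurite-mask component area (px); removes
#'   specks and imaging artefacts before skeletonization.
#' @param attachment_radius Radius (px) of the disk dilation of the soma mask
#'   used to classify skeleton terminals near a soma as attachment points.
#'   Must bridge the few-pixel cut the pipeline leaves between skeleton and
#'   soma (the opening suppresses the top-hat where a neurite climbs the
#'   soma's intensity skirt) without reaching unrelated structures.
#'   Default 6.
#' @param reference_soma_area User-defined area (px) of a typical single
#'   neuronal cell body; divides total soma area into an estimated neuron
#'   count. Default 400 (~11 px radius disk).
#' @param invert_input If `TRUE`, intensities are complemented before
#'   processing (dark-on-light input such as brightfield silver stains).
#' @param bit_depth Input bit depth, 8 or 16 (used for inversion and
#'   rendering).
#' @param individual_length_denominator Denominator of the average length of
#'   individual neurites: `"attachments"` (default; attachment points count
#'   neurite roots) or `"endpoints"`.
#' @param low_content_min_length,low_content_min_soma_area Floors below which
#'   ratio-based derived measurements of a field are flagged low-content
#'   (complex ratios are unreliable when only a few small fragments are
#'   measured).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(soma_open_radius = 6,
                            soma_open_shape = c("disk", "square"),
                            soma_threshold = 100,
                            neurite_threshold = 35,
                            soma_min_area = 60,
                            neurite_min_area = 12,
                            attachment_radius = 6,
                            reference_soma_area = 400,
                            invert_input = FALSE,
                            bit_depth = 8,
                            individual_length_denominator = c("attachments",
                                                              "endpoints"),
                            low_content_min_length = 50,
                            low_content_min_soma_area = 100) {
  soma_open_shape <- match.arg(soma_open_shape)
  individual_length_denominator <- match.arg(individual_length_denominator)
  stopifnot(soma_open_radius >= 1, attachment_radius >= 1,
            soma_threshold >= 0, neurite_threshold >= 0,
            soma_min_area >= 0, neurite_min_area >= 0,
            reference_soma_area > 0, bit_depth %in% c(8, 16))
  structure(list(
    soma_open_se = structuring_element(soma_open_radius, soma_open_shape),
    soma_threshold = soma_threshold,
    neurite_threshold = neurite_threshold,
    soma_min_area = soma_min_area,
    neurite_min_area = neurite_min_area,
    attachment_se = structuring_element(attachment_radius, "disk"),
    reference_soma_area = reference_soma_area,
    invert_input = isTRUE(invert_input),
    bit_depth = bit_depth,
    individual_length_denominator = individual_length_denominator,
    low_content_min_length = low_content_min_length,
    low_content_min_soma_area = low_content_min_soma_area
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  soma opening: %s r=%d, threshold %g, min area %g px\n",
              x$soma_open_se$shape, x$soma_open_se$radius, x$soma_threshold,
              x$soma_min_area))
  cat(sprintf("  neurites: top-hat threshold %g, min area %g px\n",
              x$neurite_threshold, x$neurite_min_area))
  cat(sprintf("  attachment dilation r=%d; reference soma area %g px\n",
              x$attachment_se$radius, x$reference_soma_area))
  if (x$invert_input) cat("  input inverted (dark-on-light)\n")
  invisible(x)
}

check_config <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) {
    stop("`cfg` must be a `pipeline_config`", call. = FALSE)
  }
  invisible(cfg)
}

#' Suggest binarization thresholds for an image set
#'
#' Non-interactive helper: applies Otsu's method to the opened image (soma
#' channel) and to the top-hat image restricted to non-trivial values
#' (neurite channel), returning a starting point for
#' [pipeline_config()] thresholds. Intended to be run on a few
#' representative fields and then fixed for the whole experiment, since a
#' single preset threshold per image set is the operating assumption of the
#' pipeline.
#'
#' @param img Numeric intensity matrix.
#' @param cfg A [pipeline_config()] supplying the opening SE and bit depth.
#' @return Named list with `soma_threshold` and `neurite_threshold`.
#' @export
suggest_thresholds <- function(img, cfg = pipeline_config()) {
  check_grey(img)
  check_config(cfg)
  if (cfg$invert_input) img <- invert_image(img, cfg$bit_depth)
  mx <- 2^cfg$bit_depth - 1
  opened <- grey_open(img, cfg$soma_open_se)
  tophat <- img_subtract(img, opened)
  otsu <- function(x) {
    x <- as.numeric(EBImage::otsu(x / mx, range = c(0, 1))) * mx
    x
  }
  list(soma_threshold = otsu(opened), neurite_threshold = otsu(tophat))
}

#' Segment neuronal cell bodies in one field
#'
#' Greyscale opening amplifies globular structures and erases fibres; the
#' opened image is binarized at `soma_threshold` and small components are
#' removed.
#'
#' @param img Numeric intensity matrix (already inverted if applicable).
#' @param cfg A [pipeline_config()].
#' @return Logical soma mask.
#' @export
segment_somata <- function(img, cfg = pipeline_config()) {
  check_grey(img)
  check_config(cfg)
  size_filter(binarize(grey_open(img, cfg$soma_open_se), cfg$soma_threshold),
              cfg$soma_min_area, connectivity = 8)
}

#' Segment and skeletonize neurites in one field
#'
#' The white top-hat (original minus opened image) isolates fibre-like
#' structures; it is binarized at `neurite_threshold`, debris below
#' `neurite_min_area` is removed, the mask is thinned to a one-pixel-wide
#' skeleton, and skeleton pixels overlapping the soma mask are subtracted so
#' that neurites running over cell bodies are excluded. The returned skeleton
#' is therefore disjoint from `soma_mask`; an unattached neurite crossing a
#' soma is split into two components (a documented limitation).
#'
#' @param img Numeric intensity matrix.
#' @param soma_mask Soma mask from [segment_somata()] on the same image.
#' @param cfg A [pipeline_config()].
#' @return Logical skeleton mask, disjoint from `soma_mask`.
#' @export
segment_neurites <- function(img, soma_mask, cfg = pipeline_config()) {
  check_grey(img)
  soma_mask <- check_mask(soma_mask, "soma_mask")
  check_config(cfg)
  tophat <- img_subtract(img, grey_open(img, cfg$soma_open_se))
  nmask <- size_filter(binarize(tophat, cfg$neurite_threshold),
                       cfg$neurite_min_area, connectivity = 8)
  skeletonize(nmask) & !soma_mask
}

# terminals of the soma-cut skeleton, split into tips (far from any soma)
# and attachment points (inside the dilated soma zone). Every terminal is
# exactly one of the two.
split_terminals <- function(skel, soma_mask, cfg) {
  terms <- find_endpoints(skel)
  zone <- dilate_mask(soma_mask, cfg$attachment_se)
  list(tips = terms & !zone, attachments = terms & zone & !soma_mask)
}

#' Detect neurite endpoints (tips)
#'
#' Neurite tips are skeleton terminals that do not lie in the soma
#' neighbourhood (the soma mask dilated by the attachment SE). Terminals
#' inside that zone are the cut ends where the skeleton meets a cell body
#' and are reported by [detect_attachments()] instead, so that an attached
#' unbranched neurite contributes exactly one tip.
#'
#' @param skel Skeleton mask from [segment_neurites()] (disjoint from
#'   `soma_mask`).
#' @param soma_mask Soma mask from [segment_somata()].
#' @param cfg A [pipeline_config()].
#' @return Logical mask of tip pixels.
#' @export
detect_endpoints <- function(skel, soma_mask, cfg = pipeline_config()) {
  skel <- check_mask(skel, "skel")
  soma_mask <- check_mask(soma_mask, "soma_mask")
  check_config(cfg)
  split_terminals(skel, soma_mask, cfg)$tips
}

#' Detect neurite-cell body attachment points
#'
#' An attachment point is a skeleton terminal lying within the dilated soma
#' mask (but outside the soma itself): the proximal cut end left where the
#' skeleton was severed at the cell-body boundary. In the generic case this
#' yields one point per neurite-soma junction. Documented failure modes are
#' preserved: an unattached neurite crossing a soma is cut into two and
#' counted as two attachments, while tangential contacts and tight V-shaped
#' double attachments leave no terminal near the soma and count as none.
#'
#' @inheritParams detect_endpoints
#' @return Logical mask of attachment-point pixels.
#' @export
detect_attachments <- function(skel, soma_mask, cfg = pipeline_config()) {
  skel <- check_mask(skel, "skel")
  soma_mask <- check_mask(soma_mask, "soma_mask")
  check_config(cfg)
  split_terminals(skel, soma_mask, cfg)$attachments
}

# skeleton length with diagonal steps weighted sqrt(2) (secondary,
# non-canonical measure; the primary length is the raw pixel count)
diag_corrected_length <- function(skel) {
  if (!any(skel)) return(0)
  orth <- sum(skel & shift_mat(skel, 1L, 0L)) + sum(skel & shift_mat(skel, 0L, 1L))
  diag <- sum(skel & shift_mat(skel, 1L, 1L)) + sum(skel & shift_mat(skel, -1L, 1L))
  n_px <- sum(skel)
  n_comp <- max(label_components(skel, 8))
  # polygonal length of the adjacency graph, one unit per pixel plus edge
  # weights; reduces to n_px for an isolated straight run
  orth + sqrt(2) * diag + n_comp
}

#' Measure one field of view
#'
#' Runs the full per-field pipeline: soma segmentation, neurite top-hat
#' segmentation and skeletonization, tip and attachment detection, and the
#' primary per-field measurements. Total neurite length is the raw pixel
#' count of the skeleton; a diagonal-corrected polygonal length is reported
#' as a clearly secondary column (`neurite_length_diag`).
#'
#' @param img Numeric intensity matrix (one greyscale field).
#' @param cfg A [pipeline_config()]; if `cfg$invert_input` is set the image
#'   is complemented before segmentation (mean intensity is still reported on
#'   the image as given).
#' @param field_id Optional identifier copied into the measurement row (and
#'   into error messages).
#' @return A list of class `"field_result"` with
#'   * `segmentation`: soma mask, neurite skeleton, endpoint and
#'     attachment-point masks;
#'   * `measurements`: a one-row tibble with `total_neurite_length`,
#'     `total_soma_area`, `soma_count`, `avg_soma_cluster_area`,
#'     `endpoint_count`, `attachment_count`, `mean_intensity` and
#'     `neurite_length_diag`.
#' @examples
#' f <- generate_field(n_neurons = 2, seed = 1)
#' res <- measure_field(f$image)
#' res$measurements
#' @export
measure_field <- function(img, cfg = pipeline_config(), field_id = NULL) {
  if (is.null(img) || !is.matrix(img) || length(img) == 0) {
    stop(sprintf("empty or unreadable image%s",
                 if (!is.null(field_id)) paste0(" [", field_id, "]") else ""),
         call. = FALSE)
  }
  check_grey(img)
  check_config(cfg)
  work <- if (cfg$invert_input) invert_image(img, cfg$bit_depth) else img
  # same steps as segment_somata() + segment_neurites(), sharing one opening
  opened <- grey_open(work, cfg$soma_open_se)
  soma <- size_filter(binarize(opened, cfg$soma_threshold),
                      cfg$soma_min_area, connectivity = 8)
  nmask <- size_filter(binarize(img_subtract(work, opened),
                                cfg$neurite_threshold),
                       cfg$neurite_min_area, connectivity = 8)
  skel <- skeletonize(nmask) & !soma
  terms <- split_terminals(skel, soma, cfg)
  soma_area <- sum(soma)
  soma_count <- if (soma_area > 0) max(label_components(soma, 8)) else 0L
  meas <- tibble::tibble(
    field_id = if (is.null(field_id)) NA_character_ else as.character(field_id),
    total_neurite_length = sum(skel),
    total_soma_area = soma_area,
    soma_count = as.integer(soma_count),
    avg_soma_cluster_area = if (soma_count > 0) soma_area / soma_count else 0,
    endpoint_count = sum(terms$tips),
    attachment_count = sum(terms$attachments),
    mean_intensity = mean(img),
    neurite_length_diag = diag_corrected_length(skel)
  )
  structure(list(
    segmentation = list(soma_mask = soma, neurite_skeleton = skel,
                        endpoints = terms$tips,
                        attachment_points = terms$attachments),
    measurements = meas,
    config = cfg
  ), class = "field_result")
}

#' @export
print.field_result <- function(x, ...) {
  cat("<field_result>\n")
  print(x$measurements)
  invisible(x)
}

#' Render a colour-coded overlay of a segmented field
#'
#' Produces an RGB array in the review colour code: raw image as grey
#' background, total soma area red, skeletonized neurites green, neurite
#' endpoints cyan and attachment points yellow (point markers are dilated
#' for visibility).
#'
#' @param result A `"field_result"` from [measure_field()].
#' @param img The raw intensity matrix that was measured.
#' @return Numeric array `height x width x 3` in `[0, 1]`, suitable for
#'   [png::writePNG()].
#' @export
render_overlay <- function(result, img) {
  stopifnot(inherits(result, "field_result"))
  check_grey(img)
  seg <- result$segmentation
  mx <- max(2^result$config$bit_depth - 1, max(img))
  base <- img / mx * 0.6
  r <- base; g <- base; b <- base
  r[seg$soma_mask] <- 1; g[seg$soma_mask] <- 0.1; b[seg$soma_mask] <- 0.1
  g[seg$neurite_skeleton] <- 1
  r[seg$neurite_skeleton] <- 0.1; b[seg$neurite_skeleton] <- 0.1
  ep <- dilate_mask(seg$endpoints, 1)
  ap <- dilate_mask(seg$attachment_points, 1)
  r[ep] <- 0; g[ep] <- 1; b[ep] <- 1          # cyan tips
  r[ap] <- 1; g[ap] <- 1; b[ap] <- 0          # yellow attachments
  out <- array(0, c(nrow(img), ncol(img), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
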