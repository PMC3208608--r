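#' @name synthetic
#' @title Synthetic neuron-field generator with exact ground truth
#' @description
#' Renders neuron-culture-like greyscale fields (bright somata and thin
#' neurites on a noisy background) together with exact morphological ground
#' truth: per-neuron neurite arc length, tip, attachment and junction counts,
#' and soma footprints. Neurite paths are axis-aligned staircases on the
#' integer grid, so the true arc length in pixels is directly comparable to
#' the pipeline's skeleton pixel count. In `"clean"` mode an occupancy map
#' keeps every structure at least ~5 px from every other, making tip,
#' attachment and junction counts exactly recoverable; `"overlap"` adds
#' unattached neurites crossing somata (the documented failure modes);
#' `"debris"` sprinkles sub-threshold specks that a correct size filter must
#' ignore.
NULL

.dirs <- list(N = c(-1L, 0L), S = c(1L, 0L), E = c(0L, 1L), W = c(0L, -1L))

# pixels start + i*d for i = 1..len (len >= 0)
run_pixels <- function(start, d, len) {
  if (len <= 0) return(matrix(integer(0), 0, 2))
  cbind(start[1] + seq_len(len) * d[1], start[2] + seq_len(len) * d[2])
}

# steps available from `cur` along `d` before entering the border margin
max_steps <- function(cur, d, dims, margin) {
  if (d[1] == -1) return(cur[1] - margin - 1L)
  if (d[1] ==  1) return(dims[1] - margin - cur[1])
  if (d[2] == -1) return(cur[2] - margin - 1L)
  dims[2] - margin - cur[2]
}

# one axis-aligned staircase neurite plan with optional single branch.
# Returns NULL if too short, else list(pixels, run_dir_idx, tips, junctions,
# root, length)
plan_neurite <- function(center, soma_r, dir_name, target_len, branch_prob,
                         dims, margin, max_turns = 2L) {
  d <- .dirs[[dir_name]]
  perp <- if (d[1] == 0) list(c(-1L, 0L), c(1L, 0L)) else
    list(c(0L, -1L), c(0L, 1L))
  p <- perp[[sample.int(2, 1)]]
  n_runs <- if (max_turns == 0L || target_len < 40) 1L else
    sample.int(max_turns + 1L, 1)
  lens <- if (n_runs == 1) target_len else {
    w <- stats::runif(n_runs, 0.5, 1.5)
    pmax(12L, as.integer(round(target_len * w / sum(w))))
  }
  start <- c(center[1] + (soma_r + 1L) * d[1], center[2] + (soma_r + 1L) * d[2])
  cur <- start
  pix <- matrix(start, 1, 2)
  run_dir <- integer(1)           # direction index per pixel: 1 = d, 2 = perp
  for (i in seq_len(n_runs)) {
    dd <- if (i %% 2 == 1) d else p
    len <- min(lens[i], max_steps(cur, dd, dims, margin))
    if (len <= 0) break
    seg <- run_pixels(cur, dd, len)
    pix <- rbind(pix, seg)
    run_dir <- c(run_dir, rep(if (i %% 2 == 1) 1L else 2L, len))
    cur <- seg[nrow(seg), ]
  }
  if (nrow(pix) < 15) return(NULL)
  tips <- matrix(pix[nrow(pix), ], 1, 2)
  junctions <- matrix(integer(0), 0, 2)
  branch_pix <- NULL
  if (stats::runif(1) < branch_prob && nrow(pix) >= 50) {
    # branch perpendicular off an outward (direction-d) segment
    cand_idx <- which(run_dir == 1L)
    cand_idx <- cand_idx[cand_idx >= round(0.35 * nrow(pix)) &
                           cand_idx <= round(0.85 * nrow(pix))]
    if (length(cand_idx) >= 3) {
      j <- cand_idx[sample.int(length(cand_idx), 1)]
      bp <- perp[[sample.int(2, 1)]]
      bl <- as.integer(round(stats::runif(1, 0.3, 0.6) * nrow(pix)))
      bl <- min(bl, max_steps(pix[j, ], bp, dims, margin))
      if (bl >= 12) {
        bpix <- run_pixels(pix[j, ], bp, bl)
        # keep the branch only if it stays clear of the rest of the arbor
        # (staircase turns can otherwise fold it back onto the main path)
        far <- bpix[-seq_len(3), , drop = FALSE]
        sep <- if (nrow(far)) {
          min(pmax(abs(outer(far[, 1], pix[, 1], "-")),
                   abs(outer(far[, 2], pix[, 2], "-"))))
        } else 99
        if (sep >= 4) {
          branch_pix <- bpix
          junctions <- matrix(pix[j, ], 1, 2)
          tips <- rbind(tips, branch_pix[nrow(branch_pix), ])
        }
      }
    }
  }
  all_pix <- unique(rbind(pix, branch_pix))
  list(pixels = all_pix, tips = tips, junctions = junctions,
       root = start, length = nrow(all_pix))
}

paint <- function(canvas, pix, value) {
  canvas[pix[, 1] + (pix[, 2] - 1L) * nrow(canvas)] <- value
  canvas
}

mask_from_pixels <- function(pix, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  if (nrow(pix)) m[pix[, 1] + (pix[, 2] - 1L) * dims[1]] <- TRUE
  m
}

disk_pixels <- function(center, r, dims) {
  rr <- max(1L, center[1] - r):min(dims[1], center[1] + r)
  cc <- max(1L, center[2] - r):min(dims[2], center[2] + r)
  g <- expand.grid(rr, cc)
  keep <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 <= r^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Generate one synthetic field with ground truth
#'
#' @param n_neurons Number of neurons to place (>= 0).
#' @param difficulty `"clean"` (structures mutually separated; counts exactly
#'   recoverable), `"overlap"` (adds unattached soma-crossing neurites and
#'   allows closer packing) or `"debris"` (clean plus sub-threshold bright
#'   specks).
#' @param seed Integer seed; the same seed gives a bit-identical field and
#'   truth.
#' @param width,height Field size in pixels.
#' @param soma_radius_range Min/max soma radius (px).
#' @param neurites_per_soma Min/max neurites per neuron (capped at 4: one per
#'   cardinal direction, which guarantees separation at the soma).
#' @param neurite_length_range Min/max requested neurite arc length (px),
#'   multiplied by `length_scale` (the dose-response dial used by
#'   [generate_plate()]).
#' @param length_scale Multiplier on neurite lengths.
#' @param branch_prob Probability that a neurite carries one side branch.
#' @param max_turns Maximum number of 90-degree turns per neurite (0 renders
#'   straight radial neurites whose arc length equals the request exactly,
#'   useful for calibrated screens).
#' @param placement_margin Minimum distance (px) of soma centres from the
#'   field border; defaults to the maximum soma radius + 8. Raise it so that
#'   neurites cannot reach the border when exact lengths are required.
#' @param min_soma_gap Minimum clearance (px) between soma rims beyond the
#'   default packing (16 in separated modes); raise it so neurites of
#'   different neurons cannot interact when exact per-field totals are
#'   required.
#' @param soma_value,neurite_value,background Rendered intensities (8-bit
#'   scale).
#' @param blur_sigma Gaussian blur sigma (px) applied after painting.
#' @param noise_sd Additive Gaussian noise SD.
#' @param n_debris Number of specks in `"debris"` mode.
#' @param bit_depth Output bit depth (8 or 16; rendering values are scaled up
#'   for 16).
#' @return List of class `"synthetic_field"`: `image` (integer-valued
#'   intensity matrix) and `truth`, a list with a per-neuron tibble
#'   (`neurons`), tip/junction coordinates, crossing metadata and the totals
#'   `total_true_length`, `total_true_soma_area`, `true_tip_count`,
#'   `true_attachment_count`, `true_junction_count`.
#' @examples
#' f <- generate_field(3, seed = 7)
#' f$truth$total_true_length
#' @export
generate_field <- function(n_neurons,
                           difficulty = c("clean", "overlap", "debris"),
                           seed = 1,
                           width = 512, height = 512,
                           soma_radius_range = c(9, 14),
                           neurites_per_soma = c(1, 4),
                           neurite_length_range = c(60, 140),
                           length_scale = 1,
                           branch_prob = 0.3,
                           max_turns = 2,
                           placement_margin = NULL,
                           min_soma_gap = NULL,
                           soma_value = 200, neurite_value = 150,
                           background = 20, blur_sigma = 1, noise_sd = 4,
                           n_debris = 30,
                           bit_depth = 8) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_neurons >= 0, width >= 64, height >= 64,
            soma_radius_range[1] >= 3, bit_depth %in% c(8, 16))
  dims <- c(height, width)
  withr::with_seed(as.integer(seed), {
    margin <- 6L
    rmax <- soma_radius_range[2]
    clean_sep <- difficulty != "overlap"
    # --- place somata -------------------------------------------------------
    centers <- matrix(integer(0), 0, 2)
    radii <- integer(0)
    tries <- 0L
    while (nrow(centers) < n_neurons) {
      tries <- tries + 1L
      if (tries > 600L * max(n_neurons, 1)) {
        stop("infeasible placement for requested geometry", call. = FALSE)
      }
      rr <- soma_radius_range[1]:soma_radius_range[2]
      r <- rr[sample.int(length(rr), 1)]
      m <- if (is.null(placement_margin)) rmax + 8L else
        as.integer(placement_margin)
      ctr <- c(sample((m + 1):(dims[1] - m), 1), sample((m + 1):(dims[2] - m), 1))
      min_gap <- if (!is.null(min_soma_gap)) as.integer(min_soma_gap) else
        if (clean_sep) 16L else 2L
      if (nrow(centers)) {
        dist2 <- (centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2
        if (any(dist2 < (radii + r + min_gap)^2)) next
      }
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
    }
    occ <- matrix(FALSE, dims[1], dims[2])
    soma_pix_list <- vector("list", n_neurons)
    for (i in seq_len(n_neurons)) {
      soma_pix_list[[i]] <- disk_pixels(centers[i, ], radii[i], dims)
      occ <- occ | mask_from_pixels(disk_pixels(centers[i, ], radii[i] + 8L,
                                                dims), dims)
    }
    # --- grow neurites ------------------------------------------------------
    neurite_pix <- matrix(integer(0), 0, 2)
    neurons <- vector("list", n_neurons)
    all_tips <- matrix(integer(0), 0, 2)
    all_junctions <- matrix(integer(0), 0, 2)
    for (i in seq_len(n_neurons)) {
      kr <- neurites_per_soma[1]:min(neurites_per_soma[2], 4L)
      k_req <- kr[sample.int(length(kr), 1)]
      dirs <- sample(names(.dirs), k_req)
      exempt <- mask_from_pixels(disk_pixels(centers[i, ], radii[i] + 8L, dims),
                                 dims)
      kept <- 0L; n_j <- 0L; n_t <- 0L; len_i <- 0L
      for (dn in dirs) {
        L <- as.integer(round(stats::runif(1, neurite_length_range[1],
                                           neurite_length_range[2]) *
                                length_scale))
        # keep the longest feasible plan over a few tries; stop early once a
        # try reaches 90% of the requested arc length
        best <- NULL
        for (try in 1:8) {
          pl <- plan_neurite(centers[i, ], radii[i], dn, L, branch_prob,
                             dims, margin, max_turns = as.integer(max_turns))
          if (is.null(pl)) next
          cand <- mask_from_pixels(pl$pixels, dims)
          if (clean_sep) {
            conflict <- any(dilate_mask(cand,
                                        structuring_element(2, "square")) &
                              occ & !exempt)
            if (conflict) next
          }
          if (is.null(best) || pl$length > best$length) {
            best <- pl
            best$cand <- cand
          }
          if (pl$length >= 0.9 * L) break
        }
        if (is.null(best)) next
        neurite_pix <- rbind(neurite_pix, best$pixels)
        occ <- occ | dilate_mask(best$cand, structuring_element(2, "square"))
        kept <- kept + 1L
        n_j <- n_j + nrow(best$junctions)
        n_t <- n_t + nrow(best$tips)
        len_i <- len_i + best$length
        all_tips <- rbind(all_tips, best$tips)
        all_junctions <- rbind(all_junctions, best$junctions)
      }
      neurons[[i]] <- tibble::tibble(
        neuron = i, soma_row = centers[i, 1], soma_col = centers[i, 2],
        soma_radius = radii[i], soma_area = nrow(soma_pix_list[[i]]),
        n_neurites = kept, n_junctions = n_j, n_tips = n_t,
        true_length = len_i
      )
    }
    neurons <- if (n_neurons > 0) dplyr::bind_rows(neurons) else
      tibble::tibble(neuron = integer(0), soma_row = integer(0),
                     soma_col = integer(0), soma_radius = integer(0),
                     soma_area = integer(0), n_neurites = integer(0),
                     n_junctions = integer(0), n_tips = integer(0),
                     true_length = integer(0))
    # --- overlap: unattached neurites crossing somata -----------------------
    crossings <- tibble::tibble(neuron = integer(0), length = integer(0))
    crossing_pix <- matrix(integer(0), 0, 2)
    if (difficulty == "overlap" && n_neurons > 0) {
      n_cross <- max(1L, n_neurons %/% 3L)
      targets <- sample(seq_len(n_neurons), n_cross)
      for (i in targets) {
        d <- .dirs[[sample(names(.dirs), 1)]]
        half <- radii[i] + 45L
        a <- pmax(pmin(centers[i, ] - half * d, dims - margin), margin + 1L)
        len <- 2L * half
        seg <- rbind(a, run_pixels(a, d, min(len, max_steps(a, d, dims,
                                                            margin))))
        inside <- (seg[, 1] - centers[i, 1])^2 +
          (seg[, 2] - centers[i, 2])^2 <= radii[i]^2
        crossing_pix <- rbind(crossing_pix, seg)
        crossings <- dplyr::bind_rows(
          crossings, tibble::tibble(neuron = i, length = sum(!inside)))
      }
    }
    # --- debris -------------------------------------------------------------
    debris_pix <- matrix(integer(0), 0, 2)
    if (difficulty == "debris") {
      forbid <- dilate_mask(occ, structuring_element(3, "square"))
      free <- which(!forbid)
      free <- free[free %% dims[1] > margin + 2 &
                     free %% dims[1] < dims[1] - margin - 2]
      if (length(free) > n_debris) {
        at <- sample(free, n_debris)
        for (a in at) {
          r0 <- ((a - 1L) %% dims[1]) + 1L
          c0 <- ((a - 1L) %/% dims[1]) + 1L
          sz <- sample.int(4L, 1)
          off <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))[seq_len(sz),
                                                                   , drop = FALSE]
          debris_pix <- rbind(debris_pix,
                              cbind(pmin(r0 + off[, 1], dims[1] - margin),
                                    pmin(c0 + off[, 2], dims[2] - margin)))
        }
      }
    }
    # --- render -------------------------------------------------------------
    scale <- if (bit_depth == 16) 257 else 1
    canvas <- matrix(background, dims[1], dims[2])
    if (nrow(neurite_pix)) canvas <- paint(canvas, neurite_pix, neurite_value)
    if (nrow(crossing_pix)) canvas <- paint(canvas, crossing_pix, neurite_value)
    if (nrow(debris_pix)) canvas <- paint(canvas, debris_pix,
                                          neurite_value + 30)
    for (i in seq_len(n_neurons)) {
      canvas <- paint(canvas, soma_pix_list[[i]], soma_value)
    }
    if (blur_sigma > 0) {
      canvas <- unclass(EBImage::gblur(canvas, sigma = blur_sigma))
      dim(canvas) <- dims
    }
    mxv <- 2^bit_depth - 1
    img <- canvas * scale + stats::rnorm(length(canvas), 0, noise_sd * scale)
    img <- matrix(round(pmin(pmax(img, 0), mxv)), dims[1], dims[2])
    truth <- list(
      neurons = neurons,
      tips = all_tips,
      junctions = all_junctions,
      crossings = crossings,
      total_true_length = sum(neurons$true_length) + sum(crossings$length),
      total_true_soma_area = sum(neurons$soma_area),
      true_tip_count = sum(neurons$n_tips) + 2L * nrow(crossings),
      true_attachment_count = sum(neurons$n_neurites),
      true_junction_count = sum(neurons$n_junctions),
      n_crossings = nrow(crossings),
      render_params = list(difficulty = difficulty, seed = as.integer(seed),
                           width = width, height = height,
                           blur_sigma = blur_sigma, noise_sd = noise_sd,
                           background = background, bit_depth = bit_depth,
                           length_scale = length_scale)
    )
    structure(list(image = img, truth = truth), class = "synthetic_field")
  })
}

#' @export
print.synthetic_field <- function(x, ...) {
  t <- x$truth
  cat(sprintf(
    "<synthetic_field %dx%d, %s: %d neurons, length %d px, %d tips, %d roots, %d junctions>\n",
    ncol(x$image), nrow(x$image), t$render_params$difficulty,
    nrow(t$neurons), t$total_true_length, t$true_tip_count,
    t$true_attachment_count, t$true_junction_count))
  invisible(x)
}

#' Generate a synthetic multi-well plate on disk
#'
#' Renders one image per well/field following the batch naming convention
#' `{plate}_{well}_f{field}_{channel}.tif` and writes a tab-delimited truth
#' manifest plus a well annotation table, enabling end-to-end screen tests
#' (tables, heatmaps, Z-factor recovery) without any external data.
#'
#' @param layout Tibble/data frame with one row per well: columns `well`,
#'   `condition`, optional `dose`, and per-well generator parameters
#'   `n_neurons` and `length_scale` (missing ones default to 6 and 1).
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; per-field seeds are derived from it.
#' @param plate Plate identifier used in filenames.
#' @param channel Channel label used in filenames.
#' @param n_fields Fields per well.
#' @param width,height Field size (px).
#' @param length_scale_sd Standard deviation of per-field Gaussian variation
#'   around each well's `length_scale` (drawn deterministically from the
#'   field seed; realized values recorded in the manifest). This is the dial
#'   for emulating biological field-to-field variability in screens, e.g.
#'   when constructing two-condition plates with a prescribed Z-factor.
#' @param ... Further arguments passed to [generate_field()].
#' @return List of class `"synthetic_plate"`: `manifest` (per-field tibble of
#'   parameters and true totals), `annotation` (well/condition/dose tibble),
#'   and the paths `dir`, `manifest_path`, `annotation_path`.
#' @export
generate_plate <- function(layout, dir, seed = 1, plate = "P1",
                           channel = "TuJ1", n_fields = 2,
                           width = 256, height = 256,
                           length_scale_sd = 0, ...) {
  layout <- tibble::as_tibble(layout)
  if (nrow(layout) > 0 && !all(c("well", "condition") %in% names(layout))) {
    stop("`layout` needs at least `well` and `condition` columns",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!"n_neurons" %in% names(layout)) layout$n_neurons <- 6L
  if (!"length_scale" %in% names(layout)) layout$length_scale <- 1
  if (!"dose" %in% names(layout)) layout$dose <- NA_real_
  rows <- list()
  idx <- 0L
  for (w in seq_len(nrow(layout))) {
    for (f in seq_len(n_fields)) {
      idx <- idx + 1L
      fseed <- (as.integer(seed) + 131L * idx) %% .Machine$integer.max
      ls_w <- layout$length_scale[w]
      if (length_scale_sd > 0) {
        ls_w <- withr::with_seed(fseed + 7L,
                                 max(0.05, stats::rnorm(1, ls_w,
                                                        length_scale_sd)))
      }
      fld <- generate_field(layout$n_neurons[w], seed = fseed,
                            width = width, height = height,
                            length_scale = ls_w, ...)
      fname <- sprintf("%s_%s_f%d_%s.tif", plate, layout$well[w], f, channel)
      tiff::writeTIFF(fld$image / (2^fld$truth$render_params$bit_depth - 1),
                      file.path(dir, fname), bits.per.sample = 8L)
      t <- fld$truth
      rows[[idx]] <- tibble::tibble(
        plate = plate, well = layout$well[w], field = f, channel = channel,
        file = fname, condition = layout$condition[w], dose = layout$dose[w],
        n_neurons = layout$n_neurons[w],
        length_scale = ls_w, seed = fseed,
        total_true_length = t$total_true_length,
        total_true_soma_area = t$total_true_soma_area,
        true_tip_count = t$true_tip_count,
        true_attachment_count = t$true_attachment_count,
        true_junction_count = t$true_junction_count
      )
    }
  }
  manifest <- if (idx > 0) dplyr::bind_rows(rows) else tibble::tibble()
  annotation <- layout[, intersect(c("well", "condition", "dose"),
                                   names(layout))]
  manifest_path <- file.path(dir, "truth_manifest.tsv")
  annotation_path <- file.path(dir, "annotation.tsv")
  readr::write_tsv(manifest, manifest_path)
  readr::write_tsv(annotation, annotation_path)
  structure(list(manifest = manifest, annotation = annotation, dir = dir,
                 manifest_path = manifest_path,
                 annotation_path = annotation_path),
            class = "synthetic_plate")
}
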