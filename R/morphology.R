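#' Structuring element for morphological operations
#'
#' Builds a flat structuring element (SE) used by [grey_open()],
#' [dilate_mask()] and [erode_mask()]. A `"disk"` SE of radius `r` contains
#' all pixels within Euclidean distance `r` of the centre; a `"square"` SE is
#' the (2r+1) x (2r+1) box.
#'
#' @param radius Integer radius in pixels (>= 1).
#' @param shape `"disk"` (default) or `"square"`.
#' @return An object of class `"struct_elem"`: a list with `shape`, `radius`
#'   and the 0/1 kernel matrix used by the morphology backend.
#' @examples
#' se <- structuring_element(3)
#' dim(se$kernel)
#' @export
structuring_element <- function(radius, shape = c("disk", "square")) {
  shape <- match.arg(shape)
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1 ||
      radius != round(radius)) {
    stop("`radius` must be a single integer >= 1", call. = FALSE)
  }
  radius <- as.integer(radius)
  kern <- EBImage::makeBrush(2L * radius + 1L,
                             shape = if (shape == "disk") "disc" else "box")
  structure(list(shape = shape, radius = radius, kernel = kern),
            class = "struct_elem")
}

#' @export
print.struct_elem <- function(x, ...) {
  cat(sprintf("<struct_elem: %s, radius %d px>\n", x$shape, x$radius))
  invisible(x)
}

as_se <- function(se) {
  if (inherits(se, "struct_elem")) return(se)
  if (is.numeric(se) && length(se) == 1) return(structuring_element(se))
  stop("expected a `struct_elem` or a numeric radius", call. = FALSE)
}

check_grey <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix of pixel intensities", arg),
         call. = FALSE)
  }
  if (any(img < 0)) {
    stop(sprintf("`%s` contains negative intensities", arg), call. = FALSE)
  }
  invisible(img)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) {
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  }
  if (!is.logical(mask)) mask <- mask != 0
  mask
}

#' Greyscale morphological opening
#'
#' Erosion followed by dilation with a flat structuring element. Opening
#' suppresses bright structures thinner than the SE (neurites) while
#' preserving wider ones (somata); it is anti-extensive, increasing and
#' idempotent.
#'
#' @param img Numeric matrix of intensities.
#' @param se A [structuring_element()] (or a numeric radius, taken as a disk).
#' @return Numeric matrix, same shape as `img`, with `result <= img`
#'   pixelwise.
#' @seealso [img_subtract()] for the top-hat used to isolate neurites.
#' @export
grey_open <- function(img, se) {
  check_grey(img)
  se <- as_se(se)
  if (2 * se$radius >= min(dim(img))) {
    stop("structuring element exceeds image", call. = FALSE)
  }
  # the morphology backend expects intensities in [0, 1]; min/max filters
  # commute with positive scaling and only ever select input values, so
  # normalizing by a power of two keeps every division exact and the result
  # bit-reproducible under intensity co-scaling
  mx <- 2^ceiling(log2(max(img, 1)))
  out <- EBImage::opening(img / mx, se$kernel)
  out <- unclass(out) * mx
  dim(out) <- dim(img)
  out
}

#' Clamped image subtraction
#'
#' Pixelwise `max(a - b, 0)`. Used as `img - grey_open(img, se)`
#' (a white top-hat) to isolate thin bright fibre-like structures. Values are
#' clamped at zero and never wrap around.
#'
#' @param a,b Numeric matrices of identical shape.
#' @return Numeric matrix `pmax(a - b, 0)`.
#' @export
img_subtract <- function(a, b) {
  check_grey(a, "a")
  check_grey(b, "b")
  if (!identical(dim(a), dim(b))) {
    stop("image shape mismatch in subtraction", call. = FALSE)
  }
  pmax(a - b, 0)
}

#' Threshold a greyscale image to a binary mask
#'
#' The mask is `TRUE` exactly where intensity is strictly greater than
#' `threshold`. Because the pipeline thresholds morphologically enhanced
#' images, `binarize(k * img, k * t)` equals `binarize(img, t)` for any
#' positive scale `k`: global staining-intensity changes do not move the
#' segmentation.
#'
#' @param img Numeric matrix of intensities.
#' @param threshold Single non-negative intensity.
#' @return Logical matrix.
#' @export
binarize <- function(img, threshold) {
  check_grey(img)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  }
  img > threshold
}

# shifted copy of a matrix: out[i, j] = x[i + dr, j + dc], `fill` at borders
shift_mat <- function(x, dr, dc, fill = FALSE) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L - dr); er <- min(nr, nr - dr)
  sc <- max(1L, 1L - dc); ec <- min(nc, nc - dc)
  if (sr <= er && sc <= ec) {
    out[sr:er, sc:ec] <- x[(sr + dr):(er + dr), (sc + dc):(ec + dc)]
  }
  out
}

# number of TRUE 8-neighbours of every pixel
neighbour_count8 <- function(mask) {
  n <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + shift_mat(mask, dr, dc)
  }
  n
}

#' Label connected components of a binary mask
#'
#' Components are found on the pixel-adjacency graph (8- or 4-connectivity).
#' Unlike flood-fill labelling that scans from the border, this handles
#' components topologically enclosed by other components (e.g. debris inside
#' a neurite loop) identically to free-standing ones.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default; diagonal neighbours connect) or 4.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- check_mask(mask)
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8",
                                       call. = FALSE)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  verts <- which(mask)
  nv <- length(verts)
  if (nv == 0) return(lab)
  nr <- nrow(mask)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  vmap <- integer(length(mask))
  vmap[verts] <- seq_len(nv)
  from <- integer(0); to <- integer(0)
  for (off in offs) {
    both <- mask & shift_mat(mask, off[1], off[2])
    f <- which(both)
    if (length(f)) {
      from <- c(from, f)
      to <- c(to, f + off[1] + off[2] * nr)
    }
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(vmap[from], vmap[to]))
  }
  memb <- igraph::components(g)$membership
  lab[verts] <- as.integer(memb)
  lab
}

#' Remove small connected components (size filter)
#'
#' Drops every connected component whose pixel area is below `min_area`,
#' including components enclosed by larger objects (such as specks inside
#' neurite loops), which border-seeded particle analysis can miss. Components
#' with area >= `min_area` pass through unchanged; the filter is idempotent.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component area in pixels (components smaller than
#'   this are removed).
#' @param connectivity 8 (default) or 4.
#' @return Logical matrix.
#' @export
size_filter <- function(mask, min_area, connectivity = 8) {
  mask <- check_mask(mask)
  if (!is.numeric(min_area) || length(min_area) != 1 || min_area < 0) {
    stop("`min_area` must be a single number >= 0", call. = FALSE)
  }
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  areas <- tabulate(lab[lab > 0L])
  keep <- areas >= min_area
  out <- mask
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Skeletonize a binary mask to one-pixel-wide curves
#'
#' Homotopy-preserving thinning (Zhang-Suen two-subiteration scheme) that
#' reduces each foreground shape to a one-pixel-wide, 8-connected skeleton
#' with the same number of components and holes. Iterates until no pixel can
#' be removed, then prunes junction spurs: short terminal chains hanging off
#' a pixel where two genuinely distinct arms already meet are thinning
#' artifacts of corners and blur bulges, not real branch tips, and are
#' removed up to `prune_spurs` pixels deep. Real tips terminate long
#' degree-2 chains and are never affected. Pruning leaf chains cannot change
#' component or hole counts, so homotopy is preserved.
#'
#' @param mask Logical matrix.
#' @param prune_spurs Maximum junction-spur length to remove (default 4;
#'   0 disables pruning).
#' @return Logical matrix, a subset of `mask`.
#' @export
skeletonize <- function(mask, prune_spurs = 4) {
  mask <- check_mask(mask)
  if (!any(mask)) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north (P2..P9), rows increase downwards
      p2 <- shift_mat(p, -1L, 0L); p3 <- shift_mat(p, -1L, 1L)
      p4 <- shift_mat(p, 0L, 1L);  p5 <- shift_mat(p, 1L, 1L)
      p6 <- shift_mat(p, 1L, 0L);  p7 <- shift_mat(p, 1L, -1L)
      p8 <- shift_mat(p, 0L, -1L); p9 <- shift_mat(p, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1L) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- p & b >= 2L & b <= 6L & a == 1L & cond
      if (any(del)) {
        p[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sk <- p[2:(nr + 1L), 2:(nc + 1L)]
  if (prune_spurs > 0) sk <- prune_skeleton_spurs(sk, prune_spurs)
  sk
}

# Remove junction spurs from a 1-px skeleton: from every terminal pixel,
# walk along the degree-2 chain for at most `max_len` steps; if the walk
# reaches a junction pixel j (>= 3 neighbours) whose remaining arms, followed
# outward for a few steps, diverge in space (walk ends >= 4 Chebyshev apart),
# then j sits on a genuine through-path and the walked chain is a thinning
# artifact (corner nub / blur bulge) to remove. A zigzag line end also
# presents a degree-3 pixel, but its apparent arms merge into the same chain
# and their walks end adjacent, so the real tip is kept; real branch tips
# terminate chains much longer than `max_len`. Repeats until stable.
# Remove junction spurs from a 1-px skeleton: from every terminal pixel,
# walk along the degree-2 chain for at most `max_len` steps until a pixel
# with >= 3 neighbours is reached. The chain is an artifact (thinning nub at
# a corner, blur bulge) exactly when the skeleton minus the chain still runs
# THROUGH that junction: within a 9x9 window, the component containing the
# junction must reach the window ring at two well-separated places. A zigzag
# line end also presents a >= 3-neighbour pixel, but without the chain the
# local skeleton leaves the window in one direction only, so the real tip is
# kept; genuine branch tips terminate chains much longer than `max_len`.
# Repeats until stable.
prune_skeleton_spurs <- function(sk, max_len) {
  nr <- nrow(sk); nc <- ncol(sk)
  nbrs <- function(p, m) {
    rr <- max(1L, p[1] - 1L):min(nr, p[1] + 1L)
    cc <- max(1L, p[2] - 1L):min(nc, p[2] + 1L)
    w <- as.matrix(expand.grid(rr, cc))
    w <- w[!(w[, 1] == p[1] & w[, 2] == p[2]), , drop = FALSE]
    w[m[w], , drop = FALSE]
  }
  through_junction <- function(j, path, m, halfwin = 4L) {
    rr <- max(1L, j[1] - halfwin):min(nr, j[1] + halfwin)
    cc <- max(1L, j[2] - halfwin):min(nc, j[2] + halfwin)
    win <- m[rr, cc, drop = FALSE]
    for (px in path) {
      if (px[1] %in% rr && px[2] %in% cc) {
        win[px[1] - rr[1] + 1L, px[2] - cc[1] + 1L] <- FALSE
      }
    }
    lab <- label_components(win, 8)
    jl <- lab[j[1] - rr[1] + 1L, j[2] - cc[1] + 1L]
    if (jl == 0L) return(FALSE)
    comp <- which(lab == jl, arr.ind = TRUE)
    cheb <- pmax(abs(comp[, 1] - (j[1] - rr[1] + 1L)),
                 abs(comp[, 2] - (j[2] - cc[1] + 1L)))
    ring <- comp[cheb >= halfwin, , drop = FALSE]
    if (nrow(ring) < 2L) return(FALSE)
    d <- as.matrix(stats::dist(ring, method = "maximum"))
    any(d >= halfwin)
  }
  repeat {
    nb <- neighbour_count8(sk)
    tips <- which(sk & nb == 1L, arr.ind = TRUE)
    removed <- FALSE
    for (k in seq_len(nrow(tips))) {
      cur <- tips[k, ]
      if (!sk[cur[1], cur[2]]) next
      prev <- NULL
      path <- list(cur)
      for (step in seq_len(max_len)) {
        ns <- nbrs(cur, sk)
        if (!is.null(prev)) {
          ns <- ns[!(ns[, 1] == prev[1] & ns[, 2] == prev[2]), , drop = FALSE]
        }
        if (nrow(ns) != 1L) break            # isolated end or odd topology
        j <- ns[1, ]
        if (nb[j[1], j[2]] >= 3L) {
          if (through_junction(j, path, sk)) {
            for (px in path) sk[px[1], px[2]] <- FALSE
            removed <- TRUE
          }
          break
        }
        prev <- cur
        cur <- j
        path[[length(path) + 1L]] <- cur
      }
    }
    if (!removed) break
  }
  sk
}

#' Find terminal pixels of a skeleton
#'
#' A terminal (endpoint) is a foreground pixel with exactly one foreground
#' neighbour in its 8-neighbourhood. On one-pixel-wide skeletons this equals
#' the erode-terminals-then-subtract construction; neighbour counting is used
#' because it is provably identical there and cheaper.
#'
#' @param skel Logical matrix, expected to be one pixel wide (output of
#'   [skeletonize()]).
#' @return Logical matrix marking terminal pixels.
#' @export
find_endpoints <- function(skel) {
  skel <- check_mask(skel, "skel")
  skel & neighbour_count8(skel) == 1L
}

#' Dilate a binary mask
#'
#' Morphological dilation: the union of SE translates centred on every
#' foreground pixel. Extensive (`mask` is a subset of the result).
#'
#' @param mask Logical matrix.
#' @param se A [structuring_element()] or numeric radius (disk).
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, se) {
  mask <- check_mask(mask)
  se <- as_se(se)
  if (!any(mask)) return(mask)
  out <- EBImage::dilate(mask * 1, se$kernel)
  matrix(unclass(out) > 0, nrow(mask), ncol(mask))
}

#' Erode a binary mask
#'
#' Morphological erosion with a flat SE; anti-extensive counterpart of
#' [dilate_mask()].
#'
#' @inheritParams dilate_mask
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, se) {
  mask <- check_mask(mask)
  se <- as_se(se)
  if (!any(mask)) return(mask)
  out <- EBImage::erode(mask * 1, se$kernel)
  matrix(unclass(out) >= 1, nrow(mask), ncol(mask))
}

#' Invert image intensities
#'
#' Complements intensities against the representable maximum
#' (`2^bit_depth - 1`), turning dark-on-light input (e.g. brightfield images
#' of silver-stained sections) into the bright-on-dark convention the
#' pipeline expects. No illumination correction is applied.
#'
#' @param img Numeric matrix.
#' @param bit_depth 8 or 16.
#' @return Numeric matrix.
#' @export
invert_image <- function(img, bit_depth = 8) {
  check_grey(img)
  if (!bit_depth %in% c(8, 16)) stop("`bit_depth` must be 8 or 16",
                                     call. = FALSE)
  mx <- 2^bit_depth - 1
  if (any(img > mx)) stop("intensities exceed the stated bit depth",
                          call. = FALSE)
  mx - img
}
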