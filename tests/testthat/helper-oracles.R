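# Brute-force oracles, deliberately independent of the package's
# shift/graph-based implementations: explicit per-pixel loops and
# queue-based flood fill. Only used on small inputs.

oracle_neighbours8 <- function(mask, i, j) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- 0L
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- i + di; jj <- j + dj
    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj]) n <- n + 1L
  }
  n
}

oracle_endpoints <- function(skel) {
  out <- matrix(FALSE, nrow(skel), ncol(skel))
  for (i in seq_len(nrow(skel))) for (j in seq_len(ncol(skel))) {
    if (skel[i, j] && oracle_neighbours8(skel, i, j) == 1L) out[i, j] <- TRUE
  }
  out
}

# queue-based flood-fill labelling
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 8) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else {
    list(c(-1,0), c(0,-1), c(0,1), c(1,0))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (o in offs) {
          q <- p + o
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  lab
}

oracle_size_filter <- function(mask, min_area, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  if (max(lab) == 0) return(mask)
  areas <- tabulate(lab[lab > 0])
  out <- mask
  for (k in seq_along(areas)) if (areas[k] < min_area) out[lab == k] <- FALSE
  out
}

oracle_dilate <- function(mask, kern) {
  nr <- nrow(mask); nc <- ncol(mask)
  kr <- (nrow(kern) - 1) / 2; kc <- (ncol(kern) - 1) / 2
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (di in -kr:kr) for (dj in -kc:kc) {
      if (kern[di + kr + 1, dj + kc + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) out[ii, jj] <- TRUE
    }
  }
  out
}

# brute-force greyscale opening: min filter then max filter over the SE,
# with border handling matching reflection-free semantics is fiddly, so
# restrict comparisons to the interior where the SE fits entirely.
oracle_open_interior <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- (nrow(kern) - 1) / 2
  er <- matrix(NA_real_, nr, nc)
  for (i in (1 + kr):(nr - kr)) for (j in (1 + kr):(nc - kr)) {
    er[i, j] <- min(img[i + (-kr:kr), j + (-kr:kr)][kern == 1])
  }
  op <- matrix(NA_real_, nr, nc)
  for (i in (1 + 2 * kr):(nr - 2 * kr)) for (j in (1 + 2 * kr):(nc - 2 * kr)) {
    op[i, j] <- max(er[i + (-kr:kr), j + (-kr:kr)][kern == 1])
  }
  op
}

# number of holes: 4-connected background components minus the outer one
# (mask padded so the outside is a single component)
oracle_holes <- function(mask) {
  padded <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  max(oracle_label(!padded, connectivity = 4)) - 1L
}

# comb-shaped 1-px tree with known leaf/junction counts: horizontal spine,
# k interior vertical teeth at columns >= 3 apart
make_comb_skeleton <- function(seed, size = 48) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  spine_row <- sample(15:(size - 15), 1)
  c0 <- 4; c1 <- size - 4
  m[spine_row, c0:c1] <- TRUE
  k <- sample(1:5, 1)
  cols <- sort(sample(seq(c0 + 3, c1 - 3, by = 3), k))
  for (cc in cols) {
    len <- sample(4:10, 1)
    up <- sample(c(TRUE, FALSE), 1)
    rows <- if (up) (spine_row - len):(spine_row - 1) else
      (spine_row + 1):(spine_row + len)
    m[rows, cc] <- TRUE
  }
  list(skel = m, leaves = k + 2L, junctions = k)
}

# small random blob mask built from dilated random seed points
random_blob_mask <- function(seed, size = 48, n_seeds = 6) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  pts <- cbind(sample(5:(size - 5), n_seeds, replace = TRUE),
               sample(5:(size - 5), n_seeds, replace = TRUE))
  m[pts] <- TRUE
  dilate_mask(m, structuring_element(sample(2:4, 1)))
}

# blank background field rendered like the synthetic generator (blur+noise)
render_raw <- function(canvas, blur_sigma = 1, noise_sd = 4, seed = 1) {
  out <- unclass(EBImage::gblur(canvas, sigma = blur_sigma))
  dim(out) <- dim(canvas)
  set.seed(seed)
  matrix(round(pmin(pmax(out + rnorm(length(out), 0, noise_sd), 0), 255)),
         nrow(canvas), ncol(canvas))
}
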