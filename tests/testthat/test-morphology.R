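test_that("greyscale opening is anti-extensive, increasing, idempotent and matches brute force", {
  set.seed(42)
  se <- structuring_element(2)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 30 * 30, replace = TRUE), 30, 30)
    op <- grey_open(img, se)
    expect_true(all(op <= img))                        # anti-extensive
    expect_equal(grey_open(op, se), op)                # idempotent
    brighter <- img + sample(0:40, 900, replace = TRUE)
    expect_true(all(grey_open(brighter, se) >= op))    # increasing
    # brute-force erosion-then-dilation oracle on the interior
    ref <- oracle_open_interior(img, se$kernel)
    inner <- !is.na(ref)
    expect_equal(op[inner], ref[inner])
  }
  # constants are fixed points
  expect_equal(grey_open(matrix(100, 20, 20), se), matrix(100, 20, 20))
  # a 1-px bright line is erased to the background
  img <- matrix(10, 40, 40); img[20, 5:35] <- 200
  expect_true(all(grey_open(img, structuring_element(3))[20, 5:35] <= 10))
  # a wide disk survives at full value where the SE fits
  img <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40) if ((i - 20)^2 + (j - 20)^2 <= 100) img[i, j] <- 180
  op <- grey_open(img, structuring_element(3))
  expect_equal(op[20, 20], 180)
  expect_true(all(op[(row(img) - 20)^2 + (col(img) - 20)^2 <= 36] == 180))
})

test_that("opening rejects structuring elements larger than the image", {
  expect_error(grey_open(matrix(0, 10, 10), structuring_element(5)),
               "structuring element exceeds image")
})

test_that("image subtraction clamps at zero and never wraps", {
  a <- matrix(50, 5, 5)
  expect_equal(img_subtract(a, a), matrix(0, 5, 5))
  expect_equal(img_subtract(a, matrix(80, 5, 5)), matrix(0, 5, 5))
  set.seed(1)
  x <- matrix(sample(0:255, 100, TRUE), 10, 10)
  y <- matrix(sample(0:255, 100, TRUE), 10, 10)
  d <- img_subtract(x, y)
  for (i in 1:10) for (j in 1:10) {
    expect_identical(d[i, j], max(x[i, j] - y[i, j], 0))
  }
  expect_error(img_subtract(x, matrix(0, 5, 5)), "shape mismatch")
})

test_that("binarize uses strict inequality and is invariant to co-scaling", {
  img <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(binarize(img, 0), img == 1)
  expect_equal(sum(binarize(matrix(0, 4, 4), 0)), 0)
  set.seed(7)
  img <- matrix(sample(0:255, 400, TRUE), 20, 20)
  m <- binarize(img, 128)
  expect_equal(m, img > 128)           # exhaustive pixel comparison
  for (k in c(0.5, 1.5, 2)) {
    expect_identical(binarize(img * k, 128 * k), m)
  }
})

test_that("size filter removes small components including enclosed ones", {
  # a 3-px blob inside a closed ring: border-seeded particle analysis misses
  # it; component labelling must not
  m <- matrix(FALSE, 30, 30)
  m[10, 5:25] <- TRUE; m[20, 5:25] <- TRUE
  m[10:20, 5] <- TRUE; m[10:20, 25] <- TRUE       # ring, area ~ 60
  m[15, 14:16] <- TRUE                             # enclosed 3-px blob
  out <- size_filter(m, 10)
  expect_equal(sum(out[15, 14:16]), 0)
  expect_true(all(out[10, 5:25]))
  expect_equal(size_filter(matrix(FALSE, 5, 5), 3), matrix(FALSE, 5, 5))
  # random blob fields against the flood-fill oracle, both connectivities
  for (seed in 1:6) {
    mask <- random_blob_mask(seed)
    for (conn in c(4, 8)) {
      got <- size_filter(mask, 25, connectivity = conn)
      expect_identical(got, oracle_size_filter(mask, 25, conn))
      expect_identical(size_filter(got, 25, connectivity = conn), got)
    }
  }
})

test_that("component labelling agrees with flood fill and distinguishes connectivity", {
  diag2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(max(label_components(diag2, 8)), 1)
  expect_equal(max(label_components(diag2, 4)), 2)
  for (seed in 7:10) {
    mask <- random_blob_mask(seed)
    for (conn in c(4, 8)) {
      got <- label_components(mask, conn)
      ref <- oracle_label(mask, conn)
      expect_equal(max(got), max(ref))
      # same partition (labels may be permuted)
      expect_equal(length(unique(paste(got[mask], ref[mask]))), max(ref))
    }
  }
})

test_that("skeletonization yields thin, homotopy-preserving subsets", {
  # straight bar reduces to its axis
  bar <- matrix(FALSE, 20, 60); bar[9:11, 5:54] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(bar[sk]))
  expect_gte(sum(sk), 46)   # two-subiteration thinning rounds off <= 2 px/end
  expect_lte(sum(sk), 52)
  # one pixel wide: no 2x2 foreground block anywhere
  no_2x2 <- function(s) {
    blocks <- s[-nrow(s), -ncol(s)] & s[-1, -ncol(s)] &
      s[-nrow(s), -1] & s[-1, -1]
    !any(blocks)
  }
  expect_true(no_2x2(sk))
  # single pixel is preserved
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_identical(skeletonize(px), px)
  # filled disk: one component, no holes
  disk <- matrix(FALSE, 30, 30)
  disk[(row(disk) - 15)^2 + (col(disk) - 15)^2 <= 64] <- TRUE
  sk <- skeletonize(disk)
  expect_equal(max(oracle_label(sk, 8)), 1)
  expect_equal(oracle_holes(sk), 0)
  # random blobs: component and hole counts preserved, output subset, thin
  for (seed in 11:16) {
    mask <- random_blob_mask(seed)
    sk <- skeletonize(mask)
    expect_true(all(mask[sk]))
    expect_true(no_2x2(sk))
    expect_equal(max(oracle_label(sk, 8)), max(oracle_label(mask, 8)))
    expect_equal(oracle_holes(sk), oracle_holes(mask))
  }
})

test_that("skeleton terminals match shapes, neighbour-count oracle and leaf counts", {
  path <- matrix(FALSE, 10, 60); path[5, 6:55] <- TRUE
  ep <- find_endpoints(path)
  expect_equal(sum(ep), 2)
  expect_true(ep[5, 6] && ep[5, 55])
  y <- matrix(FALSE, 30, 30)                     # three arms from one junction
  y[15, 5:15] <- TRUE; y[5:14, 15] <- TRUE; y[16:25, 15] <- TRUE
  expect_equal(sum(find_endpoints(y)), 3)
  ring <- matrix(FALSE, 20, 20)
  ring[5, 5:15] <- TRUE; ring[15, 5:15] <- TRUE
  ring[5:15, 5] <- TRUE; ring[5:15, 15] <- TRUE
  expect_equal(sum(find_endpoints(ring)), 0)
  # comb trees with known graph-theoretic leaf counts
  for (seed in 1:25) {
    comb <- make_comb_skeleton(seed)
    ep <- find_endpoints(comb$skel)
    expect_identical(ep, oracle_endpoints(comb$skel))
    expect_equal(sum(ep), comb$leaves)
  }
})

test_that("dilation matches union-of-translates; erosion/dilation order correctly", {
  one <- matrix(FALSE, 11, 11); one[6, 6] <- TRUE
  se <- structuring_element(2)
  d <- dilate_mask(one, se)
  expect_equal(sum(d), sum(se$kernel))
  expect_true(d[6, 8] && d[4, 6] && !d[3, 3])
  expect_identical(dilate_mask(matrix(FALSE, 6, 6), se), matrix(FALSE, 6, 6))
  for (seed in 20:24) {
    mask <- random_blob_mask(seed, n_seeds = 4)
    expect_identical(dilate_mask(mask, se), oracle_dilate(mask, se$kernel))
    expect_true(all(dilate_mask(mask, se)[mask]))      # extensive
    op <- dilate_mask(erode_mask(mask, se), se)        # binary opening
    cl <- erode_mask(dilate_mask(mask, se), se)        # binary closing
    expect_true(all(mask[op]))                         # opening <= mask
    expect_true(all(cl[mask]))                         # mask <= closing
  }
})

test_that("intensity inversion complements against the bit-depth maximum", {
  img <- matrix(c(0, 100, 255, 30), 2, 2)
  expect_equal(invert_image(img, 8), 255 - img)
  expect_equal(invert_image(invert_image(img, 8), 8), img)
  expect_error(invert_image(img * 300, 8), "exceed")
})
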