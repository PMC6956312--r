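test_that("normalization maps the window to [0,1], clips, inverts and is idempotent", {
  arr <- array(c(-1000, 2000, 500, -2000, 3000, 40, 1000, 0, 250), dim = c(1, 3, 3))
  v <- new_volume(arr, "HU", 1)
  n <- normalize_volume(v, c(-1000, 2000))
  expect_equal(n$data[1, 1, 1], 0)
  expect_equal(n$data[1, 2, 1], 1)
  expect_equal(n$data[1, 1, 2], 0)   # clipped below
  expect_equal(n$data[1, 2, 2], 1)   # clipped above
  expect_identical(normalize_volume(n, c(-1000, 2000))$data, n$data)
  # constant mid-window volume maps to 0.5
  mid <- new_volume(array(500, dim = c(1, 4, 4)), "HU", 1)
  expect_true(all(normalize_volume(mid, c(-1000, 2000))$data == 0.5))
  # unclipped voxels invert exactly
  back <- denormalize_volume(n, c(-1000, 2000))
  unclipped <- arr >= -1000 & arr <= 2000
  expect_true(all(abs(back$data[unclipped] - arr[unclipped]) < 1e-9))
  expect_error(normalize_volume(v, c(10, 10)), "lo < hi")
})

test_that("patch grids follow the exclusive-origin convention with inclusive fallback", {
  # 512 with 64/32: 14 positions per axis under the exclusive bound
  expect_equal(patch_grid_axis_count(512, 64, 32), 14L)
  expect_equal(patch_grid_axis_count(512, 64, 32, "inclusive"), 15L)
  # 64 with 64/32: zero under the default, one at the boundary
  expect_equal(patch_grid_axis_count(64, 64, 32), 0L)
  expect_equal(patch_grid_axis_count(64, 64, 32, "inclusive"), 1L)
  expect_error(patch_grid_axis_count(32, 64, 32), "exceeds")
})

test_that("extract_patch_grid enumerates the 196-patch grid on a 512 image", {
  img <- matrix(seq_len(512 * 512), 512)
  g <- extract_patch_grid(img, 64, 32)
  expect_equal(nrow(g$origins), 196L)
  expect_length(g$patches, 196L)
  # origins are stride multiples and every patch sits fully inside
  expect_true(all(g$origins$row %% 32 == 0))
  expect_true(all(g$origins$row + 64 <= 512))
  # patch content matches a direct crop at a spot-checked origin
  i <- 37
  r <- g$origins$row[i]; c <- g$origins$col[i]
  expect_identical(g$patches[[i]], img[(r + 1):(r + 64), (c + 1):(c + 64)])
})

test_that("axis-count formula equals brute-force origin enumeration across a sweep", {
  for (n_img in c(64L, 96L, 128L, 256L, 512L))
    for (size in c(16L, 32L, 64L))
      for (stride in c(8L, 16L, 32L)) {
        if (size > n_img) next
        k <- patch_grid_axis_count(n_img, size, stride)
        expect_equal(k, as.integer(floor((n_img - size) / stride)))
        g <- extract_patch_grid(matrix(0, n_img, n_img), size, stride)
        expect_equal(nrow(g$origins), k^2)
      }
})

test_that("the corpus of 2566 slices of 512x512 yields exactly 502936 patches", {
  per_image <- patch_grid_axis_count(512, 64, 32)^2
  expect_identical(as.integer(per_image) * 2566L, 502936L)
})

test_that("3D stacks pair few and full identically with stride one in the slice axis", {
  set.seed(1)
  mkvol <- function() new_volume(array(runif(20 * 32 * 32), dim = c(20, 32, 32)),
                                 "normalized", 1)
  pair <- list(few = mkvol(), full = mkvol(), patient = 3L)
  orig <- data.frame(row = c(0L, 8L), col = c(0L, 16L))
  st <- build_3d_stacks(pair, orig, size = 16L, ns = 9L)
  expect_length(st, 2 * (20 - 9 + 1))
  expect_identical(dim(st[[1]]$few), c(9L, 16L, 16L))
  for (s in st) {
    expect_identical(dim(s$few), dim(s$full))
    pv <- s$provenance
    expect_equal(pv$patient, 3L)
    sl <- (pv$slice + 1):(pv$slice + 9)
    expect_identical(s$few, pair$few$data[sl, (pv$row + 1):(pv$row + 16),
                                          (pv$col + 1):(pv$col + 16)])
  }
  # exactly one stack per origin when S equals ns
  pair9 <- list(few = new_volume(pair$few$data[1:9, , , drop = FALSE], "normalized", 1),
                full = new_volume(pair$full$data[1:9, , , drop = FALSE], "normalized", 1))
  expect_length(build_3d_stacks(pair9, orig, size = 16L, ns = 9L), 2L)
  pair5 <- list(few = new_volume(pair$few$data[1:5, , , drop = FALSE], "normalized", 1),
                full = new_volume(pair$full$data[1:5, , , drop = FALSE], "normalized", 1))
  expect_error(build_3d_stacks(pair5, orig, size = 16L, ns = 9L), "fewer slices")
})

test_that("batch iterator shuffles reproducibly, drops short batches and covers each epoch", {
  st <- random_stacks(25, ns = 3L, N = 8L)
  it1 <- batch_iterator(st, nb = 10L, seed = 5L)
  it2 <- batch_iterator(st, nb = 10L, seed = 5L)
  b1 <- it1(); b2 <- it2()
  expect_identical(b1$few, b2$few)
  expect_identical(dim(b1$few), c(10L, 3L, 8L, 8L, 1L))
  expect_equal(b1$steps_per_epoch, 2L)
  expect_true(b1$new_epoch)
  # 2 batches per epoch; the third call starts epoch 2
  b <- it1()
  expect_false(b$new_epoch)
  b3 <- it1()
  expect_true(b3$new_epoch)
  expect_equal(b3$epoch, 2L)
  # pairing integrity: few and full of every element share provenance source
  idx <- vapply(b1$provenance, function(p) p$patient, numeric(1))
  expect_length(idx, 10L)
  expect_error(batch_iterator(st[1:5], nb = 10L), "at least")
})

test_that("two epochs of batches cover every stack at least once each epoch", {
  st <- random_stacks(20, ns = 3L, N = 8L)
  for (i in seq_along(st)) st[[i]]$provenance$slice <- i  # tag identity
  it <- batch_iterator(st, nb = 10L, seed = 2L)
  seen <- function() sort(unique(unlist(lapply(1:2, function(k)
    vapply(it()$provenance, `[[`, numeric(1), "slice")))))
  expect_equal(seen(), as.numeric(1:20))  # epoch 1
  expect_equal(seen(), as.numeric(1:20))  # epoch 2
})
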