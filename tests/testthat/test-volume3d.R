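# Rigid transforms, registration, ion volumes, dissection, composites.

smooth_test_image <- function(n = 48) {
  xg <- matrix(rep(seq_len(n), each = n), n, n)
  yg <- matrix(rep(seq_len(n), times = n), n, n)
  exp(-((xg - n / 2 - 4)^2 + (yg - n / 2)^2) / 40) +
    0.6 * exp(-((xg - n / 2 + 8)^2 + (yg - n / 2 - 6)^2) / 25)
}

# asymmetric blocks + speckle: well-conditioned for rotation estimation
sharp_test_image <- function(n = 48, seed = 3) {
  set.seed(seed)
  img <- matrix(0, n, n)
  img[15:30, 12:25] <- 1
  img[20:26, 30:38] <- 2
  img + matrix(runif(n * n, 0, 0.1), n)
}

test_that("rigid transforms compose and invert within interpolation error", {
  img <- smooth_test_image()
  t1 <- rigid_transform(5, 2, -1)
  t2 <- rigid_transform(-3, -1, 2)
  a <- apply_transform(apply_transform(img, t1), t2)
  b <- apply_transform(img, compose_transforms(t2, t1))
  interior <- 9:40
  expect_lt(sqrt(sum((a - b)[interior, interior]^2)) /
              sqrt(sum(img[interior, interior]^2)), 0.02)
  back <- apply_transform(apply_transform(img, t1), invert_transform(t1))
  expect_lt(sqrt(sum((back - img)[interior, interior]^2)) /
              sqrt(sum(img[interior, interior]^2)), 0.02)
  expect_equal(apply_transform(img, rigid_transform(0, 0, 0)), img)
  # interior mass approximately preserved
  moved <- apply_transform(img, rigid_transform(3, 1, 1))
  expect_lt(abs(sum(moved) - sum(img)) / sum(img), 0.01)
})

test_that("a known rigid misalignment is recovered to subpixel accuracy", {
  img <- sharp_test_image()
  idn <- estimate_rigid(img, img)
  expect_equal(idn$theta, 0)
  expect_lt(abs(idn$dx) + abs(idn$dy), 0.1)
  expect_gt(attr(idn, "ncc"), 0.999)
  tf <- rigid_transform(4, 3, -2)
  moved <- apply_transform(img, tf)
  est <- estimate_rigid(img, moved)
  inv <- invert_transform(tf)
  expect_lt(abs(est$theta - inv$theta), 0.5)
  expect_lt(abs(est$dx - inv$dx), 0.5)
  expect_lt(abs(est$dy - inv$dy), 0.5)
  expect_error(estimate_rigid(img, matrix(1, 48, 48)),
               class = "msi3d_input_error")
})

test_that("a pre-aligned stack registers to near-identity transforms", {
  img <- sharp_test_image()
  set.seed(33)
  imgs <- lapply(1:4, function(i) img + matrix(rnorm(48^2, 0, 0.002), 48))
  tfs <- register_stack(imgs)
  for (tf in tfs) {
    expect_lt(abs(tf$theta), 0.3)
    expect_lt(abs(tf$dx) + abs(tf$dy), 0.3)
  }
})

test_that("serial-section misalignments are recovered within 1 px and 1 degree", {
  stk <- phantom_stack()
  tfs <- register_stack(stk$study)
  errs <- vapply(seq_along(tfs), function(i) {
    expected <- compose_transforms(
      stk$truth$sections[[1]]$transform,
      invert_transform(stk$truth$sections[[i]]$transform))
    c(abs(tfs[[i]]$theta - expected$theta),
      sqrt((tfs[[i]]$dx - expected$dx)^2 + (tfs[[i]]$dy - expected$dy)^2))
  }, numeric(2))
  expect_lt(mean(errs[1, ]), 1)
  expect_lt(mean(errs[2, ]), 1)
})

test_that("volumes stack slices and conserve intensity", {
  vol <- phantom_volume()
  v <- vol$vol_margin
  expect_equal(dim(v$data)[3], length(vol$study$sections))
  slices_sum <- sum(vapply(seq_along(vol$study$sections), function(i)
    sum(pmax(apply_transform(
      ion_image(vol$study$sections[[i]], vol$study$mz, v$center, 0.0901),
      vol$transforms[[i]]), 0)), numeric(1)))
  expect_equal(sum(v$data), slices_sum, tolerance = 1e-8)
  # single-section volume has depth 1
  one <- msi_study(vol$study$sections[1])
  v1 <- build_volume(one, NULL, center = v$center, sigma = 0.0901)
  expect_equal(dim(v1$data)[3], 1L)
})

test_that("margin volume forms a shell enclosing the core volume", {
  vol <- phantom_volume()
  thM <- vol$vol_margin$data >= 0.5 * max(vol$vol_margin$data)
  thC <- vol$vol_core$data >= 0.5 * max(vol$vol_core$data)
  lab <- concomp3d(thM)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  expect_gte(max(sizes) / sum(sizes), 0.9)
  shell <- lab == main
  d <- dim(thC)
  enclosed <- vapply(which(thC), function(ci) {
    z <- (ci - 1) %/% (d[1] * d[2])
    rem <- (ci - 1) %% (d[1] * d[2])
    x <- rem %/% d[1] + 1
    y <- rem %% d[1] + 1
    sl <- shell[, , z + 1]
    any(sl[y, 1:x]) && any(sl[y, x:d[2]]) &&
      any(sl[1:y, x]) && any(sl[y:d[1], x])
  }, logical(1))
  expect_gte(mean(enclosed), 0.95)
  zC <- range(which(apply(thC, 3, any)))
  zS <- range(which(apply(shell, 3, any)))
  expect_lte(zS[1], zC[1])
  expect_gte(zS[2], zC[2])
})

test_that("virtual dissection reproduces axis-aligned content", {
  arr <- array(2, dim = c(8, 8, 4))
  vol <- structure(list(data = arr, voxel_um = c(y = 10, x = 10, z = 10),
                        center = 400, transforms = NULL),
                   class = "ion_volume")
  dis <- virtual_dissection(vol, point = c(30, 30, 10), normal = c(0, 0, 1),
                            spacing_um = 10)
  inside <- dis[dis > 0]
  expect_true(all(abs(inside - 2) < 1e-9))
  expect_gt(length(inside), 0)
  # voxel-aligned z plane reproduces the slab values
  arr2 <- array(0, dim = c(6, 6, 3)); arr2[, , 2] <- matrix(1:36, 6)
  vol2 <- structure(list(data = arr2, voxel_um = c(y = 1, x = 1, z = 1),
                         center = 1, transforms = NULL),
                    class = "ion_volume")
  dis2 <- virtual_dissection(vol2, point = c(2, 2, 1), normal = c(0, 0, 1),
                             spacing_um = 1)
  expect_true(all(sort(unique(dis2[dis2 > 0])) %in% 1:36))
  expect_equal(max(dis2), 36)
})

test_that("longitudinal dissection shows margin bands flanking a weak core", {
  vol <- phantom_volume()
  d <- dim(vol$vol_margin$data)
  vx <- vol$vol_margin$voxel_um
  pt <- c((d[2] - 1) / 2 * vx[["x"]], (d[1] - 1) / 2 * vx[["y"]],
          (d[3] - 1) / 2 * vx[["z"]])
  dis <- virtual_dissection(vol$vol_margin, pt, normal = c(0, 1, 0),
                            spacing_um = vx[["x"]])
  disC <- virtual_dissection(vol$vol_core, pt, normal = c(0, 1, 0),
                             spacing_um = vx[["x"]])
  band <- dis > 0.7 * max(dis)
  core <- disC > 0.7 * max(disC)
  expect_gt(mean(dis[band]) / mean(dis[core]), 3)
})

test_that("composite channels scale, stay separate, and mix where they overlap", {
  a <- array(0, dim = c(4, 4, 2)); a[1:2, , ] <- 5
  b <- array(0, dim = c(4, 4, 2)); b[3:4, , ] <- 3
  mkvol <- function(x) structure(
    list(data = x, voxel_um = c(y = 1, x = 1, z = 1), center = 1,
         transforms = NULL), class = "ion_volume")
  comp <- composite_channels(list(mkvol(a), mkvol(b)), c("red", "blue"))
  mip <- mip_composite(comp, "z")
  expect_equal(dim(mip), c(4L, 4L, 3L))
  # disjoint channels never mix
  expect_true(all(mip[1:2, , 3] == 0))
  expect_true(all(mip[3:4, , 1] == 0))
  # single channel renders as its own grayscale in that color
  solo <- mip_composite(composite_channels(list(mkvol(a)), "white"), "z")
  expect_equal(solo[, , 1], solo[, , 2])
  # overlap: both channels > 0.5 exactly where both masks overlap
  bo <- array(0, dim = c(4, 4, 2)); bo[2:3, , ] <- 3
  co <- composite_channels(list(mkvol(a), mkvol(bo)), c("red", "blue"))
  both <- co$channels[[1]] > 0.5 & co$channels[[2]] > 0.5
  expect_equal(both, a > 0.5 & bo > 0.5)
})

test_that("volumes export as NRRD and multi-page TIFF", {
  dir <- withr::local_tempdir()
  set.seed(35)
  arr <- array(runif(60), dim = c(5, 4, 3))
  vol <- structure(list(data = arr, voxel_um = c(y = 40, x = 40, z = 204),
                        center = 400.3, transforms = NULL),
                   class = "ion_volume")
  f <- file.path(dir, "v.nrrd")
  write_volume_nrrd(vol, f)
  lines <- readLines(f, n = 9, warn = FALSE)
  expect_equal(lines[1], "NRRD0004")
  expect_true(any(grepl("sizes: 5 4 3", lines)))
  con <- file(f, "rb")
  repeat {
    ln <- readLines(con, n = 1, warn = FALSE)
    if (!length(ln) || ln == "") break
  }
  raw <- readBin(con, "numeric", n = 60, size = 8, endian = "little")
  close(con)
  expect_equal(array(raw, dim = dim(arr)), arr)
  ftif <- file.path(dir, "v.tif")
  write_volume_tiff(vol, ftif)
  pages <- tiff::readTIFF(ftif, all = TRUE)
  expect_length(pages, 3L)
})
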