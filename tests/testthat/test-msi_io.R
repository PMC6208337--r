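# imzML round-trips, processed-mode resampling, tabular exports.

test_that("continuous imzML round-trips a small study", {
  dir <- withr::local_tempdir()
  mz <- seq(400, 410, by = 0.5)
  # float32-representable values round-trip bit-exactly
  vals <- rbind(c(rep(0.5, 10), rep(1.25, 11)),
                c(rep(2, 15), rep(0.75, 6)),
                matrix(seq(0.25, 5.25, by = 0.25), 1),
                numeric(21))
  sec <- msi_section(mz, vals, data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)),
                     segment = "L", timepoint_days = 3, z_index = 2L)
  write_imzml(sec, file.path(dir, "test"))
  back <- read_imzml(file.path(dir, "test.imzML"))
  expect_length(back, 1L)
  expect_equal(back[[1]]$mz, mz)
  expect_identical(back[[1]]$intensities, vals)
  expect_equal(back[[1]]$coords, sec$coords)
  expect_equal(back[[1]]$meta$z_index, 2L)
})

test_that("64-bit encoding round-trips arbitrary doubles exactly", {
  dir <- withr::local_tempdir()
  mz <- seq(300, 305, by = 0.1)
  set.seed(30)
  vals <- matrix(runif(2 * length(mz)), 2)
  sec <- msi_section(mz, vals, data.frame(x = 0:1, y = c(0, 0)))
  write_imzml(sec, file.path(dir, "dbl"), intensity_bytes = 8L)
  back <- read_imzml(file.path(dir, "dbl.imzML"))
  expect_identical(back[[1]]$intensities, vals)
})

test_that("multiple z sections share one file and split on read", {
  dir <- withr::local_tempdir()
  mz <- seq(400, 402, by = 1)
  mk <- function(z) msi_section(mz, matrix(z * 1.0, 1, 3),
                                data.frame(x = 0, y = 0), z_index = z)
  write_imzml(list(mk(1L), mk(2L), mk(3L)), file.path(dir, "stack"))
  back <- read_imzml(file.path(dir, "stack.imzML"))
  expect_length(back, 3L)
  expect_equal(vapply(back, function(s) s$intensities[1, 1], numeric(1)),
               c(1, 2, 3))
})

test_that("missing or malformed files raise format errors", {
  dir <- withr::local_tempdir()
  expect_error(read_imzml(file.path(dir, "nope.imzML")), "not found")
  mz <- seq(400, 402, by = 1)
  sec <- msi_section(mz, matrix(1.0, 1, 3), data.frame(x = 0, y = 0))
  write_imzml(sec, file.path(dir, "orphan"))
  file.remove(file.path(dir, "orphan.ibd"))
  expect_error(read_imzml(file.path(dir, "orphan.imzML")),
               class = "msi3d_format_error")
  writeLines("<mzML><fileDescription/></mzML>",
             file.path(dir, "bad.imzML"))
  writeBin(as.raw(1:16), file.path(dir, "bad.ibd"))
  expect_error(read_imzml(file.path(dir, "bad.imzML")),
               class = "msi3d_format_error")
})

write_processed_fixture <- function(path, mz_list, int_list) {
  p <- sub("\\.imzML$", "", path)
  con <- file(paste0(p, ".ibd"), "wb")
  writeBin(as.raw(rep(7L, 16L)), con)
  off <- 16
  meta <- list()
  for (i in seq_along(mz_list)) {
    writeBin(as.numeric(mz_list[[i]]), con, size = 8, endian = "little")
    mz_off <- off; off <- off + 8 * length(mz_list[[i]])
    writeBin(as.numeric(int_list[[i]]), con, size = 8, endian = "little")
    int_off <- off; off <- off + 8 * length(int_list[[i]])
    meta[[i]] <- c(mz_off, int_off)
  }
  close(con)
  spec <- vapply(seq_along(mz_list), function(i) sprintf(
    paste0('<spectrum index="%d"><scanList count="1"><scan>',
           '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
           '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="1"/>',
           '</scan></scanList><binaryDataArrayList count="2">',
           '<binaryDataArray><referenceableParamGroupRef ref="mzArray"/>',
           '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
           '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
           '<binary/></binaryDataArray>',
           '<binaryDataArray><referenceableParamGroupRef ref="intensityArray"/>',
           '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
           '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
           '<binary/></binaryDataArray></binaryDataArrayList></spectrum>'),
    i - 1L, i, length(mz_list[[i]]), meta[[i]][1],
    length(int_list[[i]]), meta[[i]][2]), character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?><mzML>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup></referenceableParamGroupList>',
    '<run><spectrumList>', paste0(spec, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, paste0(p, ".imzML"))
}

test_that("processed-mode spectra resample onto a common axis conserving intensity", {
  dir <- withr::local_tempdir()
  mz1 <- seq(400, 420, by = 0.05)
  mz2 <- seq(400.02, 420.02, by = 0.04)
  i1 <- 5 * exp(-(mz1 - 405)^2 / (2 * 0.5^2))
  i2 <- 3 * exp(-(mz2 - 412)^2 / (2 * 0.4^2))
  write_processed_fixture(file.path(dir, "proc.imzML"),
                          list(mz1, mz2), list(i1, i2))
  back <- read_imzml(file.path(dir, "proc.imzML"), bin_width = 0.02)
  expect_length(back, 1L)
  s <- back[[1]]
  expect_equal(nrow(s$intensities), 2L)
  tot_before <- c(trapz_num(i1, 0.05), trapz_num(i2, 0.04))
  tot_after <- c(trapz_num(s$intensities[1, ], 0.02),
                 trapz_num(s$intensities[2, ], 0.02))
  expect_lt(max(abs(tot_after - tot_before) / tot_before), 0.01)
})

test_that("feature matrix CSV export round-trips with one row per pixel", {
  dir <- withr::local_tempdir()
  fm1 <- feature_matrix(matrix(2.5, 1, 1), data.frame(section = 1, x = 0, y = 0),
                        centers = 400.3)
  f <- file.path(dir, "one.csv")
  export_feature_matrix(fm1, f)
  expect_equal(nrow(utils::read.csv(f)), 1L)
  set.seed(31)
  vals <- matrix(runif(12), 4)
  keys <- data.frame(section = c(1, 1, 2, 2), x = c(0, 1, 0, 1), y = 0)
  fm <- feature_matrix(vals, keys, centers = c(400.1, 500.2, 616.3))
  f2 <- file.path(dir, "many.csv")
  export_feature_matrix(fm, f2)
  back <- read_feature_matrix(f2)
  expect_equal(back$values, fm$values, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$centers, fm$centers, tolerance = 1e-4)
  expect_equal(nrow(back$keys), sum(c(2, 2)))
})

test_that("phantom studies written as imzML read back to study order", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(grid_size = 16, sections_per_segment = 2,
                        segments = "L", timepoints = 3,
                        mz_range = c(350, 400), mz_bin_width = 0.5, seed = 7)
  r <- generate_study(cfg, outdir = dir)
  back <- read_imzml(file.path(dir, "day3_L.imzML"))
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$intensities, r$study$sections[[i]]$intensities,
                 tolerance = 1e-6)
  }
})
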