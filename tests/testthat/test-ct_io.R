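test_that("array fixtures round-trip bit-for-bit", {
  ph <- generate_phantom(small_phantom_params(seed = 3))
  stem <- file.path(withr::local_tempdir(), "slice")
  write_slice_fixture(ph$ct, stem)
  back <- load_ct_slice(paste0(stem, ".json"))
  expect_identical(back$hu, ph$ct$hu)
  expect_equal(back$spacing_mm, ph$ct$spacing_mm)
  expect_equal(back$slice_location, ph$ct$slice_location)
  expect_equal(back$source_id, ph$ct$source_id)
})

test_that("series loading sorts by slice location with name tie-break", {
  dir <- withr::local_tempdir()
  locs <- c(30, 10, 20)
  for (i in seq_along(locs)) {
    ct <- ct_slice(matrix(0, 4, 4), c(1, 1), slice_location = locs[i],
                   source_id = paste0("s", i))
    write_slice_fixture(ct, file.path(dir, sprintf("f%d", i)))
  }
  ser <- load_ct_series(dir)
  expect_equal(vapply(ser$slices, function(s) s$slice_location, numeric(1)),
               c(10, 20, 30))
  expect_length(ser, 3L)

  ## single slice
  d1 <- withr::local_tempdir()
  write_slice_fixture(ct_slice(matrix(1, 2, 2)), file.path(d1, "only"))
  expect_length(load_ct_series(d1), 1L)

  ## mixed spacing is a consistency error
  d2 <- withr::local_tempdir()
  write_slice_fixture(ct_slice(matrix(0, 4, 4), c(1, 1), 0), file.path(d2, "a"))
  write_slice_fixture(ct_slice(matrix(0, 4, 4), c(2, 2), 1), file.path(d2, "b"))
  expect_error(load_ct_series(d2), class = "adipoquant_series_consistency")

  expect_error(load_ct_series(withr::local_tempdir()),
               class = "adipoquant_format_error")
})

test_that("measures CSV has fixed columns, empty cells for NA, and round-trips", {
  m1 <- structure(list(source_id = "a", slice_location = 0, tat_cm2 = 1.5,
                       vat_cm2 = 0.5, sat_cm2 = 1.0, vsr = 0.5,
                       vtr = 1 / 3, wc_cm = 40, tat_px = 150, vat_px = 50,
                       sat_px = 100), class = "adipose_measures")
  m2 <- m1; m2$source_id <- "b"; m2$vsr <- NA_real_; m2$vtr <- NA_real_
  path <- file.path(withr::local_tempdir(), "m.csv")
  write_measures(list(m1, m2), path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_match(lines[1], '^"source_id","slice_location","tat_cm2","vat_cm2","sat_cm2","vsr","vtr","wc_cm"$')
  expect_false(grepl("NaN|NA", lines[3]))   # undefined ratios -> empty cells
  back <- read_measures(path)
  expect_equal(back$tat_cm2, c(1.5, 1.5), tolerance = 1e-6)
  expect_equal(back$vsr, c(0.5, NA))
  expect_error(write_measures(list(), "x.csv"),
               class = "adipoquant_invalid_params")
})

test_that("EHR extract readers pivot long CSVs to per-subject layouts", {
  dir <- withr::local_tempdir()
  vp <- file.path(dir, "visits.csv")
  write.csv(data.frame(subject_id = c("s1", "s1", "s2"),
                       icd9_code = c("250.00", "272.00", "250.00"),
                       n_visits = c(3L, 1L, 0L)), vp, row.names = FALSE)
  v <- read_visits(vp)
  expect_equal(dim(v), c(2L, 2L))
  expect_equal(v["s1", "250.00"], 3L)
  expect_equal(v["s2", "272.00"], 0L)   # absent pair -> zero visits

  lp <- file.path(dir, "labs.csv")
  write.csv(data.frame(subject_id = c("s1", "s2", "s1"),
                       lab_name = c("hdl", "hdl", "trig"),
                       value = c(50, 60, 120)), lp, row.names = FALSE)
  l <- read_labs(lp)
  expect_setequal(names(l), c("subject_id", "hdl", "trig"))

  cp <- file.path(dir, "cov.csv")
  write.csv(data.frame(subject_id = "s1", age = 50, sex = "F"), cp,
            row.names = FALSE)
  expect_equal(read_covariates(cp)$sex, "F")
  write.csv(data.frame(subject_id = "s1", age = 50, sex = "female"), cp,
            row.names = FALSE)
  expect_error(read_covariates(cp), class = "adipoquant_schema_error")
  write.csv(data.frame(subject_id = "s1", age = 50), cp, row.names = FALSE)
  expect_error(read_covariates(cp), class = "adipoquant_schema_error")
})

test_that("DICOM reader applies the modality rescale and reads geometry", {
  dir <- withr::local_tempdir()
  py <- sprintf('
import numpy as np, pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

def write(path, slope, intercept, arr, loc):
    fm = FileMetaDataset()
    fm.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    fm.MediaStorageSOPInstanceUID = generate_uid()
    fm.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = Dataset()
    ds.file_meta = fm
    ds.SOPInstanceUID = fm.MediaStorageSOPInstanceUID
    ds.Modality = "CT"
    ds.Rows, ds.Columns = arr.shape
    ds.PixelSpacing = ["0.75", "0.70"]
    ds.SliceLocation = str(loc)
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleSlope = str(slope); ds.RescaleIntercept = str(intercept)
    ds.PixelData = arr.astype(np.int16).tobytes()
    ds.save_as(path, enforce_file_format=True)

a = np.arange(12, dtype=np.int16).reshape(3, 4)
a[0, 0] = 0
write("%s/a.dcm", 1.0, -1024.0, a, 5.0)
b = np.full((2, 2), -190, dtype=np.int16)
write("%s/b.dcm", 1.0, 0.0, b, 1.0)
c = pydicom.dcmread("%s/b.dcm")
del c.RescaleSlope
c.save_as("%s/c.dcm", enforce_file_format=True)
', dir, dir, dir, dir)
  res <- system2("python", c("-c", shQuote(py)), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "a.dcm")),
              info = paste(res, collapse = "\n"))

  s <- load_ct_slice(file.path(dir, "a.dcm"))
  expect_equal(dim(s$hu), c(3L, 4L))
  expect_equal(s$hu[1, 1], -1024)          # stored 0, slope 1, intercept -1024
  expect_equal(s$hu[1, 2], 1 - 1024)       # row-major pixel order
  expect_equal(s$spacing_mm, c(0.75, 0.70))
  expect_equal(s$slice_location, 5)

  s2 <- load_ct_slice(file.path(dir, "b.dcm"))
  expect_true(all(s2$hu == -190))          # identity rescale keeps stored HU

  ## missing rescale attributes are a metadata error
  expect_error(load_ct_slice(file.path(dir, "c.dcm")),
               class = "adipoquant_metadata_error")

  ## a non-DICOM file is a format error
  junk <- file.path(dir, "junk.dcm")
  writeLines("not a dicom", junk)
  expect_error(load_ct_slice(junk), class = "adipoquant_format_error")
})
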