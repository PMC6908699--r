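test_that("FASTA reading, writing and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 test protein", "MAAA"), f)
  rec <- read_fasta(f)
  expect_equal(rec$accession, "P1")
  expect_equal(rec$description, "test protein")
  expect_equal(rec$sequence, "MAAA")
  # 100-record synthetic database round-trips byte-identically
  db <- random_protein_db(100, c(50, 120), seed = 3)
  write_fasta(db, f)
  back <- read_fasta(f)
  expect_identical(back$sequence, db$sequence)
  expect_identical(back$accession, db$accession)
  # empty file: empty collection, no error
  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0L)
  # sequence before any header is malformed
  writeLines(c("MAAA", ">P1", "GG"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("CSV peak lists parse strictly and sort ascending", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("100.0,5", "200.0,3"), f)
  pl <- read_peaklist(f)
  expect_s3_class(pl, "peak_list")
  expect_equal(nrow(pl$peaks), 2L)
  # unsorted input comes back sorted; header auto-detected
  writeLines(c("mz,intensity", "200.0,3", "100.0,5"), f)
  pl <- read_peaklist(f)
  expect_equal(pl$peaks$mz, c(100, 200))
  # non-numeric row rejected with its line number
  writeLines(c("100.0,5", "oops,3"), f)
  expect_error(read_peaklist(f), "line 2")
  # round-trip
  pl <- peak_list(c(500.1, 100.2), c(1, 2), mode = "linear")
  write_peaklist(pl, f)
  expect_equal(read_peaklist(f)$peaks, pl$peaks)
})

test_that("MGF round-trip preserves peaks and precursor metadata", {
  f <- withr::local_tempfile(fileext = ".mgf")
  pl <- simulate_msms("ALQASALSAWRGVKENEK", "b", frag_sd_da = 0.01,
                      n_noise = 3, seed = 5)
  write_mgf(list(pl, pl), f)
  back <- read_mgf(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$peaks$mz, pl$peaks$mz, tolerance = 1e-4)
  expect_equal(back[[1]]$peaks$intensity, pl$peaks$intensity,
               tolerance = 1e-4)
  expect_equal(attr(back[[1]], "pepmass"), attr(pl, "pepmass"),
               tolerance = 1e-6)
  expect_equal(attr(back[[1]], "charge"), 1L)
  # malformed block
  writeLines(c("BEGIN IONS", "100 1"), f)
  expect_error(read_mgf(f), "END IONS")
  writeLines(c("BEGIN IONS", "100 xx", "END IONS"), f)
  expect_error(read_mgf(f), "line 2")
})

test_that("select_peaks applies the 10%-above-noise and top-n rules", {
  expect_equal(nrow(select_peaks(peak_list())$peaks), 0L)
  set.seed(31)
  mz <- sort(runif(60, 800, 3000))
  intensity <- runif(60, 50, 100)  # all well above 1.1 x default noise? no:
  pl <- peak_list(mz, intensity)
  # explicit low noise: all 60 pass threshold, keep the 50 most intense
  sel <- select_peaks(pl, max_n = 50, noise = 1)
  expect_equal(nrow(sel$peaks), 50L)
  expect_setequal(sel$peaks$intensity,
                  sort(intensity, decreasing = TRUE)[1:50])
  expect_true(!is.unsorted(sel$peaks$mz))
  # a peak at 1.05 x noise is excluded, one clearly above 1.1 x kept
  pl <- peak_list(c(100, 200, 300), c(105, 120, 200))
  sel <- select_peaks(pl, noise = 100)
  expect_setequal(sel$peaks$mz, c(200, 300))
  # subset + idempotence at a fixed noise level
  sel2 <- select_peaks(sel, noise = 100)
  expect_equal(sel2$peaks, sel$peaks)
  expect_true(all(sel$peaks$mz %in% pl$peaks$mz))
})

test_that("peak_list validates its invariants", {
  expect_error(peak_list(c(-1, 2), c(1, 1)), "positive")
  expect_error(peak_list(c(1, 2), c(1, -1)), "non-negative")
  expect_error(peak_list(1, c(1, 2)))
})
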