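test_that("charge-family assignment groups +1/+2/+3 ions of one protein", {
  # hand-converted m/z for a ~39163 Da component
  pl <- peak_list(c(39164.0, 19582.5, 13055.4), c(100, 60, 30),
                  mode = "linear")
  fams <- assign_charge_families(pl)
  expect_length(fams, 1L)
  expect_setequal(fams[[1]]$charge, 1:3)
  expect_true(all(abs(fams[[1]]$mass_estimate - 39163) < 40))
  # single peak: singleton family at charge 1
  fams <- assign_charge_families(peak_list(10001, 5, mode = "linear"))
  expect_length(fams, 1L)
  expect_equal(fams[[1]]$charge, 1L)
  # two neutral masses 5% apart never merge
  pl <- peak_list(c(40001.007276, 42001.007276), c(10, 9), mode = "linear")
  expect_length(assign_charge_families(pl), 2L)
  # empty input
  expect_length(assign_charge_families(peak_list(mode = "linear")), 0L)
})

test_that("every input peak lands in exactly one family", {
  set.seed(41)
  for (i in 1:10) {
    comp <- data.frame(mass = runif(8, 10000, 60000), abundance = runif(8))
    pl <- simulate_linear_profile(comp, rel_mass_sd = 0.001, seed = i)
    fams <- assign_charge_families(pl)
    expect_equal(sum(vapply(fams, nrow, 0L)), nrow(pl$peaks))
    all_mz <- sort(unlist(lapply(fams, function(f) f$mz)))
    expect_equal(all_mz, pl$peaks$mz)
  }
})

test_that("component_mass averages charge-state estimates", {
  fam <- assign_charge_families(
    peak_list(10001.007276, 5, mode = "linear"))[[1]]
  cm <- component_mass(fam)
  expect_equal(cm$mass, 10000, tolerance = 1e-6)
  expect_equal(cm$sd, 0)
  # frozen mean/sd for three estimates
  fam <- data.frame(mz = 1, intensity = 1, charge = 1:3,
                    mass_estimate = c(39162.9, 39163.0, 39163.2))
  cm <- component_mass(fam)
  expect_equal(cm$mass, 39163.03, tolerance = 1e-2)
  expect_equal(cm$sd, 0.15275, tolerance = 1e-4)  # hand sample SD
  expect_equal(cm$n_charges, 3L)
  expect_error(component_mass(NULL), "empty")
})

test_that("recovered component mean is CLT-consistent with truth", {
  # single component, 0.2% per-charge jitter: the mean of the three
  # estimates should sit within 3 sigma/sqrt(3) of truth ~99.7% of the time
  M <- 39163
  sigma <- 0.002 * M
  ok <- 0
  for (s in 1:200) {
    pl <- simulate_linear_profile(data.frame(mass = M, abundance = 1),
                                  rel_mass_sd = 0.002, seed = s)
    dec <- deconvolve_profile(pl, rel_tol = 0.006)
    main <- dec[which.min(abs(dec$mass - M)), ]
    n <- main$n_charges
    ok <- ok + (abs(main$mass - M) <= 3 * sigma / sqrt(n))
  }
  expect_gte(ok / 200, 0.95)
})

test_that("align_profiles pairs by relative mass and stays symmetric", {
  a <- deconvolve_profile(
    simulate_linear_profile(table1_components("hypoxia"),
                            rel_mass_sd = 0, seed = 1))
  cmp <- align_profiles(a, a)
  expect_equal(nrow(cmp$shared), nrow(a))
  expect_equal(nrow(cmp$unique_a) + nrow(cmp$unique_b), 0L)
  # the two published aldolase signals are 1.3% apart: never paired
  ca <- structure(data.frame(mass = 39163, sd = 153, n_charges = 3,
                             label = "hyp"),
                  class = c("deconvolved_components", "data.frame"))
  cb <- structure(data.frame(mass = 39668, sd = 83, n_charges = 3,
                             label = "nor"),
                  class = c("deconvolved_components", "data.frame"))
  cmp <- align_profiles(ca, cb)
  expect_equal(nrow(cmp$shared), 0L)
  expect_equal(cmp$unique_a$mass, 39163)
  expect_equal(cmp$unique_b$mass, 39668)
  # 0.03% apart: shared
  cb2 <- ca; cb2$mass <- 39175
  expect_equal(nrow(align_profiles(ca, cb2)$shared), 1L)
  # symmetry
  swapped <- align_profiles(cb, ca)
  expect_equal(swapped$unique_a$mass, cmp$unique_b$mass)
  expect_equal(swapped$unique_b$mass, cmp$unique_a$mass)
})

test_that("differential_report partitions and rounds to the Table dialect", {
  expect_equal(nrow(differential_report(
    align_profiles(merge_components(list()), merge_components(list())))), 0L)
  ca <- structure(data.frame(mass = c(39163.4, 44164.2),
                             sd = c(152.8, 45.1), n_charges = 3L,
                             label = "A"),
                  class = c("deconvolved_components", "data.frame"))
  cb <- structure(data.frame(mass = c(39668.1, 44166.0),
                             sd = c(83.4, 44.0), n_charges = 3L,
                             label = "B"),
                  class = c("deconvolved_components", "data.frame"))
  cmp <- align_profiles(ca, cb)
  rep <- differential_report(cmp)
  expect_equal(nrow(rep),
               nrow(cmp$shared) + nrow(cmp$unique_a) + nrow(cmp$unique_b))
  expect_setequal(rep$status[!is.na(rep$mass_a) & is.na(rep$mass_b)],
                  "A-only")
  expect_true(all(rep$mass_a[rep$status == "A-only"] == 39163))
  expect_true(all(rep$mass_b[rep$status == "B-only"] == 39668))
  # integer-Da rounding
  expect_true(all(rep$mass_a[!is.na(rep$mass_a)] %% 1 == 0))
  # TSV writing
  f <- withr::local_tempfile(fileext = ".tsv")
  differential_report(cmp, path = f)
  expect_equal(nrow(utils::read.delim(f)), nrow(rep))
})
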