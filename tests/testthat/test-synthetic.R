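test_that("generators are pure functions of (parameters, seed)", {
  expect_identical(random_protein_db(10, seed = 9),
                   random_protein_db(10, seed = 9))
  expect_false(identical(random_protein_db(10, seed = 9)$sequence,
                         random_protein_db(10, seed = 10)$sequence))
  p1 <- simulate_msms("GASTKLLR", seed = 4)
  p2 <- simulate_msms("GASTKLLR", seed = 4)
  expect_identical(p1$peaks, p2$peaks)
  expect_identical(simulate_pmf("GAKSTWRLLK", seed = 2)$masses,
                   simulate_pmf("GAKSTWRLLK", seed = 2)$masses)
  # the generator leaves the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(random_protein_db(5, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("random_protein_db respects size and composition contracts", {
  expect_equal(nrow(random_protein_db(0, seed = 1)), 0L)
  db <- random_protein_db(100, c(200, 500), seed = 8)
  lens <- nchar(db$sequence)
  expect_true(all(lens >= 200 & lens <= 500))
  expect_false(any(grepl("[^GASPVTCLINDQKEMHFRYW]", db$sequence)))
})

test_that("mutate_isoform plants recoverable substitutions", {
  parent <- random_protein_db(1, c(364, 364), seed = 71)$sequence
  expect_identical(mutate_isoform(parent, 0, seed = 1)$sequence, parent)
  expect_error(mutate_isoform("GAK", 10, seed = 1), "eligible")
  ids <- vapply(1:10, function(s) {
    iso <- mutate_isoform(parent, 95, seed = s)
    expect_equal(nrow(iso$substitutions), 95L)
    got <- substitutions(parent, iso$sequence)
    expect_equal(got$position, iso$substitutions$position)
    expect_identical(got$b, iso$substitutions$b)
    global_identity(parent, iso$sequence)
  }, 0)
  # gap-free pair: identity = (364 - 95) / 364 = 73.9%
  expect_true(all(abs(ids - 73.9) < 2))
})

test_that("simulate_pmf respects jitter, dropout and contaminants", {
  prot <- random_protein_db(1, c(150, 200), seed = 72)
  clean <- simulate_pmf(prot, ppm_sd = 0, dropout = 0, n_contaminants = 0,
                        seed = 1)
  expect_setequal(clean$masses, clean$truth$true_masses)
  jit <- simulate_pmf(prot, ppm_sd = 3, dropout = 0, n_contaminants = 0,
                      seed = 1)
  ppm <- (sort(jit$masses) - sort(jit$truth$true_masses)) /
    sort(jit$truth$true_masses) * 1e6
  expect_true(all(abs(ppm) < 15))   # ~5 sigma
  withc <- simulate_pmf(prot, ppm_sd = 0, dropout = 0.3, n_contaminants = 5,
                        seed = 1)
  expect_equal(length(withc$masses), withc$truth$n_real + 5)
})

test_that("simulate_msms emits the advertised series", {
  pl <- simulate_msms("ALQASALSAWRGVKENEK", "b", frag_sd_da = 0,
                      n_noise = 0, seed = 1)
  expect_equal(pl$peaks$mz, sort(b_series("ALQASALSAWRGVKENEK")$mz),
               tolerance = 1e-9)
  expect_equal(attr(pl, "truth")$n_signal, 17L)
  pl <- simulate_msms("AGKL", "both", frag_sd_da = 0, n_noise = 4, seed = 1)
  expect_equal(nrow(pl$peaks), 2 * 3 + 4)
})

test_that("simulate_linear_profile emits one peak per component x charge", {
  comp <- data.frame(mass = 20000, abundance = 2)
  pl <- simulate_linear_profile(comp, rel_mass_sd = 0, seed = 1)
  expect_equal(pl$peaks$mz,
               sort(mz_from_mass(20000, 3:1)), tolerance = 1e-9)
  expect_equal(max(pl$peaks$intensity), 2)   # z=1 carries weight 1
  pl <- simulate_linear_profile(comp, charge_weights = c(`1` = 1),
                                rel_mass_sd = 0, seed = 1)
  expect_equal(nrow(pl$peaks), 1L)
})

test_that("reference component table encodes the two condition presets", {
  hyp <- table1_components("hypoxia")
  nor <- table1_components("normoxia")
  expect_true(39163 %in% hyp$mass && !39668 %in% hyp$mass)
  expect_true(39668 %in% nor$mass && !39163 %in% nor$mass)
  expect_equal(nrow(hyp), 12L)
  expect_equal(nrow(table1_components("all")), 13L)
})

test_that("ground-truth sidecars round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_ground_truth(list(seed = 7L, masses = c(39163.2, 44164),
                          accession = "SYN0001"), f)
  back <- read_ground_truth(f)
  expect_equal(as.integer(back$seed), 7L)
  expect_equal(as.numeric(back$masses), c(39163.2, 44164))
  expect_equal(back$accession, "SYN0001")
})
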