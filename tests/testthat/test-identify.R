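test_that("pmf_search: self-match, tolerance window and determinism", {
  db <- random_protein_db(5, c(80, 150), seed = 51)
  spans <- digest_trypsin(db$sequence[3], 2, db$accession[3])
  q <- sort(unique(span_mh(spans)))
  res <- pmf_search(q, db, mods = list())
  expect_equal(res$accession[1], db$accession[3])
  expect_equal(res$matched_count[1], length(q))
  expect_equal(res$total_query_masses[1], length(q))
  # +50 ppm offset throws every query outside the 10 ppm window
  res_off <- pmf_search(q * (1 + 50e-6), db, mods = list())
  expect_equal(res_off$matched_count[res_off$accession == db$accession[3]],
               0L)
  # empty query: empty ranking
  expect_equal(nrow(pmf_search(numeric(0), db)), 0L)
  # deterministic total order on repeated runs
  res2 <- pmf_search(q, db, mods = list())
  expect_identical(res$accession, res2$accession)
  expect_false(any(duplicated(res$accession)))
})

test_that("pmf_search sees phospho-shifted masses when expansion is on", {
  db <- protein_records("P1", "AAASTKGGGLK")
  spans <- expand_variable_mods(digest_trypsin(db$sequence, 0, "P1"))
  q <- span_mh(spans[spans$n_mods == 1, ])[1]
  expect_equal(pmf_search(q, db)$matched_count, 1L)
  expect_equal(pmf_search(q, db, mods = list())$matched_count, 0L)
})

test_that("msms_match ranks the generating peptide first", {
  pep <- "ALQASALSAWRGVKENEK"
  pl <- simulate_msms(pep, "b", frag_sd_da = 0, n_noise = 0, seed = 1)
  set.seed(52)
  shuffles <- vapply(1:20, function(i)
    paste(sample(strsplit(pep, "")[[1]]), collapse = ""), "")
  cand <- peptide_spans(c(pep, shuffles))
  ranked <- msms_match(pl, cand, precursor_mz = attr(pl, "pepmass"))
  expect_equal(ranked$sequence[1], pep)
  expect_equal(ranked$b_matched[1], 17L)
  expect_equal(ranked$score[1], 17 / 34)  # all b, no y emitted
  # noiseless both-series spectrum scores 1.0
  pl2 <- simulate_msms(pep, "both", frag_sd_da = 0, n_noise = 0, seed = 1)
  r2 <- msms_match(pl2, cand, precursor_mz = attr(pl2, "pepmass"))
  expect_equal(r2$score[1], 1)
  # empty peak list: all scores zero
  r3 <- msms_match(peak_list(), cand, precursor_mz = attr(pl, "pepmass"))
  expect_true(all(r3$score == 0))
  # nothing within precursor tolerance: empty ranking
  r4 <- msms_match(pl, cand, precursor_mz = attr(pl, "pepmass") * 1.01)
  expect_equal(nrow(r4), 0L)
})

test_that("fragment-peak assignment is one-to-one", {
  # one dense peak cannot satisfy several theoretical ions
  cand <- peptide_spans("AGGK")
  theo <- fragment_ions("AGGK")
  pl <- peak_list(theo$mz[1], 100)
  r <- msms_match(pl, cand,
                  precursor_mz = peptide_neutral_mass("AGGK") + 1.007276,
                  frag_tol_da = 200)  # absurd tolerance: every ion is near
  expect_equal(r$b_matched + r$y_matched, 1L)
})

test_that("substitutions and identity behave on anchors", {
  expect_equal(nrow(substitutions("ACDE", "ACDE")), 0L)
  s <- substitutions("ACDE", "ACDF")
  expect_equal(s$position, 4L)
  expect_equal(s$a, "E"); expect_equal(s$b, "F")
  expect_equal(global_identity("ACDE", "ACDE"), 100)
  expect_equal(global_identity("ACDE", "ACDF"), 75)
})

test_that("coverage matches the bitmap oracle", {
  expect_equal(coverage(peptide_spans(character(0)), 10), 0)
  sp <- data.frame(start = c(1, 5), end = c(10, 14))
  expect_equal(coverage(sp, 20), 70)
  expect_error(coverage(data.frame(start = 0, end = 5), 10), "bounds")
  expect_error(coverage(data.frame(start = 2, end = 30), 10), "bounds")
  set.seed(53)
  for (i in 1:50) {
    len <- sample(30:400, 1)
    n <- sample(1:12, 1)
    st <- sample(len, n, replace = TRUE)
    en <- pmin(st + sample(0:30, n, replace = TRUE), len)
    expect_equal(coverage(data.frame(start = st, end = en), len),
                 oracle_coverage(st, en, len))
  }
})

test_that("discriminating peptides overlap planted substitutions", {
  parent <- random_protein_db(1, c(200, 260), seed = 54)$sequence
  expect_equal(
    nrow(discriminating_peptides(parent, parent)$discriminating_a), 0L)
  for (s in 1:5) {
    iso <- mutate_isoform(parent, 25, seed = s)
    rep <- discriminating_peptides(
      protein_records("PARENT", parent),
      protein_records("ISO", iso$sequence))
    expect_gt(nrow(rep$discriminating_a), 0L)
    expect_true(all(rep$discriminating_a$n_substitutions_spanned >= 1))
    expect_true(all(rep$discriminating_b$n_substitutions_spanned >= 1))
    # the alignment recovers exactly the planted substitution set
    expect_equal(rep$substitutions$position, iso$substitutions$position)
    expect_equal(rep$substitutions$b, iso$substitutions$b)
  }
})
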