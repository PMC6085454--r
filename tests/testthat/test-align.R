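# Global alignment conventions, active-site mapping and reciprocal best hits.

unit_scoring <- list(substitutionMatrix = NULL, match = 1, mismatch = -1,
                     gapOpening = 0, gapExtension = 1)

test_that("identical sequences give 100% identity and full coverage", {
  al <- pairwise_align("MKWVTFISLLFLFSSAYS", "MKWVTFISLLFLFSSAYS")
  expect_equal(al$identity, 100)
  expect_equal(al$coverage_a, 100)
  expect_equal(al$coverage_b, 100)
})

test_that("an internal gap yields 2/3 identity under unit costs", {
  al <- pairwise_align("ACD", "AD", scoring = unit_scoring)
  expect_equal(al$identity, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(al$columns, 3)
  expect_equal(al$matches, 2)
})

test_that("alignment score is symmetric under argument swap", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:5) {
    a <- paste(sample(aa, 30, TRUE), collapse = "")
    b <- paste(sample(aa, 25, TRUE), collapse = "")
    expect_equal(pairwise_align(a, b)$score,
                 pairwise_align(b, a)$score, tolerance = 1e-9)
    # identity is symmetric too when the optimum is essentially unique
    # (closely related pair)
    a2 <- sub("A", "G", a)
    expect_equal(pairwise_align(a, a2)$identity,
                 pairwise_align(a2, a)$identity, tolerance = 1e-9)
  }
  expect_error(pairwise_align("", "AC"), "non-empty")
})

test_that("active-site conservation reports residues, mismatches and deletions", {
  # query identical to reference: conserved
  r <- check_active_site("AACAA", "AACAA", 3, "C")
  expect_true(r$conserved)
  expect_equal(r$query_residue, "C")

  # substitution at the site
  r2 <- check_active_site("AAGAA", "AACAA", 3, "C", scoring = unit_scoring)
  expect_false(r2$conserved)
  expect_equal(r2$query_residue, "G")

  # deletion opposite the site: construct query lacking the middle residue
  r3 <- check_active_site("AAAA", "AACAA", 3, "C", scoring = unit_scoring)
  expect_equal(r3$query_residue, "-")
  expect_false(r3$conserved)

  expect_error(check_active_site("AA", "AA", 5, "C"), "outside")
})

test_that("low-identity alignments are flagged unreliable", {
  expect_warning(
    r <- check_active_site("WWWWWWWWWWFFFFFFFF", "MKLVNQERTAGSHYPDCI", 5, "N"),
    "unreliable")
  expect_false(attr(r, "reliable"))
})

test_that("identical proteomes pair fully; disjoint ones are all unique", {
  set.seed(17)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prots <- setNames(vapply(1:6, function(i)
    paste(sample(aa, 80, TRUE), collapse = ""), character(1)),
    paste0("p", 1:6))
  same <- reciprocal_unique(prots, prots)
  expect_equal(nrow(same$pairs), 6)
  expect_length(same$unique_to_a, 0)
  expect_length(same$unique_to_b, 0)

  other <- setNames(vapply(1:4, function(i)
    paste(sample(aa, 80, TRUE), collapse = ""), character(1)),
    paste0("q", 1:4))
  disj <- reciprocal_unique(prots, other)
  expect_equal(nrow(disj$pairs), 0)
  expect_setequal(disj$unique_to_a, names(prots))
  expect_setequal(disj$unique_to_b, names(other))
})

test_that("the strain pair comparison isolates exactly the planted cytochrome", {
  pair <- generate_strain_pair(strain_pair_spec(seed = 5, n_background = 12))
  comp <- reciprocal_unique(pair$strain_a$proteome, pair$strain_b$proteome)
  expect_length(comp$unique_to_a, 0)
  expect_equal(comp$unique_to_b, pair$truth$unique_b)
  expect_true(all(comp$pairs$identity >= 97))
})
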