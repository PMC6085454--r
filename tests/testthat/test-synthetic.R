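# Synthetic-data generators: determinism, ledger conservation and
# generator/analyzer closure.

test_that("culture scenarios validate their fields", {
  expect_error(culture_scenario("ferrihydrite_CO_lactate",
                                partition_phase1 = 1.2), "partitions")
  expect_error(culture_scenario("ferrihydrite_CO_lactate", co0 = -1),
               "non-negative")
  expect_error(culture_scenario("unknown_mode"))
})

test_that("noise-free trajectories satisfy the electron ledger at every step", {
  for (scen in c("ferrihydrite_CO_lactate", "glauconite_CO_lactate",
                 "lowEh_CO_only")) {
    ts <- simulate_culture(scen)
    co_ox <- ts$CO_mmol[1] - ts$CO_mmol
    lhs <- 4 * (ts$acetate_mM - ts$acetate_mM[1]) + 2 * co_ox
    rhs <- (ts$Fe2_mM - ts$Fe2_mM[1]) + 2 * (ts$H2_mmol - ts$H2_mmol[1])
    expect_equal(lhs, rhs, tolerance = 1e-8)
    # pools never negative
    expect_true(all(ts$CO_mmol >= -1e-12))
    expect_true(all(ts$lactate_mM >= -1e-12))
  }
})

test_that("the ferrihydrite preset reproduces the reported metabolite totals", {
  ts <- simulate_culture("ferrihydrite_CO_lactate")
  sc <- culture_scenario("ferrihydrite_CO_lactate")
  n <- nrow(ts)
  consumed <- sc$lactate0 - ts$lactate_mM[n]
  expect_equal(consumed, 2.3, tolerance = 0.1)          # ~2.3 mM consumed
  expect_equal(ts$acetate_mM[n], 1.1, tolerance = 0.1)  # ~1.1 mM acetate
  # first phase converts ~77% of consumed lactate to acetate
  sw <- attr(ts, "truth")$switch_time
  i <- which.min(abs(ts$time_h - sw))
  expect_equal(ts$acetate_mM[i] / (sc$lactate0 - ts$lactate_mM[i]), 0.77,
               tolerance = 0.03)
})

test_that("the glauconite preset stops at CO exhaustion with no acetate", {
  ts <- simulate_culture("glauconite_CO_lactate")
  n <- nrow(ts)
  expect_true(all(ts$acetate_mM == 0))
  expect_equal(ts$Fe2_mM[n], 1.42, tolerance = 0.05)
  expect_lt(ts$CO_mmol[n], 0.05)
  expect_equal(ts$Eh_mV[n], -520, tolerance = 5)
  # iron reduction ceases once CO is effectively gone
  i_co0 <- which(ts$CO_mmol < 0.02)[1]
  expect_lt(ts$Fe2_mM[n] - ts$Fe2_mM[i_co0], 0.005)
})

test_that("identical seeds give identical noisy trajectories", {
  a <- simulate_culture("ferrihydrite_CO_lactate", noise_sd = 0.02, seed = 9)
  b <- simulate_culture("ferrihydrite_CO_lactate", noise_sd = 0.02, seed = 9)
  c_ <- simulate_culture("ferrihydrite_CO_lactate", noise_sd = 0.02, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$Fe2_mM, c_$Fe2_mM))
})

test_that("strain pairs are deterministic under seed", {
  p1 <- generate_strain_pair(strain_pair_spec(seed = 4, n_background = 8))
  p2 <- generate_strain_pair(strain_pair_spec(seed = 4, n_background = 8))
  expect_identical(p1$strain_a$genome, p2$strain_a$genome)
  expect_identical(p1$strain_b$proteome, p2$strain_b$proteome)
})

test_that("planted features are recoverable with screening defaults", {
  pair <- generate_strain_pair(strain_pair_spec(seed = 2))
  tr <- pair$truth

  # CooA boxes: the two planted sites are found at their planted positions
  hits <- scan_iupac(pair$strain_a$genome, tr$consensus, contig = "chrA")
  expect_true(all(tr$sites_a %in% hits$start))

  # operon structure: cooA alone, cooSC pair, ten-gene CODH-ECH operon
  ops <- infer_operons(pair$strain_a$features)
  coo_ids <- tr$coo_genes_a
  sizes <- vapply(tr$coo_operons, length, integer(1))
  found <- vapply(ops$genes, function(g) {
    ids <- strsplit(g, ",")[[1]]
    if (!any(ids %in% coo_ids)) return(NA_integer_)
    length(ids)
  }, integer(1))
  expect_setequal(found[!is.na(found)], sizes)

  # heme census: 30 shared multihemes in A, 31 in B, max 17 in B only
  cenA <- find_multihemes(pair$strain_a$proteome)
  cenB <- find_multihemes(pair$strain_b$proteome)
  expect_equal(nrow(cenA), 30)
  expect_equal(nrow(cenB), 31)
  expect_equal(max(cenB$hemes), 17)
  expect_lt(max(cenA$hemes), 17)
  expect_setequal(cenA$id, names(tr$multiheme_a))
  # census counts equal the planted heme numbers
  expect_equal(cenA$hemes[match(names(tr$multiheme_a), cenA$id)],
               unname(tr$multiheme_a))
})

test_that("disabling the exclusive cytochrome removes all uniques", {
  pair <- generate_strain_pair(strain_pair_spec(seed = 6, n_background = 8,
                                                unique_multiheme_hemes = 0))
  expect_length(pair$truth$unique_b, 0)
  comp <- reciprocal_unique(pair$strain_a$proteome, pair$strain_b$proteome)
  expect_length(comp$unique_to_a, 0)
  expect_length(comp$unique_to_b, 0)
})

test_that("strain pairs round trip through FASTA/TSV files", {
  pair <- generate_strain_pair(strain_pair_spec(seed = 8, n_background = 6))
  dir <- withr::local_tempdir()
  write_strain_pair(pair, dir)
  g <- read_genome_fasta(file.path(dir, "strain_a_genome.fasta"))
  expect_equal(unname(g), pair$strain_a$genome)
  f <- read_features(file.path(dir, "strain_a_features.tsv"))
  expect_equal(f$id, pair$strain_a$features$id)
  expect_equal(f$start, pair$strain_a$features$start)
  p <- read_proteome_fasta(file.path(dir, "strain_a_proteome.fasta"))
  expect_equal(p, pair$strain_a$proteome)
})

test_that("GFF3 export reads back with identical coordinates", {
  pair <- generate_strain_pair(strain_pair_spec(seed = 8, n_background = 6))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_features(pair$strain_a$features, path, format = "gff3")
  back <- read_features(path)
  expect_equal(back$id, pair$strain_a$features$id)
  expect_equal(back$end, pair$strain_a$features$end)
  expect_equal(back$strand, pair$strain_a$features$strand)
})
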