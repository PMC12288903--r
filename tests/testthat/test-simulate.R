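test_that("the simulator is deterministic given a seed", {
  a <- simulateCohort(simConfig(seed = 5, nDyads = 3, phagesPerDyad = 2))
  b <- simulateCohort(simConfig(seed = 5, nDyads = 3, phagesPerDyad = 2))
  expect_identical(a$hits, b$hits)
  expect_identical(a$manifest, b$manifest)
  expect_identical(as.data.frame(a$db), as.data.frame(b$db))
  c <- simulateCohort(simConfig(seed = 6, nDyads = 3, phagesPerDyad = 2))
  expect_false(identical(a$hits, c$hits))
})

test_that("simulated artifacts respect their declared bounds", {
  sim <- simulateCohort(simConfig(seed = 11, nDyads = 4,
                                  contaminantPhages = 2, noisePhages = 4,
                                  multimapFraction = 0.3))
  h <- sim$hits
  glen <- genomeLengths(sim$db)
  key <- paste(h$database, h$phage_id, sep = "::")
  expect_true(all(h$subject_start >= 1))
  expect_true(all(h$subject_end <= glen[key]))
  expect_true(all(h$fragment_length >= 50 & h$fragment_length <= 200))
  expect_true(all(h$align_length <= 75))
  planted <- h[!grepl("_J", h$read_id), ]
  expect_true(all(planted$evalue < 5e-4))
  junk <- h[grepl("_J", h$read_id), ]
  expect_true(all(junk$evalue >= 5e-4))
  # planted start sites are distinct per (sample, phage); trap phages are
  # exempt (their secondary hits land wherever)
  direct <- planted[!planted$phage_id %in% sim$trapPhages, ]
  spl <- split(direct$subject_start,
               paste(direct$sample_id, direct$database, direct$phage_id))
  expect_true(all(vapply(spl, anyDuplicated, 1L) == 0L))
})

test_that("full sharing yields all-shared dyad decompositions", {
  sim <- simulateCohort(simConfig(seed = 21, nDyads = 5, sharedFraction = 1,
                                  phagesPerDyad = 3))
  res <- runPipeline(sim$hits, sim$db, sim$sheet)
  ov <- res$overlap
  expect_true(all(ov$n_maternal_only == 0))
  expect_true(all(ov$n_fetal_only == 0))
  expect_true(all(ov$n_shared >= 3))
})

test_that("planted contaminants are exactly the prevalent phages", {
  sim <- simulateCohort(simConfig(seed = 31, nDyads = 10,
                                  contaminantPhages = 7))
  res <- runPipeline(sim$hits, sim$db, sim$sheet)
  prev <- phageKeys(res$calls)[
    SummarizedExperiment::rowData(res$calls)$prevalent]
  man <- sim$manifest
  contam <- unique(paste(man$database, man$phage_id,
                         sep = "::")[man$kind == "contaminant"])
  expect_setequal(prev, contam)
  expect_equal(length(prev), 7L)
})

test_that("pipeline output matches the truth manifest on noise-free cohorts", {
  sim <- simulateCohort(simConfig(seed = 41, nDyads = 6, noisePhages = 5,
                                  multimapFraction = 0.25))
  res <- runPipeline(sim$hits, sim$db, sim$sheet)
  cdf <- as.data.frame(res$calls)
  man <- sim$manifest
  mkey <- paste(man$sample_id, man$database, man$phage_id)
  ckey <- paste(cdf$sample_id, cdf$database, cdf$phage_id)
  expect_setequal(mkey, ckey)
  i <- match(mkey, ckey)
  expect_equal(cdf$called[i], man$expect_called)
  expect_equal(cdf$n_unique_reads[i], man$planted_unique_reads)
  expect_equal(cdf$coverage_bp[i], man$planted_coverage_bp)
  # below-threshold noise phages are never called
  noisy <- man$kind %in% c("noise_reads", "noise_coverage")
  expect_false(any(cdf$called[i][noisy]))
  # the multimapping trap phages receive no assignment at all
  expect_false(any(res$assignments$phage_id %in% sim$trapPhages))
})

test_that("planted two-sample phages drive the enrichment analysis", {
  base <- simulateCohort(simConfig(seed = 51, nDyads = 10,
                                   phagesPerDyad = 0))
  sim <- plantTwoSamplePhages(base, nPairs = 10, nDyadPairs = 3)
  res <- runPipeline(sim$hits, sim$db, sim$sheet)
  enr <- res$enrichment
  expect_equal(enr$n, 10L)
  expect_equal(enr$observed, 3L)
  expect_equal(enr$N, 20L)
  expect_equal(enr$D, 10L)
  expect_equal(round(enr$expected, 2), 0.53)
  # zero planted dyad pairs -> zero observed
  sim0 <- plantTwoSamplePhages(base, nPairs = 4, nDyadPairs = 0)
  expect_equal(runPipeline(sim0$hits, sim0$db,
                           sim0$sheet)$enrichment$observed, 0L)
  expect_error(plantTwoSamplePhages(base, 3, 4), "nDyadPairs")
})

test_that("a written cohort round-trips through the readers", {
  sim <- simulateCohort(simConfig(seed = 61, nDyads = 2, phagesPerDyad = 2,
                                  nDatabases = 2, phagesPerDb = 4))
  dir <- withr::local_tempdir()
  writeCohort(sim, dir)
  back <- readCohort(dir)
  expect_equal(sort(sampleIds(back$sheet)), sort(sampleIds(sim$sheet)))
  expect_equal(sort(genomeLengths(back$db)), sort(genomeLengths(sim$db)))
  expect_equal(nrow(back$hits), nrow(sim$hits))
  # the analysis gives identical calls from disk and from memory
  resMem <- runPipeline(sim$hits, sim$db, sim$sheet)
  resDisk <- runPipeline(back$hits, back$db, back$sheet)
  expect_equal(as.data.frame(resDisk$calls), as.data.frame(resMem$calls))
})

test_that("infeasible configurations are rejected up front", {
  expect_error(simConfig(readsPerTruePhage = c(40, 80),
                         genomeLengthRange = c(1000, 2000)), "infeasible")
  expect_error(simConfig(readLength = 300), "fragment")
  expect_error(simConfig(nDatabases = 1, phagesPerDb = 3, phagesPerDyad = 6),
               "infeasible")
})
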