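# A call set built directly from per-sample phage membership lists.
callSetFromSets <- function(sets, allSamples = names(sets)) {
  phages <- sort(unique(unlist(sets)))
  if (!length(phages)) phages <- character(0)
  db <- PhageDb(phages, rep(10000L, length(phages)), "DB")
  h <- do.call(rbind, lapply(allSamples, function(s) {
    ph <- sets[[s]]
    if (is.null(ph) || !length(ph)) return(NULL)
    do.call(rbind, lapply(ph, function(p)
      fixtureCallHits(10, 500, phage = p, sample = s)))
  }))
  if (is.null(h)) h <- makeHits(integer(0), integer(0))
  callPhages(h, db, samples = allSamples)
}

pairSheet <- function(nDyads, cohort = "C") {
  SampleSheet(c(sprintf("M%02d", 1:nDyads), sprintf("F%02d", 1:nDyads)),
              cohort, rep(c("maternal", "fetal"), each = nDyads),
              rep(sprintf("D%02d", 1:nDyads), 2))
}

test_that("dyad overlap decomposes called sets", {
  sheet <- pairSheet(3)
  calls <- callSetFromSets(
    list(M01 = c("A", "B"), F01 = c("B", "C"),
         M02 = character(0), F02 = "A",
         M03 = c("A", "B", "C"), F03 = c("A", "B", "C")),
    allSamples = sampleIds(sheet))
  ov <- dyadOverlap(calls, sheet)
  expect_equal(ov$n_maternal_only, c(1L, 0L, 0L))
  expect_equal(ov$n_fetal_only, c(1L, 1L, 0L))
  expect_equal(ov$n_shared, c(1L, 0L, 3L))
  # set-size identities hold for every dyad
  sets <- calledSets(calls)
  for (i in 1:3) {
    m <- sets[[sprintf("M%02d", i)]]; f <- sets[[sprintf("F%02d", i)]]
    expect_equal(ov$n_shared[i] + ov$n_maternal_only[i], length(m))
    expect_equal(ov$n_shared[i] + ov$n_fetal_only[i], length(f))
  }
})

test_that("overlap counts are invariant to sample order and phage renaming", {
  sheet <- pairSheet(2)
  sets <- list(M01 = c("A", "B"), F01 = "B", M02 = "C", F02 = c("C", "A"))
  ov1 <- dyadOverlap(callSetFromSets(sets, sampleIds(sheet)), sheet)
  ren <- lapply(sets, function(s) chartr("ABC", "ZYX", s))
  ov2 <- dyadOverlap(callSetFromSets(ren, sampleIds(sheet)), sheet)
  expect_equal(ov1[, -(1:2)], ov2[, -(1:2)])
})

test_that("sample-count histogram tallies singletons", {
  sheet <- pairSheet(2)
  calls <- callSetFromSets(
    list(M01 = c("A", "B"), F01 = "A", M02 = "A", F02 = character(0)),
    sampleIds(sheet))
  h <- sampleCountHistogram(calls)
  expect_equal(h$n_samples[h$phage_id == "A"], 3L)
  expect_equal(h$n_samples[h$phage_id == "B"], 1L)
  expect_equal(attr(h, "n_singletons"), 1L)
  empty <- callSetFromSets(list(M01 = character(0)), sampleIds(sheet))
  expect_equal(nrow(sampleCountHistogram(empty)), 0L)
})

test_that("expected dyad pairs follow n * D / C(N,2)", {
  expect_equal(expectedDyadPairs(10, 20, 10), 100 / 190)
  expect_equal(round(expectedDyadPairs(10, 20, 10), 1), 0.5)
  expect_equal(expectedDyadPairs(28, 124, 62), 1736 / 7626)
  expect_equal(round(expectedDyadPairs(28, 124, 62), 1), 0.2)
  expect_equal(expectedDyadPairs(17, 50, 0), 0)
  expect_error(expectedDyadPairs(5, 1, 0), "at least 2")
})

test_that("expected dyad pairs agree with a Monte-Carlo null", {
  set.seed(2024)
  for (cfg in list(c(N = 20, D = 10), c(N = 124, D = 62))) {
    N <- cfg[["N"]]; D <- cfg[["D"]]
    # dyads pair sample 2i-1 with 2i; draw unordered pairs uniformly
    nSim <- 1e5
    a <- sample.int(N, nSim, replace = TRUE)
    b <- sample.int(N - 1L, nSim, replace = TRUE)
    b <- ifelse(b >= a, b + 1L, b)
    isDyad <- (abs(a - b) == 1L) & (pmin(a, b) %% 2L == 1L) &
      (pmax(a, b) <= 2L * D)
    pHat <- mean(isDyad)
    p <- D / choose(N, 2)
    se <- sqrt(p * (1 - p) / nSim)
    expect_lt(abs(pHat - p), 3 * se)
    # and the expectation is the per-trial probability times n
    expect_equal(expectedDyadPairs(7, N, D), 7 * p)
  }
})

test_that("the exact enrichment test reproduces frozen tail probabilities", {
  # Large-cohort configuration: 11 observed dyads among 28 two-sample
  # phages over 124 samples / 62 dyads is far beyond the 0.001 bound
  witt <- dyadNullTest(11, 28, 124, 62)
  expect_lt(witt$p.value, 0.001)
  expect_equal(round(witt$expected, 1), 0.2)
  # and under the Fisher 2x2 variant as well
  expect_lt(dyadNullTest(11, 28, 124, 62, method = "fisher")$p.value, 0.001)

  # Small-cohort configuration: the exact binomial upper tail
  # sum_{k>=3} C(10,k) p^k (1-p)^(10-k), p = 10/190, evaluated
  # independently by direct summation over k = 3..10
  p <- 10 / 190
  tail3 <- sum(vapply(3:10, function(k)
    choose(10, k) * p^k * (1 - p)^(10 - k), 0))
  pope <- dyadNullTest(3, 10, 20, 10)
  expect_equal(pope$p.value, tail3, tolerance = 1e-12)
  expect_equal(round(tail3, 6), 0.013229)

  # degenerate and boundary behaviour
  expect_equal(dyadNullTest(0, 10, 20, 10)$p.value, 1)
  expect_true(is.na(dyadNullTest(0, 0, 20, 10)$p.value))
  # one-sided p is non-increasing in the observed count
  ps <- vapply(0:10, function(k) dyadNullTest(k, 10, 20, 10)$p.value, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("dyadEnrichmentTest extracts two-sample phages and dyad pairs", {
  sheet <- pairSheet(5)
  calls <- callSetFromSets(
    list(M01 = c("A", "C"), F01 = c("A", "D"),     # A on dyad D01
         M02 = "B", F03 = "B",                     # B on a non-dyad pair
         M04 = "C",                                # C on non-dyad pair M01/M04
         F05 = "E"),                               # E a singleton: ignored
    sampleIds(sheet))
  res <- dyadEnrichmentTest(calls, sheet)
  expect_equal(res$n, 3L)
  expect_equal(res$observed, 1L)
  expect_equal(res$N, 10L)
  expect_equal(res$D, 5L)
  expect_equal(res$expected, 3 * 5 / choose(10, 2))
  pairs <- attr(res, "pairs")
  expect_true(pairs$is_dyad[pairs$phage_id == "A"])
  expect_false(any(pairs$is_dyad[pairs$phage_id %in% c("B", "C")]))
})

test_that("condition stratification keeps phages in more than 7 samples", {
  n <- 9L
  sheet <- SampleSheet(
    c(sprintf("M%02d", 1:n), sprintf("F%02d", 1:n)), "W",
    rep(c("maternal", "fetal"), each = n), rep(sprintf("D%02d", 1:n), 2),
    term = rep(c(rep(TRUE, 5), rep(FALSE, 4)), 2),
    chorioamnionitis = rep(c(rep(FALSE, 7), TRUE, TRUE), 2))
  samples <- sampleIds(sheet)
  sets <- c(setNames(rep(list("P8"), 8), samples[1:8]),
            setNames(rep(list(character(0)), 10), samples[9:18]))
  sets[seq_len(7)] <- lapply(sets[seq_len(7)], c, "P7")  # P7 in 7 samples
  calls <- callSetFromSets(sets, samples)
  tab <- stratifyByCondition(calls, sheet, minSamples = 8)
  expect_equal(tab$phage_id, "P8")          # 7-sample phage excluded
  expect_equal(tab$n_samples, 8L)
  # carriers are M01..M08: term M01-M05, preterm M06-M08, chorio M08
  expect_equal(tab$n_term, 5L)
  expect_equal(tab$n_preterm, 3L)
  expect_equal(tab$n_chorio_affected, 1L)
  expect_equal(tab$n_chorio_unaffected, 7L)
})

test_that("cross-cohort overlap counts intersections of phage key sets", {
  a <- c("DB::A", "DB::B", "DB::C")
  b <- c("DB::B", "DB::C", "DB::D")
  ov <- crossCohortOverlap(list(pope = a, witt = b))
  expect_equal(unname(ov$sizes), c(3L, 3L))
  expect_equal(ov$pairwise["pope", "witt"], 2L)
  expect_setequal(ov$shared_all, c("DB::B", "DB::C"))
  expect_equal(crossCohortOverlap(list(x = a, y = a))$pairwise["x", "y"], 3L)
  expect_equal(crossCohortOverlap(list(x = a, y = "Z::Q"))$pairwise["x", "y"], 0L)
  expect_error(crossCohortOverlap(list(x = a)), "two cohorts")
})
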