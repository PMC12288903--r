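## Presence/absence statistics over called phages: dyad overlap, sample
## count histograms, the exactly-two-samples enrichment test, condition
## stratification and cross-cohort overlap.

#' Per-dyad overlap decomposition
#'
#' For every complete maternal-infant dyad, splits the called phage sets
#' (database-qualified) into maternal-only, fetal-only and shared.
#' Incomplete dyads are skipped with a warning.
#'
#' @param calls a [PhageCallSet-class].
#' @param samples a [SampleSheet-class].
#' @param dropPrevalent drop phages flagged by [prevalenceFilter()].
#' @return a data.frame with columns `cohort`, `dyad_id`,
#'   `n_maternal_only`, `n_fetal_only`, `n_shared`.
#' @export
dyadOverlap <- function(calls, samples, dropPrevalent = FALSE) {
    inc <- incompleteDyads(samples)
    if (length(inc))
        warning("skipping incomplete dyad(s): ",
                paste(inc, collapse = ", "))
    dy <- dyadTable(samples)
    sets <- calledSets(calls, dropPrevalent = dropPrevalent)
    res <- lapply(seq_len(nrow(dy)), function(i) {
        m <- sets[[dy$maternal_id[i]]]
        f <- sets[[dy$fetal_id[i]]]
        if (is.null(m)) m <- character(0)
        if (is.null(f)) f <- character(0)
        data.frame(cohort = dy$cohort[i], dyad_id = dy$dyad_id[i],
                   n_maternal_only = length(setdiff(m, f)),
                   n_fetal_only = length(setdiff(f, m)),
                   n_shared = length(intersect(m, f)),
                   stringsAsFactors = FALSE)
    })
    if (!length(res))
        return(data.frame(cohort = character(0), dyad_id = character(0),
                          n_maternal_only = integer(0),
                          n_fetal_only = integer(0), n_shared = integer(0),
                          stringsAsFactors = FALSE))
    do.call(rbind, res)
}

#' Sample-count histogram of called phages
#'
#' For each called phage, the number of samples in which it was called;
#' the number of phages seen in exactly one sample (the "unique" tally)
#' is attached as attribute `n_singletons`.
#'
#' @inheritParams dyadOverlap
#' @return a data.frame (`database`, `phage_id`, `n_samples`), phages with
#'   at least one call only.
#' @export
sampleCountHistogram <- function(calls, dropPrevalent = FALSE) {
    if (dropPrevalent) calls <- dropPrevalentPhages(calls)
    n <- rowSums(assay(calls, "called"))
    keep <- n > 0L
    out <- data.frame(database = rowData(calls)$database[keep],
                      phage_id = rowData(calls)$phage_id[keep],
                      n_samples = as.integer(n[keep]),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "n_singletons") <- sum(out$n_samples == 1L)
    out
}

#' Expected dyad pairs under the uniform random-pair null
#'
#' Each phage present in exactly two samples defines an unordered pair of
#' samples. Under the null that this pair is uniform over all `choose(N,
#' 2)` unordered sample pairs, of which `D` are maternal-infant dyads, the
#' expected number of dyad pairs among `n` such phages is
#' `n * D / (N * (N - 1) / 2)`.
#'
#' @param n number of two-sample phages (each one trial).
#' @param N number of (non-excluded) samples, at least 2.
#' @param D number of complete dyads.
#' @return the expected count, exactly.
#' @examples
#' expectedDyadPairs(10, 20, 10)   # 0.526...
#' expectedDyadPairs(28, 124, 62)  # 0.2276...
#' @export
expectedDyadPairs <- function(n, N, D) {
    if (N < 2) stop("N must be at least 2")
    stopifnot(n >= 0, D >= 0, D <= N / 2)
    n * D / (N * (N - 1) / 2)
}

#' Exact test of dyad enrichment among two-sample phages
#'
#' Given `n` phages each present in exactly two samples, of which
#' `observed` landed on maternal-infant dyads, tests one-sidedly whether
#' dyads occur more often than the uniform random-pair null predicts.
#' The primary method is the exact binomial tail with success probability
#' `D / choose(N, 2)` over `n` trials; `method = "fisher"` instead builds
#' the 2x2 table (pairs defined by two-sample phages vs all other
#' unordered sample pairs) x (dyad vs non-dyad) and applies a one-sided
#' Fisher's exact test.
#'
#' @param observed observed dyad pairs (0..n).
#' @param n number of two-sample phages.
#' @param N number of samples.
#' @param D number of dyads.
#' @param method `"binomial"` (default) or `"fisher"`.
#' @return a list of class `dyadNullResult` with `n`, `N`, `D`,
#'   `observed`, `expected`, `p.value`, `method`.
#' @export
dyadNullTest <- function(observed, n, N, D,
                         method = c("binomial", "fisher")) {
    method <- match.arg(method)
    stopifnot(observed >= 0, observed <= n)
    expected <- expectedDyadPairs(n, N, D)
    if (n == 0L) {
        p <- NA_real_
    } else if (method == "binomial") {
        p <- pbinom(observed - 1L, n, D / (N * (N - 1) / 2),
                    lower.tail = FALSE)
    } else {
        pairsTotal <- N * (N - 1) / 2
        a <- observed; b <- n - observed
        c_ <- max(D - observed, 0L)
        d_ <- pairsTotal - n - c_
        p <- fisher.test(matrix(c(a, b, c_, d_), nrow = 2, byrow = TRUE),
                         alternative = "greater")$p.value
    }
    structure(list(n = n, N = N, D = D, observed = observed,
                   expected = expected, p.value = p, method = method),
              class = "dyadNullResult")
}

#' @export
print.dyadNullResult <- function(x, ...) {
    cat("Dyad enrichment among two-sample phages (", x$method, ")\n",
        sep = "")
    cat(sprintf("  n = %d two-sample phages, N = %d samples, D = %d dyads\n",
                x$n, x$N, x$D))
    cat(sprintf("  observed dyad pairs: %d; expected: %.4g\n",
                x$observed, x$expected))
    if (is.na(x$p.value)) cat("  p-value: not applicable (n = 0)\n")
    else cat(sprintf("  one-sided p-value: %.4g\n", x$p.value))
    invisible(x)
}

#' Dyad enrichment from a call set
#'
#' Identifies phages called in exactly two (non-excluded) samples, counts
#' how many of those sample pairs are maternal-infant dyads, and runs
#' [dyadNullTest()]. Each phage contributes one trial even when several
#' phages define the same sample pair. By default the analysis runs before
#' prevalence filtering.
#'
#' @inheritParams dyadOverlap
#' @param method passed to [dyadNullTest()].
#' @return a `dyadNullResult`, with the two-sample phage table attached as
#'   attribute `pairs`.
#' @export
dyadEnrichmentTest <- function(calls, samples,
                               method = c("binomial", "fisher"),
                               dropPrevalent = FALSE) {
    method <- match.arg(method)
    if (dropPrevalent) calls <- dropPrevalentPhages(calls)
    act <- activeSamples(samples)
    keep <- colnames(calls) %in% sampleIds(act)
    calls <- calls[, keep]
    called <- assay(calls, "called")
    two <- which(rowSums(called) == 2L)
    dy <- dyadTable(samples)
    dyKey <- paste(pmin(dy$maternal_id, dy$fetal_id),
                   pmax(dy$maternal_id, dy$fetal_id), sep = "\r")
    pairs <- lapply(two, function(i) {
        sm <- colnames(calls)[called[i, ]]
        data.frame(database = rowData(calls)$database[i],
                   phage_id = rowData(calls)$phage_id[i],
                   sample_1 = min(sm), sample_2 = max(sm),
                   is_dyad = paste(min(sm), max(sm), sep = "\r") %in% dyKey,
                   stringsAsFactors = FALSE)
    })
    pairs <- if (length(pairs)) do.call(rbind, pairs) else
        data.frame(database = character(0), phage_id = character(0),
                   sample_1 = character(0), sample_2 = character(0),
                   is_dyad = logical(0), stringsAsFactors = FALSE)
    res <- dyadNullTest(sum(pairs$is_dyad), nrow(pairs),
                        ncol(calls), nrow(dy), method = method)
    attr(res, "pairs") <- pairs
    res
}

#' Stratify common phages by condition
#'
#' Phages called in at least `minSamples` samples are tabulated by the
#' condition classes of the carrying samples: term, preterm,
#' chorioamnionitis-affected and -unaffected (samples with an unknown flag
#' are not counted for that condition). Purely descriptive.
#'
#' @inheritParams dyadOverlap
#' @param minSamples minimum call count for inclusion (default 8, i.e.
#'   "more than 7 samples").
#' @return a data.frame with per-phage condition counts.
#' @export
stratifyByCondition <- function(calls, samples, minSamples = 8L,
                                dropPrevalent = FALSE) {
    if (dropPrevalent) calls <- dropPrevalentPhages(calls)
    act <- as.data.frame(activeSamples(samples)@samples)
    calls <- calls[, colnames(calls) %in% act$sample_id]
    called <- assay(calls, "called")
    n <- rowSums(called)
    keep <- which(n >= minSamples)
    meta <- act[match(colnames(calls), act$sample_id), ]
    countIf <- function(i, flag) sum(called[i, ] & !is.na(flag) & flag)
    res <- lapply(keep, function(i) data.frame(
        database = rowData(calls)$database[i],
        phage_id = rowData(calls)$phage_id[i],
        n_samples = as.integer(n[i]),
        n_term = countIf(i, meta$term),
        n_preterm = countIf(i, !meta$term),
        n_chorio_affected = countIf(i, meta$chorioamnionitis),
        n_chorio_unaffected = countIf(i, !meta$chorioamnionitis),
        stringsAsFactors = FALSE))
    if (!length(res))
        return(data.frame(database = character(0), phage_id = character(0),
                          n_samples = integer(0), n_term = integer(0),
                          n_preterm = integer(0),
                          n_chorio_affected = integer(0),
                          n_chorio_unaffected = integer(0),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Cross-cohort overlap of called phages
#'
#' @param callsByCohort a named list (cohort -> [PhageCallSet-class] or
#'   character vector of phage keys).
#' @param dropPrevalent drop prevalent-flagged phages from `PhageCallSet`
#'   inputs.
#' @return a list with per-cohort set sizes, the pairwise intersection
#'   matrix, the intersection of all cohorts and the per-cohort sets.
#' @export
crossCohortOverlap <- function(callsByCohort, dropPrevalent = FALSE) {
    if (length(callsByCohort) < 2L)
        stop("need at least two cohorts")
    sets <- lapply(callsByCohort, function(x) {
        if (is(x, "PhageCallSet")) {
            h <- sampleCountHistogram(x, dropPrevalent = dropPrevalent)
            unique(paste(h$database, h$phage_id, sep = "::"))
        } else unique(as.character(x))
    })
    k <- length(sets)
    inter <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
    for (i in seq_len(k)) for (j in seq_len(k))
        inter[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    list(sizes = lengths(sets),
         pairwise = inter,
         shared_all = Reduce(intersect, sets),
         sets = sets)
}
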