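## Per-sample phage calling: unique-read counts, breadth of coverage,
## the calling rule, and the prevalence filter.

#' Calling configuration
#'
#' @param minUniqueReads minimum unique reads for a call (default 10).
#' @param minCoverageBp minimum breadth of coverage in bp (default 500).
#' @param prevalenceMax a phage called in strictly more than this fraction
#'   of samples is flagged prevalent (default 0.75).
#' @return a list of class `callingConfig`.
#' @export
callingConfig <- function(minUniqueReads = 10L, minCoverageBp = 500L,
                          prevalenceMax = 0.75) {
    stopifnot(minUniqueReads >= 1L, minCoverageBp >= 1L,
              prevalenceMax > 0, prevalenceMax <= 1)
    structure(list(minUniqueReads = as.integer(minUniqueReads),
                   minCoverageBp = as.integer(minCoverageBp),
                   prevalenceMax = prevalenceMax),
              class = "callingConfig")
}

#' Count unique reads for one (sample, phage)
#'
#' A unique read has a unique sequencing ID and a unique alignment start
#' site on the phage genome. Duplicate read IDs are collapsed first,
#' keeping the hit with the best (lowest) e-value, ties broken by longer
#' alignment; then duplicate start sites are collapsed. The start site is
#' the 5'-most subject coordinate, `min(subject_start, subject_end)`, so
#' reverse-strand duplicates collapse with forward duplicates at the same
#' locus.
#'
#' @param hits assigned hit rows for a single (sample, phage).
#' @return integer count of unique reads.
#' @export
countUniqueReads <- function(hits) {
    if (!nrow(hits)) return(0L)
    start <- pmin(hits$subject_start, hits$subject_end)
    ord <- order(hits$read_id, hits$evalue, -hits$align_length)
    keep <- ord[!duplicated(hits$read_id[ord])]
    length(unique(start[keep]))
}

#' Breadth of coverage for one (sample, phage)
#'
#' The number of genome positions covered by at least one assigned
#' alignment: the size of the union of all subject intervals, equivalent
#' to marking each aligned position off a 1..L genome vector and counting
#' what is marked.
#'
#' @param hits assigned hit rows for a single (sample, phage); subject
#'   coordinates 1-based inclusive.
#' @param genomeLength the phage genome length in bp.
#' @return covered bp, between 0 and `genomeLength`.
#' @export
computeCoverage <- function(hits, genomeLength) {
    if (!nrow(hits)) return(0L)
    s <- pmin(hits$subject_start, hits$subject_end)
    e <- pmax(hits$subject_start, hits$subject_end)
    if (any(s < 1L) || any(e > genomeLength))
        stop("alignment interval outside [1, ", genomeLength, "]")
    sum(width(reduce(IRanges(start = s, end = e))))
}

#' Call phages per sample
#'
#' Builds a [PhageCallSet-class]: for every (database, phage) with at
#' least one assigned read in any sample, per-sample assigned-read counts,
#' unique-read counts and breadth of coverage, and the call flag
#' (`nUniqueReads >= minUniqueReads` and `coverageBp >= minCoverageBp`).
#'
#' @param hits assigned hits (see [assignedHits()]) with `sample_id`.
#' @param db a [PhageDb-class] indexing every phage in `hits`.
#' @param config a [callingConfig()].
#' @param samples optional [SampleSheet-class] or character vector fixing
#'   the sample (column) set; defaults to the samples present in `hits`.
#'   When a sheet is given, its non-excluded samples form the columns and
#'   the sheet's metadata becomes `colData`.
#' @return a [PhageCallSet-class].
#' @export
callPhages <- function(hits, db, config = callingConfig(), samples = NULL) {
    if (is(samples, "SampleSheet")) {
        act <- activeSamples(samples)
        sampleIdsUse <- sampleIds(act)
        colMeta <- act@samples
    } else if (is.character(samples)) {
        sampleIdsUse <- samples
        colMeta <- DataFrame(sample_id = samples)
    } else {
        sampleIdsUse <- sort(unique(hits$sample_id))
        colMeta <- DataFrame(sample_id = sampleIdsUse)
    }
    if (is.null(hits))
        hits <- cbind(data.frame(sample_id = character(0)),
                      emptyHitTable())
    hits <- hits[hits$sample_id %in% sampleIdsUse, , drop = FALSE]

    glen <- genomeLengths(db)
    hkey <- paste(hits$database, hits$phage_id, sep = "::")
    unknown <- setdiff(unique(hkey), names(glen))
    if (length(unknown))
        stop("phage(s) absent from database index: ",
             paste(head(unknown, 5L), collapse = ", "))

    phages <- sort(unique(hkey))
    nr <- length(phages); nc <- length(sampleIdsUse)
    zero <- matrix(0L, nr, nc, dimnames = list(phages, sampleIdsUse))
    nReads <- nUnique <- covBp <- zero

    if (nrow(hits)) {
        grp <- split(seq_len(nrow(hits)),
                     paste(hkey, hits$sample_id, sep = "\r"))
        for (g in grp) {
            ph <- hkey[g[1L]]; sm <- hits$sample_id[g[1L]]
            sub <- hits[g, , drop = FALSE]
            nReads[ph, sm] <- length(unique(sub$read_id))
            nUnique[ph, sm] <- countUniqueReads(sub)
            covBp[ph, sm] <- computeCoverage(sub, glen[[ph]])
        }
    }
    called <- nUnique >= config$minUniqueReads & covBp >= config$minCoverageBp

    split2 <- strsplit(phages, "::", fixed = TRUE)
    rd <- DataFrame(database = vapply(split2, `[`, "", 1L),
                    phage_id = vapply(split2, `[`, "", 2L),
                    genome_length = unname(glen[phages]),
                    row.names = phages)
    se <- SummarizedExperiment(
        assays = list(nReads = nReads, nUniqueReads = nUnique,
                      coverageBp = covBp, called = called),
        rowData = rd, colData = colMeta)
    out <- new("PhageCallSet", se)
    metadata(out)$callingConfig <- config
    out
}

#' Flag prevalent phages
#'
#' A phage called in strictly more than `prevalenceMax` of the samples is
#' flagged prevalent (putative ubiquitous signal or contamination).
#' Downstream statistics may include or drop prevalent phages via their
#' `dropPrevalent` argument.
#'
#' @param x a [PhageCallSet-class].
#' @param config a [callingConfig()]; only `prevalenceMax` is used.
#' @param nSamples denominator; defaults to the number of columns of `x`
#'   (the non-excluded cohort samples).
#' @return `x` with a logical `prevalent` column in `rowData`.
#' @export
prevalenceFilter <- function(x, config = callingConfig(),
                             nSamples = ncol(x)) {
    if (nSamples == 0L)
        stop("nSamples must be positive")
    prev <- rowSums(assay(x, "called")) / nSamples > config$prevalenceMax
    rowData(x)$prevalent <- unname(prev)
    metadata(x)$prevalenceMax <- config$prevalenceMax
    x
}

#' @describeIn PhageCallSet-class database-qualified phage keys
#'   (`database::phage_id`)
#' @param x a `PhageCallSet`.
#' @export
setMethod("phageKeys", "PhageCallSet", function(x) {
    paste(rowData(x)$database, rowData(x)$phage_id, sep = "::")
})

#' @describeIn PhageCallSet-class list of called phage keys per sample
#' @param dropPrevalent drop phages flagged by [prevalenceFilter()].
#' @export
setMethod("calledSets", "PhageCallSet", function(x, dropPrevalent = FALSE) {
    if (dropPrevalent) x <- dropPrevalentPhages(x)
    called <- assay(x, "called")
    keys <- phageKeys(x)
    lapply(setNames(seq_len(ncol(x)), colnames(x)),
           function(j) keys[called[, j]])
})

dropPrevalentPhages <- function(x) {
    prev <- rowData(x)$prevalent
    if (is.null(prev))
        stop("run prevalenceFilter() before dropPrevalent = TRUE")
    x[!prev, ]
}

#' Report likely duplicate sequences across databases
#'
#' Pairs of phages from different databases with identical call patterns,
#' identical unique-read counts and identical coverage across all samples
#' are reported as putative inter-database duplicates. They are never
#' merged.
#'
#' @param x a [PhageCallSet-class].
#' @return a data.frame of candidate pairs (possibly empty).
#' @export
duplicateSequenceReport <- function(x) {
    called <- assay(x, "called")
    active <- which(rowSums(called) > 0L)
    sig <- vapply(active, function(i)
        paste(c(assay(x, "nUniqueReads")[i, ], assay(x, "coverageBp")[i, ],
                as.integer(called[i, ])), collapse = ","), "")
    dupGroups <- split(active, sig)
    out <- list()
    for (g in dupGroups) {
        if (length(g) < 2L) next
        dbs <- rowData(x)$database[g]
        if (length(unique(dbs)) < 2L) next
        cmb <- combn(g, 2L)
        for (k in seq_len(ncol(cmb))) {
            i <- cmb[1L, k]; j <- cmb[2L, k]
            if (rowData(x)$database[i] == rowData(x)$database[j]) next
            out[[length(out) + 1L]] <- data.frame(
                phage_1 = phageKeys(x)[i], phage_2 = phageKeys(x)[j],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(phage_1 = character(0), phage_2 = character(0),
                          stringsAsFactors = FALSE))
    do.call(rbind, out)
}

setMethod("show", "PhageCallSet", function(object) {
    called <- assay(object, "called")
    cat("PhageCallSet:", nrow(object), "phage(s) x", ncol(object),
        "sample(s);", sum(called), "call(s)\n")
    prev <- rowData(object)$prevalent
    if (!is.null(prev))
        cat("  prevalent phage(s):", sum(prev), "\n")
})

#' Tidy calls table
#'
#' One row per (sample, database, phage) with at least one assigned read.
#'
#' @param x a [PhageCallSet-class].
#' @param ... unused.
#' @export
as.data.frame.PhageCallSet <- function(x, ...) {
    nR <- assay(x, "nReads")
    idx <- which(nR > 0L, arr.ind = TRUE)
    rd <- rowData(x)
    out <- data.frame(
        sample_id = colnames(x)[idx[, 2L]],
        database = rd$database[idx[, 1L]],
        phage_id = rd$phage_id[idx[, 1L]],
        n_reads = nR[idx],
        n_unique_reads = assay(x, "nUniqueReads")[idx],
        coverage_bp = assay(x, "coverageBp")[idx],
        called = assay(x, "called")[idx],
        stringsAsFactors = FALSE)
    if (!is.null(rd$prevalent))
        out$prevalent <- rd$prevalent[idx[, 1L]]
    out[order(out$sample_id, out$database, out$phage_id), , drop = FALSE]
}
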