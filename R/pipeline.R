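## End-to-end orchestration: assign -> call -> prevalence -> dyad
## statistics -> annotation, with a run report.

#' Run the full analysis pipeline
#'
#' Executes every stage on in-memory inputs: e-value filtering and
#' multimapper resolution ([assignReads()]), per-sample calling
#' ([callPhages()]), the prevalence filter, dyad statistics
#' ([dyadOverlap()], [sampleCountHistogram()], [dyadEnrichmentTest()],
#' [stratifyByCondition()]) and host annotation ([annotateHosts()]).
#' Deterministic: identical inputs and configuration yield identical
#' outputs. Any stage error is re-raised with the stage named.
#'
#' @param hits hit data.frame with a `sample_id` column (e.g. from
#'   [readCohort()] or [simulateCohort()]).
#' @param db a [PhageDb-class].
#' @param samples a [SampleSheet-class].
#' @param assignCfg an [assignmentConfig()].
#' @param callCfg a [callingConfig()].
#' @param genusLists a [habitatGenusLists()].
#' @param minSamplesStratify threshold for [stratifyByCondition()].
#' @param outDir optional directory; when given, every table is written as
#'   TSV and the report as `report.tsv`.
#' @return a list: `assignments`, `calls` (a [PhageCallSet-class] with
#'   the prevalent flag), `overlap`, `histogram`, `enrichment`,
#'   `stratification`, `annotations`, `habitat`, `duplicates`, `report`.
#' @export
runPipeline <- function(hits, db, samples,
                        assignCfg = assignmentConfig(),
                        callCfg = callingConfig(),
                        genusLists = habitatGenusLists(),
                        minSamplesStratify = 8L,
                        outDir = NULL) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    filtered <- stage("filter", filterHits(hits, assignCfg))
    assignments <- stage("assign", assignReads(hits, assignCfg))
    ahits <- stage("assign", assignedHits(filtered, assignments))
    calls <- stage("call",
                   callPhages(ahits, db, callCfg, samples = samples))
    calls <- stage("prevalence", prevalenceFilter(calls, callCfg))
    overlap <- stage("dyadstats", dyadOverlap(calls, samples))
    histogram <- stage("dyadstats", sampleCountHistogram(calls))
    enrichment <- stage("dyadstats", dyadEnrichmentTest(calls, samples))
    strat <- stage("dyadstats",
                   stratifyByCondition(calls, samples,
                                       minSamples = minSamplesStratify))
    annotations <- stage("annotate", annotateHosts(calls, db, genusLists))
    habitat <- stage("annotate", habitatSummary(annotations, calls, samples))
    dups <- stage("call", duplicateSequenceReport(calls))

    report <- data.frame(
        stage = c("input", "filter", "assign", "call", "prevalence",
                  "dyadstats", "annotate"),
        rows = c(nrow(hits), nrow(filtered), nrow(assignments),
                 sum(assay(calls, "called")),
                 sum(rowData(calls)$prevalent),
                 nrow(overlap), nrow(annotations)),
        detail = c("hit rows", "hits passing e-value filter",
                   "read assignments", "phage calls",
                   "prevalent phages", "complete dyads",
                   "annotated phages"),
        stringsAsFactors = FALSE)

    out <- list(assignments = assignments, calls = calls,
                overlap = overlap, histogram = histogram,
                enrichment = enrichment, stratification = strat,
                annotations = annotations, habitat = habitat,
                duplicates = dups, report = report)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeResultTable(assignments, file.path(outDir, "assignments.tsv"))
        writeResultTable(as.data.frame(calls), file.path(outDir, "calls.tsv"))
        writeResultTable(overlap, file.path(outDir, "dyad_overlap.tsv"))
        writeResultTable(histogram, file.path(outDir, "sample_counts.tsv"))
        writeResultTable(strat, file.path(outDir, "stratification.tsv"))
        writeResultTable(annotations, file.path(outDir, "annotations.tsv"))
        writeResultTable(habitat, file.path(outDir, "habitat_summary.tsv"))
        writeResultTable(dups, file.path(outDir, "duplicates.tsv"))
        enr <- data.frame(n = enrichment$n, N = enrichment$N,
                          D = enrichment$D, observed = enrichment$observed,
                          expected = enrichment$expected,
                          p_value = enrichment$p.value,
                          method = enrichment$method)
        writeResultTable(enr, file.path(outDir, "enrichment.tsv"))
        writeResultTable(report, file.path(outDir, "report.tsv"))
    }
    out
}
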