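#' Phage database records
#'
#' A `PhageDb` holds one row per database sequence: the sequence identifier,
#' its genome length in bp, the database it came from (e.g. CPD, GPD, GVD,
#' ELGV, MGV), and optional metadata (predicted bacterial host genus,
#' morphology, source habitat). Phage identity is database-qualified
#' throughout the package: the same identifier in two databases is two
#' phages, and records must be unique within a database.
#'
#' @slot records a [S4Vectors::DataFrame] with columns `phage_id`,
#'   `genome_length`, `database`, `host_genus`, `morphology`,
#'   `source_habitat`.
#' @seealso [PhageDb()], [readPhageDb()], [dbCensus()]
#' @name PhageDb-class
#' @exportClass PhageDb
setClass("PhageDb", slots = c(records = "DataFrame"))

setValidity("PhageDb", function(object) {
    rec <- object@records
    need <- c("phage_id", "genome_length", "database",
              "host_genus", "morphology", "source_habitat")
    miss <- setdiff(need, colnames(rec))
    if (length(miss))
        return(paste("missing record columns:", paste(miss, collapse = ", ")))
    if (nrow(rec) == 0L)
        return(TRUE)
    if (anyNA(rec$phage_id) || anyNA(rec$database))
        return("phage_id and database must be non-missing")
    if (anyNA(rec$genome_length) || any(rec$genome_length < 1L))
        return("genome_length must be >= 1 for every record")
    key <- paste(rec$database, rec$phage_id, sep = "\r")
    if (anyDuplicated(key))
        return("phage_id must be unique within a database")
    TRUE
})

#' Cohort sample sheet
#'
#' A `SampleSheet` describes the samples of one or more cohorts: sample ID,
#' cohort, role (`maternal` or `fetal`), dyad ID linking the two samples of
#' a pregnancy, tri-state condition flags (`preeclampsia`, `term`,
#' `chorioamnionitis`; `NA` = unknown), and an `excluded` flag. Excluded
#' samples take part in no statistic. Within a cohort a dyad may hold at
#' most one maternal and one fetal sample.
#'
#' @slot samples a [S4Vectors::DataFrame] with columns `sample_id`,
#'   `cohort`, `role`, `dyad_id`, `preeclampsia`, `term`,
#'   `chorioamnionitis`, `excluded`.
#' @seealso [SampleSheet()], [readSampleSheet()], [activeSamples()],
#'   [dyadTable()]
#' @name SampleSheet-class
#' @exportClass SampleSheet
setClass("SampleSheet", slots = c(samples = "DataFrame"))

setValidity("SampleSheet", function(object) {
    s <- object@samples
    need <- c("sample_id", "cohort", "role", "dyad_id",
              "preeclampsia", "term", "chorioamnionitis", "excluded")
    miss <- setdiff(need, colnames(s))
    if (length(miss))
        return(paste("missing sample columns:", paste(miss, collapse = ", ")))
    if (nrow(s) == 0L)
        return(TRUE)
    if (anyDuplicated(s$sample_id))
        return("duplicated sample_id")
    if (!all(s$role %in% c("maternal", "fetal")))
        return("role must be 'maternal' or 'fetal'")
    if (anyNA(s$excluded))
        return("excluded must be TRUE or FALSE")
    has_dyad <- !is.na(s$dyad_id) & nzchar(s$dyad_id)
    key <- paste(s$cohort, s$dyad_id, s$role, sep = "\r")[has_dyad]
    if (anyDuplicated(key))
        return("a dyad_id may hold at most one maternal and one fetal sample per cohort")
    TRUE
})

#' Per-sample phage calls
#'
#' A `PhageCallSet` extends [SummarizedExperiment::SummarizedExperiment]:
#' rows are database-qualified phages, columns are samples, and the assays
#' are `nReads` (assigned reads), `nUniqueReads` (reads after collapsing
#' duplicate sequencing IDs and duplicate genome start sites), `coverageBp`
#' (breadth of coverage: the interval-union size over assigned alignments)
#' and `called` (the calling rule: at least `minUniqueReads` unique reads
#' covering at least `minCoverageBp` of the genome). [prevalenceFilter()]
#' adds a logical `prevalent` column to `rowData` marking phages called in
#' more than a set fraction of samples.
#'
#' @seealso [callPhages()], [prevalenceFilter()], [calledSets()],
#'   [phageKeys()]
#' @name PhageCallSet-class
#' @exportClass PhageCallSet
setClass("PhageCallSet", contains = "SummarizedExperiment")

setValidity("PhageCallSet", function(object) {
    need <- c("nReads", "nUniqueReads", "coverageBp", "called")
    miss <- setdiff(need, names(assays(object)))
    if (length(miss))
        return(paste("missing assays:", paste(miss, collapse = ", ")))
    rd <- rowData(object)
    if (!all(c("database", "phage_id") %in% colnames(rd)))
        return("rowData must carry database and phage_id")
    if (nrow(object)) {
        nu <- assay(object, "nUniqueReads")
        if (any(nu > assay(object, "nReads")))
            return("nUniqueReads must not exceed nReads")
        if (any(assay(object, "coverageBp") < 0))
            return("coverageBp must be non-negative")
    }
    TRUE
})
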