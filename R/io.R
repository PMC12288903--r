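## Readers and writers for every external artifact the pipeline touches:
## alignment hit tables (12-column tabular), phage database FASTA +
## metadata, sample sheets, and result tables.

HIT_COLUMNS <- c("read_id", "phage_id", "percent_identity", "align_length",
                 "mismatches", "gap_opens", "query_start", "query_end",
                 "subject_start", "subject_end", "evalue", "bitscore")

#' Construct a phage database record table
#'
#' @param phage_id character vector of sequence identifiers.
#' @param genome_length integer vector of genome lengths in bp (>= 1).
#' @param database database label (recycled), e.g. `"CPD"`, `"GPD"`,
#'   `"GVD"`, `"ELGV"`, `"MGV"` or any free string.
#' @param host_genus,morphology,source_habitat optional metadata vectors
#'   (`NA` where unknown).
#' @return a [PhageDb-class] object.
#' @examples
#' db <- PhageDb(paste0("GVD_", 1:3), c(5000L, 8000L, 12000L), "GVD")
#' dbCensus(db)
#' @export
PhageDb <- function(phage_id, genome_length, database,
                    host_genus = NA_character_,
                    morphology = NA_character_,
                    source_habitat = NA_character_) {
    n <- length(phage_id)
    rec <- DataFrame(
        phage_id = as.character(phage_id),
        genome_length = as.integer(genome_length),
        database = rep_len(as.character(database), n),
        host_genus = rep_len(as.character(host_genus), n),
        morphology = rep_len(as.character(morphology), n),
        source_habitat = rep_len(as.character(source_habitat), n))
    new("PhageDb", records = rec)
}

#' Read phage databases from FASTA files
#'
#' Genome lengths are taken from the sequence lengths; sequences themselves
#' are not retained. Optional metadata (host genus, morphology, source
#' habitat) can be joined afterwards with [addPhageMetadata()].
#'
#' @param fastaFiles character vector of FASTA paths, named by database
#'   label; unnamed entries use the file base name.
#' @return a [PhageDb-class] covering all files.
#' @export
readPhageDb <- function(fastaFiles) {
    if (!length(fastaFiles))
        stop("no FASTA files given")
    labs <- names(fastaFiles)
    if (is.null(labs)) labs <- rep("", length(fastaFiles))
    blank <- !nzchar(labs)
    labs[blank] <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                       basename(fastaFiles[blank]))
    parts <- lapply(seq_along(fastaFiles), function(i) {
        f <- fastaFiles[[i]]
        if (!file.exists(f))
            stop("FASTA file not found: ", f)
        len <- fasta.seqlengths(f)
        ids <- sub("\\s.*$", "", names(len))
        PhageDb(ids, as.integer(len), labs[[i]])@records
    })
    new("PhageDb", records = do.call(rbind, parts))
}

#' Read a phage metadata table
#'
#' Tab-separated with header; required columns `database` and `phage_id`,
#' optional `host_genus`, `morphology`, `source_habitat`.
#'
#' @param path file path.
#' @return a data.frame keyed by (database, phage_id).
#' @export
readPhageMetadata <- function(path) {
    if (!file.exists(path))
        stop("metadata file not found: ", path)
    m <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
    need <- c("database", "phage_id")
    miss <- setdiff(need, colnames(m))
    if (length(miss))
        stop("metadata lacks columns: ", paste(miss, collapse = ", "))
    for (col in c("host_genus", "morphology", "source_habitat"))
        if (!col %in% colnames(m)) m[[col]] <- NA_character_
    m
}

#' Join metadata onto a phage database
#'
#' @param db a [PhageDb-class].
#' @param metadata a data.frame as returned by [readPhageMetadata()].
#' @return `db` with host_genus / morphology / source_habitat filled where
#'   the metadata has a matching (database, phage_id) row.
#' @export
addPhageMetadata <- function(db, metadata) {
    rec <- db@records
    key <- paste(rec$database, rec$phage_id, sep = "\r")
    mkey <- paste(metadata$database, metadata$phage_id, sep = "\r")
    idx <- match(key, mkey)
    hit <- !is.na(idx)
    for (col in c("host_genus", "morphology", "source_habitat")) {
        v <- as.character(metadata[[col]][idx[hit]])
        rec[[col]][hit] <- ifelse(is.na(v) | !nzchar(v),
                                  rec[[col]][hit], v)
    }
    new("PhageDb", records = rec)
}

#' @describeIn PhageDb-class phage identifiers (optionally one database)
#' @param x a `PhageDb`.
#' @param database restrict to one database label (default all).
#' @export
setMethod("phageIds", "PhageDb", function(x, database = NULL) {
    rec <- x@records
    if (!is.null(database)) rec <- rec[rec$database %in% database, ]
    rec$phage_id
})

#' @describeIn PhageDb-class genome lengths named `database::phage_id`
#' @export
setMethod("genomeLengths", "PhageDb", function(x) {
    rec <- x@records
    setNames(rec$genome_length, paste(rec$database, rec$phage_id, sep = "::"))
})

#' @describeIn PhageDb-class sequence counts per database, plus the total
#' @export
setMethod("dbCensus", "PhageDb", function(x) {
    rec <- x@records
    tab <- table(rec$database)
    out <- data.frame(database = names(tab),
                      n_sequences = as.integer(tab),
                      stringsAsFactors = FALSE)
    attr(out, "total") <- sum(out$n_sequences)
    out
})

setMethod("show", "PhageDb", function(object) {
    cen <- dbCensus(object)
    cat("PhageDb with", attr(cen, "total"), "sequences in",
        nrow(cen), "database(s)\n")
    for (i in seq_len(nrow(cen)))
        cat(sprintf("  %s: %d\n", cen$database[i], cen$n_sequences[i]))
})

#' @export
setMethod("length", "PhageDb", function(x) nrow(x@records))

#' @export
as.data.frame.PhageDb <- function(x, ...) as.data.frame(x@records)

#' Rename database sequences to a sequential numbering scheme
#'
#' The i-th sequence (in file order) becomes `<prefix>_<i>`; lengths and
#' content are unchanged. This mirrors the conventional renaming applied to
#' database FASTA files (e.g. `GVD_1, GVD_2, ...`) so identifiers are
#' pipeline-safe.
#'
#' @param x an [Biostrings::XStringSet] or a character vector of names.
#' @param prefix non-empty string.
#' @return the input with names replaced.
#' @examples
#' s <- Biostrings::DNAStringSet(c("ACGT", "GGCC", "TTAA"))
#' names(renameDatabaseSequences(s, "GVD"))
#' @export
setMethod("renameDatabaseSequences", "XStringSet", function(x, prefix) {
    names(x) <- renameDatabaseSequences(as.character(seq_along(x)), prefix)
    x
})

#' @rdname renameDatabaseSequences-XStringSet-method
#' @export
setMethod("renameDatabaseSequences", "character", function(x, prefix) {
    if (!is.character(prefix) || length(prefix) != 1L || !nzchar(prefix))
        stop("prefix must be a non-empty string")
    paste0(prefix, "_", seq_along(x))
})

#' Read a tabular alignment hit table
#'
#' Parses the 12-column tab-separated alignment format (query id, subject
#' id, percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score). Reverse-strand hits
#' (subject start > subject end) are normalised to `subject_start <=
#' subject_end` with the original orientation kept in a `strand` column.
#' Rows with more than 12 columns raise one warning and the extras are
#' dropped; rows with fewer, or with unparseable numeric fields, raise an
#' error naming the line.
#'
#' @param path file path.
#' @param database database label attached to every hit.
#' @return a data.frame with columns `read_id`, `phage_id`, `database`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `evalue`,
#'   `bitscore`, `strand`.
#' @seealso [writeHitTable()]
#' @export
readHitTable <- function(path, database) {
    if (!file.exists(path))
        stop("hit table not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(emptyHitTable(database))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L))
        stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                     which(nf < 12L)[1L], nf[which(nf < 12L)[1L]]))
    if (any(nf > 12L)) {
        warning(sprintf("%d row(s) carry more than 12 columns; extras ignored",
                        sum(nf > 12L)))
        fields <- lapply(fields, `[`, 1:12)
    }
    m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
    num <- function(col, what) {
        v <- suppressWarnings(as.numeric(m[, col]))
        bad <- which(is.na(v) & !is.na(m[, col]))
        if (length(bad))
            stop(sprintf("line %d: cannot parse %s value '%s'",
                         bad[1L], what, m[bad[1L], col]))
        v
    }
    sstart <- num(9L, "subject start")
    send <- num(10L, "subject end")
    data.frame(
        read_id = m[, 1L],
        phage_id = m[, 2L],
        database = database,
        percent_identity = num(3L, "percent identity"),
        align_length = as.integer(num(4L, "alignment length")),
        mismatches = as.integer(num(5L, "mismatches")),
        gap_opens = as.integer(num(6L, "gap opens")),
        query_start = as.integer(num(7L, "query start")),
        query_end = as.integer(num(8L, "query end")),
        subject_start = as.integer(pmin(sstart, send)),
        subject_end = as.integer(pmax(sstart, send)),
        evalue = num(11L, "e-value"),
        bitscore = num(12L, "bit score"),
        strand = ifelse(sstart <= send, "+", "-"),
        stringsAsFactors = FALSE)
}

emptyHitTable <- function(database = character(0)) {
    data.frame(read_id = character(0), phage_id = character(0),
               database = character(0), percent_identity = numeric(0),
               align_length = integer(0), mismatches = integer(0),
               gap_opens = integer(0), query_start = integer(0),
               query_end = integer(0), subject_start = integer(0),
               subject_end = integer(0), evalue = numeric(0),
               bitscore = numeric(0), strand = character(0),
               stringsAsFactors = FALSE)
}

#' Write a hit table back to the 12-column tabular format
#'
#' Reverse-strand hits are written with their original subject orientation
#' (start > end), so `readHitTable()` followed by `writeHitTable()` is a
#' field-identical round trip.
#'
#' @param hits a data.frame as returned by [readHitTable()].
#' @param path output path.
#' @export
writeHitTable <- function(hits, path) {
    rev <- hits$strand == "-"
    s1 <- ifelse(rev, hits$subject_end, hits$subject_start)
    s2 <- ifelse(rev, hits$subject_start, hits$subject_end)
    out <- data.frame(hits$read_id, hits$phage_id,
                      formatC(hits$percent_identity, format = "g"),
                      hits$align_length, hits$mismatches, hits$gap_opens,
                      hits$query_start, hits$query_end, s1, s2,
                      formatC(hits$evalue, format = "g"),
                      formatC(hits$bitscore, format = "g"))
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Construct a sample sheet
#'
#' @param sample_id,cohort,role,dyad_id character vectors (role must be
#'   `"maternal"` or `"fetal"`).
#' @param preeclampsia,term,chorioamnionitis tri-state condition flags
#'   (`TRUE`/`FALSE`/`NA`).
#' @param excluded logical; excluded samples take part in no statistic.
#' @return a [SampleSheet-class].
#' @export
SampleSheet <- function(sample_id, cohort, role, dyad_id,
                        preeclampsia = NA, term = NA,
                        chorioamnionitis = NA, excluded = FALSE) {
    n <- length(sample_id)
    s <- DataFrame(
        sample_id = as.character(sample_id),
        cohort = rep_len(as.character(cohort), n),
        role = rep_len(as.character(role), n),
        dyad_id = rep_len(as.character(dyad_id), n),
        preeclampsia = rep_len(as.logical(preeclampsia), n),
        term = rep_len(as.logical(term), n),
        chorioamnionitis = rep_len(as.logical(chorioamnionitis), n),
        excluded = rep_len(as.logical(excluded), n))
    new("SampleSheet", samples = s)
}

parseTriState <- function(v) {
    if (is.logical(v)) return(v)
    v <- tolower(trimws(as.character(v)))
    out <- rep(NA, length(v))
    out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
    out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
    out
}

#' Read a sample sheet from CSV or TSV
#'
#' The header must provide `sample_id`, `cohort`, `role`, `dyad_id`.
#' Condition columns (`preeclampsia`, `term`, `chorioamnionitis`) are
#' optional and default to unknown (`NA`); `excluded` defaults to `FALSE`.
#' The separator is taken from the extension (`.csv` = comma, otherwise
#' tab). Duplicate sample IDs, or a dyad with two samples of the same role,
#' are validation errors.
#'
#' @param path file path.
#' @return a [SampleSheet-class].
#' @export
readSampleSheet <- function(path) {
    if (!file.exists(path))
        stop("sample sheet not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    s <- read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "")
    need <- c("sample_id", "cohort", "role", "dyad_id")
    miss <- setdiff(need, colnames(s))
    if (length(miss))
        stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
    get3 <- function(col) {
        if (col %in% colnames(s)) parseTriState(s[[col]]) else NA
    }
    excl <- if ("excluded" %in% colnames(s)) parseTriState(s$excluded) else FALSE
    excl[is.na(excl)] <- FALSE
    sheet <- SampleSheet(s$sample_id, s$cohort, s$role, s$dyad_id,
                         preeclampsia = get3("preeclampsia"),
                         term = get3("term"),
                         chorioamnionitis = get3("chorioamnionitis"),
                         excluded = excl)
    incomplete <- incompleteDyads(sheet)
    if (length(incomplete))
        message("incomplete dyad(s): ", paste(incomplete, collapse = ", "))
    sheet
}

#' @describeIn SampleSheet-class sample identifiers
#' @param x a `SampleSheet`.
#' @export
setMethod("sampleIds", "SampleSheet", function(x) x@samples$sample_id)

#' @describeIn SampleSheet-class drop excluded samples
#' @export
setMethod("activeSamples", "SampleSheet", function(x) {
    new("SampleSheet", samples = x@samples[!x@samples$excluded, ])
})

#' @describeIn SampleSheet-class complete dyads among non-excluded samples:
#'   one row per dyad with its maternal and fetal sample IDs
#' @export
setMethod("dyadTable", "SampleSheet", function(x) {
    s <- as.data.frame(activeSamples(x)@samples)
    s <- s[!is.na(s$dyad_id) & nzchar(s$dyad_id), ]
    mat <- s[s$role == "maternal", ]
    fet <- s[s$role == "fetal", ]
    key <- function(d) paste(d$cohort, d$dyad_id, sep = "\r")
    common <- intersect(key(mat), key(fet))
    mi <- match(common, key(mat)); fi <- match(common, key(fet))
    data.frame(cohort = mat$cohort[mi], dyad_id = mat$dyad_id[mi],
               maternal_id = mat$sample_id[mi],
               fetal_id = fet$sample_id[fi],
               stringsAsFactors = FALSE)
})

incompleteDyads <- function(x) {
    s <- as.data.frame(activeSamples(x)@samples)
    s <- s[!is.na(s$dyad_id) & nzchar(s$dyad_id), ]
    tab <- table(paste(s$cohort, s$dyad_id, sep = "/"))
    names(tab)[tab < 2L]
}

setMethod("show", "SampleSheet", function(object) {
    s <- object@samples
    cat("SampleSheet:", nrow(s), "sample(s),",
        nrow(dyadTable(object)), "complete dyad(s),",
        sum(s$excluded), "excluded\n")
})

#' @export
setMethod("length", "SampleSheet", function(x) nrow(x@samples))

#' @export
as.data.frame.SampleSheet <- function(x, ...) as.data.frame(x@samples)

#' Write a result table as TSV
#'
#' Fixed, documented column order (the data.frame's own order); tab
#' separated with a header, no quoting, `NA` written as empty.
#'
#' @param x a data.frame.
#' @param path output path.
#' @export
writeResultTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE, na = "")
    invisible(path)
}
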