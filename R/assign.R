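## E-value filtering and greedy resolution of multimapping reads.

#' Assignment configuration
#'
#' @param evalueMax keep hits with e-value strictly below this (default
#'   5e-4, matching the upstream search's significance cutoff).
#' @param cullingLimit documented upstream cap on hits per read per
#'   database (default 20); validated, not enforced.
#' @param perDatabase resolve multimapping per database (default `TRUE`);
#'   a read may then hold one assignment per database.
#' @param tally rank phages by `"unique"` (reads mapping only to that
#'   phage; the default) or `"total"` (all mapping reads) during greedy
#'   resolution.
#' @param dynamicTally if `TRUE`, tallies are recomputed each round over
#'   the reads still in play; the default (`FALSE`) fixes the ranking
#'   pool before iteration. With `tally = "unique"` the two coincide (a
#'   winning phage absorbs every contested read it holds and leaves the
#'   competition), so the switch only changes `"total"` rankings.
#' @return a list of class `assignmentConfig`.
#' @export
assignmentConfig <- function(evalueMax = 5e-4, cullingLimit = 20L,
                             perDatabase = TRUE,
                             tally = c("unique", "total"),
                             dynamicTally = FALSE) {
    tally <- match.arg(tally)
    stopifnot(evalueMax > 0, cullingLimit >= 1L)
    structure(list(evalueMax = evalueMax,
                   cullingLimit = as.integer(cullingLimit),
                   perDatabase = isTRUE(perDatabase),
                   tally = tally,
                   dynamicTally = isTRUE(dynamicTally)),
              class = "assignmentConfig")
}

#' Filter alignment hits by e-value
#'
#' Retains exactly the hits with e-value strictly below
#' `config$evalueMax` ("below", not "at or below": a hit at the threshold
#' is removed).
#'
#' @param hits a hit data.frame (see [readHitTable()]).
#' @param config an [assignmentConfig()].
#' @return the retained rows.
#' @export
filterHits <- function(hits, config = assignmentConfig()) {
    hits[hits$evalue < config$evalueMax, , drop = FALSE]
}

#' Resolve multimapping reads to a single phage
#'
#' Reads with passing hits to more than one phage within a database are
#' assigned to exactly one by an iterative greedy procedure. Reads hitting
#' a single phage are assigned there first; the number of such reads per
#' phage is its unique-mapping-read tally. Then, repeatedly, the phage with
#' the highest tally among those still holding unresolved multimapping
#' reads absorbs all of its unresolved reads; those reads leave every other
#' phage's pool; the process repeats until no unresolved reads remain.
#' Ties are broken by higher total mapping-read count, then lexicographic
#' phage ID, so the output is deterministic and independent of row order.
#'
#' @param hits filtered hits for a single sample and (when
#'   `config$perDatabase`) a single database.
#' @param config an [assignmentConfig()]; `tally` and `dynamicTally`
#'   select the ranking variant.
#' @return a data.frame with one row per distinct read: `read_id`,
#'   `database`, `phage_id` (the assignment), `hits_considered` (number of
#'   distinct phages the read hit).
#' @export
resolveMultimappers <- function(hits, config = assignmentConfig()) {
    if (!nrow(hits))
        return(data.frame(read_id = character(0), database = character(0),
                          phage_id = character(0),
                          hits_considered = integer(0),
                          stringsAsFactors = FALSE))
    dbs <- unique(hits$database)
    if (config$perDatabase && length(dbs) > 1L)
        stop("hits span ", length(dbs),
             " databases; resolve per database (see assignReads)")
    pairs <- unique(hits[, c("read_id", "phage_id")])
    byRead <- split(pairs$phage_id, pairs$read_id)
    nHits <- lengths(byRead)
    reads <- names(byRead)

    totalTally <- table(pairs$phage_id)
    singly <- reads[nHits == 1L]
    uniqueTally <- table(unlist(byRead[singly], use.names = FALSE))
    tallyOf <- function(tab, ph) {
        v <- as.integer(tab[ph]); v[is.na(v)] <- 0L; v
    }

    assignment <- setNames(vapply(byRead, `[`, "", 1L), reads)
    assignment[nHits > 1L] <- NA_character_

    pool <- reads[nHits > 1L]
    baseTally <- if (config$tally == "unique") uniqueTally else totalTally
    ## dynamicTally recomputes each round over reads still in play (the
    ## pool plus a phage's own assignments). With tally = "unique" this is
    ## provably identical to the static default -- a winning phage absorbs
    ## every contested read it holds and leaves the competition -- so the
    ## switch only changes behaviour with tally = "total".
    while (length(pool)) {
        cand <- unique(unlist(byRead[pool], use.names = FALSE))
        if (config$dynamicTally && config$tally == "total") {
            a <- assignment[pairs$read_id]
            inPlay <- pairs$read_id %in% pool |
                (!is.na(a) & a == pairs$phage_id)
            score <- tallyOf(table(pairs$phage_id[inPlay]), cand)
        } else {
            score <- tallyOf(baseTally, cand)
        }
        tot <- tallyOf(totalTally, cand)
        ord <- order(-score, -tot, cand)
        winner <- cand[ord[1L]]
        takes <- pool[vapply(byRead[pool],
                             function(p) winner %in% p, logical(1))]
        assignment[takes] <- winner
        pool <- setdiff(pool, takes)
    }

    data.frame(read_id = reads,
               database = if (length(dbs)) dbs[1L] else NA_character_,
               phage_id = unname(assignment),
               hits_considered = as.integer(nHits),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter and resolve hits across samples and databases
#'
#' Convenience wrapper: applies [filterHits()], then
#' [resolveMultimappers()] within each (sample, database) group.
#'
#' @param hits a hit data.frame carrying a `sample_id` column (and
#'   `database`, as from [readHitTable()]).
#' @param config an [assignmentConfig()].
#' @return a data.frame of read assignments with a `sample_id` column.
#' @export
assignReads <- function(hits, config = assignmentConfig()) {
    if (!"sample_id" %in% colnames(hits))
        stop("hits must carry a sample_id column")
    hits <- filterHits(hits, config)
    if (!nrow(hits))
        return(data.frame(sample_id = character(0), read_id = character(0),
                          database = character(0), phage_id = character(0),
                          hits_considered = integer(0),
                          stringsAsFactors = FALSE))
    grp <- paste(hits$sample_id, hits$database, sep = "\r")
    parts <- lapply(split(seq_len(nrow(hits)), grp), function(i) {
        res <- resolveMultimappers(hits[i, , drop = FALSE], config)
        res$sample_id <- hits$sample_id[i[1L]]
        res
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out[, c("sample_id", "read_id", "database", "phage_id",
            "hits_considered")]
}

#' Restrict hits to their resolved assignment
#'
#' Keeps only the hit rows joining a read to the phage it was assigned to,
#' annotated with the sample. These are the alignments that feed
#' unique-read counting and coverage.
#'
#' @param hits filtered hits with a `sample_id` column.
#' @param assignments output of [assignReads()].
#' @return the matching hit rows.
#' @export
assignedHits <- function(hits, assignments) {
    hkey <- paste(hits$sample_id, hits$database, hits$read_id,
                  hits$phage_id, sep = "\r")
    akey <- paste(assignments$sample_id, assignments$database,
                  assignments$read_id, assignments$phage_id, sep = "\r")
    hits[hkey %in% akey, , drop = FALSE]
}
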