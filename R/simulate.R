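## Synthetic cohort simulator: phage databases, dyad-structured sample
## sheets, per-sample alignment hit tables and a ground-truth manifest.

#' Simulation configuration
#'
#' Defaults emulate a small maternal/cord cfDNA cohort: 75-bp single-end
#' reads from 50-200 bp cell-free fragments, paired maternal/fetal samples
#' with dyad-shared phages, ubiquitous contaminant phages and
#' below-threshold noise phages. One phage per database is reserved as a
#' multimapping "trap": it receives only secondary hits from multimapping
#' reads and no unique reads, so correct greedy resolution must leave it
#' uncalled.
#'
#' @param seed master seed; each component (genomes, membership,
#'   positions, e-values, decoys) draws from a sub-seed derived from it.
#' @param nDyads number of maternal-fetal dyads (samples = 2 * nDyads).
#' @param nDatabases number of phage databases; 5 uses the labels CPD,
#'   GPD, GVD, ELGV, MGV.
#' @param phagesPerDb phages per database (one of which is the trap).
#' @param genomeLengthRange phage genome length range in bp.
#' @param readLength read length in bp (default 75).
#' @param fragmentLengthRange cfDNA fragment length range in bp (default
#'   50-200); alignments span `min(readLength, fragment)` bp.
#' @param readsPerTruePhage integer range for reads planted per
#'   above-threshold (sample, phage).
#' @param sharedFraction probability a dyad phage is planted in both dyad
#'   members rather than one.
#' @param phagesPerDyad phages planted per dyad (drawn from a shared pool,
#'   so phages recur across dyads).
#' @param contaminantPhages phages planted above threshold in every
#'   sample.
#' @param noisePhages phages planted below threshold (alternately too few
#'   unique reads, or reads clustered under the coverage minimum) in one
#'   sample each.
#' @param multimapFraction fraction of each planted phage's reads that
#'   also hit the database's trap phage (always leaving at least one
#'   uniquely mapping read).
#' @param junkHitsPerSample decoy hit rows per sample with e-value at or
#'   above 5e-4, which the e-value filter must remove.
#' @param jitterStarts jitter planted read starts (keeping them distinct)
#'   to stress interval-union coverage.
#' @param cohort cohort label.
#' @return a validated list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L, nDyads = 10L, nDatabases = 5L,
                      phagesPerDb = 20L,
                      genomeLengthRange = c(2000L, 20000L),
                      readLength = 75L,
                      fragmentLengthRange = c(50L, 200L),
                      readsPerTruePhage = c(10L, 25L),
                      sharedFraction = 0.5, phagesPerDyad = 6L,
                      contaminantPhages = 0L, noisePhages = 0L,
                      multimapFraction = 0.2, junkHitsPerSample = 5L,
                      jitterStarts = FALSE, cohort = "SIM") {
    cfg <- list(seed = as.integer(seed), nDyads = as.integer(nDyads),
                nDatabases = as.integer(nDatabases),
                phagesPerDb = as.integer(phagesPerDb),
                genomeLengthRange = as.integer(genomeLengthRange),
                readLength = as.integer(readLength),
                fragmentLengthRange = as.integer(fragmentLengthRange),
                readsPerTruePhage = as.integer(readsPerTruePhage),
                sharedFraction = sharedFraction,
                phagesPerDyad = as.integer(phagesPerDyad),
                contaminantPhages = as.integer(contaminantPhages),
                noisePhages = as.integer(noisePhages),
                multimapFraction = multimapFraction,
                junkHitsPerSample = as.integer(junkHitsPerSample),
                jitterStarts = isTRUE(jitterStarts),
                cohort = as.character(cohort))
    stopifnot(cfg$nDyads >= 1L, cfg$nDatabases >= 1L, cfg$phagesPerDb >= 2L,
              cfg$readLength >= 1L,
              cfg$sharedFraction >= 0, cfg$sharedFraction <= 1,
              cfg$multimapFraction >= 0, cfg$multimapFraction <= 1,
              cfg$phagesPerDyad >= 0L, cfg$contaminantPhages >= 0L,
              cfg$noisePhages >= 0L)
    if (cfg$readLength > max(cfg$fragmentLengthRange))
        stop("readLength exceeds the maximum fragment length")
    if (max(cfg$readsPerTruePhage) * cfg$readLength >
        min(cfg$genomeLengthRange))
        stop("infeasible config: planted coverage would exceed the ",
             "shortest genome")
    pool <- cfg$nDatabases * (cfg$phagesPerDb - 1L)
    if (cfg$contaminantPhages + cfg$noisePhages + cfg$phagesPerDyad > pool)
        stop("infeasible config: not enough phages for contaminants, ",
             "noise and dyad planting")
    structure(cfg, class = "simConfig")
}

dbLabels <- function(n) {
    if (n == 5L) c("CPD", "GPD", "GVD", "ELGV", "MGV")
    else paste0("DB", seq_len(n))
}

subSeed <- function(seed, k) (seed * 11L + k * 7919L) %% 2147483647L

## Plant k reads on one phage. mode "spread": starts spaced one read
## length apart (target breadth achieved exactly, before fragment-length
## truncation); mode "cluster": starts packed into a 450-bp window so the
## union stays below the 500-bp default minimum.
plantReads <- function(k, genomeLength, cfg, mode = "spread") {
    rl <- cfg$readLength
    if (mode == "spread") {
        span <- k * rl
        off <- sample.int(genomeLength - span + 1L, 1L)
        starts <- off + (seq_len(k) - 1L) * rl
        if (cfg$jitterStarts && k > 1L) {
            starts <- starts + sample.int(rl, k, replace = TRUE) - 1L
            starts <- pmin(starts, genomeLength - rl + 1L)
            while (anyDuplicated(starts))
                starts[duplicated(starts)] <- starts[duplicated(starts)] - 1L
        }
    } else {
        span <- 450L
        off <- sample.int(genomeLength - span + 1L, 1L)
        step <- (span - rl) %/% max(k - 1L, 1L)
        starts <- off + (seq_len(k) - 1L) * step
    }
    frag <- sample(seq(cfg$fragmentLengthRange[1L],
                       cfg$fragmentLengthRange[2L]), k, replace = TRUE)
    alen <- pmin(rl, frag)
    data.frame(subject_start = as.integer(starts),
               subject_end = as.integer(starts + alen - 1L),
               align_length = as.integer(alen),
               fragment_length = as.integer(frag),
               strand = ifelse(runif(k) < 0.3, "-", "+"),
               stringsAsFactors = FALSE)
}

#' Simulate a synthetic maternal-infant cfDNA cohort
#'
#' Generates phage databases (record table with genome lengths and partial
#' host/morphology metadata), a dyad-structured sample sheet with
#' condition flags, per-sample alignment hit tables in the 12-column
#' dialect, and a ground-truth manifest recording what was planted where.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @return a list of class `phageCohortSim` with elements `config`, `db`
#'   ([PhageDb-class]), `sheet` ([SampleSheet-class]), `hits` (one
#'   data.frame over all samples, `sample_id` column included) and
#'   `manifest` (one row per planted (sample, database, phage) with
#'   planted read/unique-read counts, planted coverage and the expected
#'   call flag under the default thresholds; `N` and `D` as attributes).
#' @export
simulateCohort <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "simConfig"))
    labs <- dbLabels(cfg$nDatabases)

    ## -- genomes & metadata stream ------------------------------------
    set.seed(subSeed(cfg$seed, 1L))
    rec <- do.call(rbind, lapply(labs, function(db) {
        ids <- renameDatabaseSequences(character(cfg$phagesPerDb), db)
        data.frame(phage_id = ids,
                   genome_length = sample(
                       seq(cfg$genomeLengthRange[1L],
                           cfg$genomeLengthRange[2L]),
                       cfg$phagesPerDb, replace = TRUE),
                   database = db, stringsAsFactors = FALSE)
    }))
    genusPool <- c(habitatGenusLists()$gut, habitatGenusLists()$vagina,
                   habitatGenusLists()$nonHuman)
    hasGenus <- runif(nrow(rec)) < 0.3
    genus <- ifelse(hasGenus, sample(genusPool, nrow(rec), replace = TRUE),
                    NA_character_)
    morph <- ifelse(runif(nrow(rec)) < 0.2,
                    sample(c("siphoviridae", "myoviridae", "podoviridae"),
                           nrow(rec), replace = TRUE), NA_character_)
    habitat <- ifelse(rec$database %in% habitatGenusLists()$gutDatabases,
                      "gut", NA_character_)
    db <- PhageDb(rec$phage_id, rec$genome_length, rec$database,
                  host_genus = genus, morphology = morph,
                  source_habitat = habitat)

    ## trap phage = last of each database; usable pool = the rest
    trap <- setNames(paste0(labs, "_", cfg$phagesPerDb), labs)
    poolKey <- paste(rec$database, rec$phage_id, sep = "::")
    poolKey <- poolKey[!rec$phage_id %in% trap]

    ## -- sample sheet & membership stream ------------------------------
    set.seed(subSeed(cfg$seed, 2L))
    dyads <- sprintf("D%02d", seq_len(cfg$nDyads))
    sheet <- SampleSheet(
        sample_id = c(sprintf("M%02d", seq_len(cfg$nDyads)),
                      sprintf("F%02d", seq_len(cfg$nDyads))),
        cohort = cfg$cohort,
        role = rep(c("maternal", "fetal"), each = cfg$nDyads),
        dyad_id = rep(dyads, 2L),
        preeclampsia = rep(runif(cfg$nDyads) < 0.3, 2L),
        term = rep(runif(cfg$nDyads) < 0.7, 2L),
        chorioamnionitis = rep(runif(cfg$nDyads) < 0.2, 2L))
    sdf <- as.data.frame(sheet)

    drawK <- function(n) sample(seq(cfg$readsPerTruePhage[1L],
                                    cfg$readsPerTruePhage[2L]),
                                n, replace = TRUE)
    pool <- sample(poolKey)  # shuffled; carve roles off the front
    take <- function(n) {
        out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out
    }
    contam <- if (cfg$contaminantPhages) take(cfg$contaminantPhages) else character(0)
    noise <- if (cfg$noisePhages) take(cfg$noisePhages) else character(0)

    memb <- list()
    addRow <- function(sample, key, kind, k) {
        memb[[length(memb) + 1L]] <<- data.frame(
            sample_id = sample, key = key, kind = kind, k = k,
            stringsAsFactors = FALSE)
    }
    for (key in contam)
        for (sm in sdf$sample_id) addRow(sm, key, "contaminant", drawK(1L))
    for (i in seq_along(noise)) {
        sm <- sample(sdf$sample_id, 1L)
        if (i %% 2L == 1L) addRow(sm, noise[i], "noise_reads", 9L)
        else addRow(sm, noise[i], "noise_coverage", 12L)
    }
    if (cfg$phagesPerDyad > 0L) {
        dyadPool <- pool
        for (d in seq_len(cfg$nDyads)) {
            keys <- sample(dyadPool, cfg$phagesPerDyad)
            m <- sdf$sample_id[sdf$dyad_id == dyads[d] & sdf$role == "maternal"]
            f <- sdf$sample_id[sdf$dyad_id == dyads[d] & sdf$role == "fetal"]
            for (key in keys) {
                if (runif(1L) < cfg$sharedFraction) {
                    addRow(m, key, "dyad_shared", drawK(1L))
                    addRow(f, key, "dyad_shared", drawK(1L))
                } else {
                    addRow(sample(c(m, f), 1L), key, "dyad_single", drawK(1L))
                }
            }
        }
    }
    memb <- if (length(memb)) do.call(rbind, memb) else
        data.frame(sample_id = character(0), key = character(0),
                   kind = character(0), k = integer(0),
                   stringsAsFactors = FALSE)
    ## the same phage may be drawn for several dyads and land twice on one
    ## sample; keep the first planting
    memb <- memb[!duplicated(paste(memb$sample_id, memb$key)), , drop = FALSE]

    ## -- read planting stream ------------------------------------------
    set.seed(subSeed(cfg$seed, 3L))
    glen <- genomeLengths(db)
    readCounter <- setNames(rep(0L, nrow(sdf)), sdf$sample_id)
    hitParts <- vector("list", nrow(memb))
    manifest <- memb
    manifest$database <- sub("::.*$", "", memb$key)
    manifest$phage_id <- sub("^.*::", "", memb$key)
    manifest$planted_coverage_bp <- rep(0L, nrow(memb))
    ord <- order(memb$sample_id, memb$key)
    for (i in ord) {
        key <- memb$key[i]; k <- memb$k[i]
        mode <- if (memb$kind[i] == "noise_coverage") "cluster" else "spread"
        plant <- plantReads(k, glen[[key]], cfg, mode)
        sm <- memb$sample_id[i]
        rid <- sprintf("%s_R%06d", sm, readCounter[[sm]] + seq_len(k))
        readCounter[[sm]] <- readCounter[[sm]] + k
        manifest$planted_coverage_bp[i] <- sum(width(reduce(
            IRanges(plant$subject_start, plant$subject_end))))
        hitParts[[i]] <- data.frame(
            sample_id = sm, read_id = rid,
            phage_id = manifest$phage_id[i],
            database = manifest$database[i],
            plant[, c("subject_start", "subject_end", "align_length",
                      "fragment_length", "strand")],
            multimap = seq_len(k) > k - floor(cfg$multimapFraction * k),
            stringsAsFactors = FALSE)
    }
    hits <- if (length(hitParts)) do.call(rbind, hitParts) else NULL

    ## secondary hits to the trap phage for multimapping reads
    trapParts <- NULL
    if (!is.null(hits) && any(hits$multimap)) {
        mm <- hits[hits$multimap, , drop = FALSE]
        tlen <- glen[paste(mm$database, trap[mm$database], sep = "::")]
        tstart <- vapply(tlen - cfg$readLength + 1L,
                         function(m) sample.int(m, 1L), 1L)
        trapParts <- data.frame(
            sample_id = mm$sample_id, read_id = mm$read_id,
            phage_id = unname(trap[mm$database]), database = mm$database,
            subject_start = as.integer(tstart),
            subject_end = as.integer(tstart + mm$align_length - 1L),
            align_length = mm$align_length,
            fragment_length = mm$fragment_length,
            strand = mm$strand, multimap = TRUE,
            stringsAsFactors = FALSE)
    }
    hits <- rbind(hits, trapParts)

    ## -- e-value / score stream ----------------------------------------
    finishHits <- function(h, passing) {
        if (is.null(h) || !nrow(h)) return(emptySimHits())
        n <- nrow(h)
        h$percent_identity <- round(runif(n, 90, 100), 2)
        h$mismatches <- as.integer(round((100 - h$percent_identity) / 100 *
                                         h$align_length))
        h$gap_opens <- 0L
        h$query_start <- 1L
        h$query_end <- h$align_length
        h$evalue <- if (passing) 10^runif(n, -30, log10(4.9e-4))
                    else 10^runif(n, log10(5e-4), -1)
        h$bitscore <- round(runif(n, 100, 150), 1)
        h
    }
    set.seed(subSeed(cfg$seed, 4L))
    hits <- finishHits(hits, passing = TRUE)

    ## -- junk (filter-failing) hits ------------------------------------
    set.seed(subSeed(cfg$seed, 5L))
    junk <- NULL
    if (cfg$junkHitsPerSample > 0L) {
        junk <- do.call(rbind, lapply(sdf$sample_id, function(sm) {
            keys <- sample(names(glen), cfg$junkHitsPerSample, replace = TRUE)
            st <- vapply(glen[keys] - cfg$readLength + 1L,
                         function(m) sample.int(m, 1L), 1L)
            data.frame(sample_id = sm,
                       read_id = sprintf("%s_J%03d", sm,
                                         seq_len(cfg$junkHitsPerSample)),
                       phage_id = sub("^.*::", "", keys),
                       database = sub("::.*$", "", keys),
                       subject_start = as.integer(st),
                       subject_end = as.integer(st + cfg$readLength - 1L),
                       align_length = cfg$readLength,
                       fragment_length = cfg$readLength,
                       strand = "+", multimap = FALSE,
                       stringsAsFactors = FALSE)
        }))
        junk <- finishHits(junk, passing = FALSE)
    }
    hits <- rbind(hits, junk)
    rownames(hits) <- NULL

    manifest$planted_reads <- manifest$k
    manifest$planted_unique_reads <- manifest$k
    defaults <- callingConfig()
    manifest$expect_called <-
        manifest$planted_unique_reads >= defaults$minUniqueReads &
        manifest$planted_coverage_bp >= defaults$minCoverageBp
    manifest <- manifest[, c("sample_id", "database", "phage_id", "kind",
                             "planted_reads", "planted_unique_reads",
                             "planted_coverage_bp", "expect_called")]
    rownames(manifest) <- NULL
    attr(manifest, "N") <- nrow(sdf)
    attr(manifest, "D") <- cfg$nDyads

    structure(list(config = cfg, db = db, sheet = sheet, hits = hits,
                   manifest = manifest, trapPhages = trap),
              class = "phageCohortSim")
}

emptySimHits <- function() {
    cbind(data.frame(sample_id = character(0)),
          emptyHitTable(),
          data.frame(fragment_length = integer(0), multimap = logical(0)))
}

#' Plant phages present in exactly two samples
#'
#' Amends a simulated cohort with `nPairs` new phages, each planted above
#' threshold in exactly two samples; exactly `nDyadPairs` of those sample
#' pairs are maternal-infant dyads and the rest are non-dyad pairs. Used
#' to exercise the exactly-two-samples enrichment analysis with known
#' truth.
#'
#' @param sim a `phageCohortSim` (base cohort; for a clean two-sample
#'   analysis simulate it with `phagesPerDyad = 0`).
#' @param nPairs number of two-sample phages to plant.
#' @param nDyadPairs how many land on dyads (`<= nPairs`, `<=` number of
#'   dyads).
#' @return the amended sim; the planted pair truth is attached as
#'   `sim$plantedPairs` (`phage`, `sample_1`, `sample_2`, `is_dyad`).
#' @export
plantTwoSamplePhages <- function(sim, nPairs, nDyadPairs) {
    stopifnot(inherits(sim, "phageCohortSim"),
              nDyadPairs <= nPairs)
    cfg <- sim$config
    dy <- dyadTable(sim$sheet)
    if (nDyadPairs > nrow(dy))
        stop("more dyad pairs requested than dyads available")
    sdf <- as.data.frame(sim$sheet)
    if (nPairs - nDyadPairs > choose(nrow(sdf), 2L) - nrow(dy))
        stop("not enough non-dyad sample pairs")

    set.seed(subSeed(cfg$seed, 6L))
    labs <- dbLabels(cfg$nDatabases)
    dyKey <- paste(pmin(dy$maternal_id, dy$fetal_id),
                   pmax(dy$maternal_id, dy$fetal_id), sep = "\r")
    pickDyads <- sample(seq_len(nrow(dy)), nDyadPairs)
    pairs <- data.frame(sample_1 = dy$maternal_id[pickDyads],
                        sample_2 = dy$fetal_id[pickDyads],
                        is_dyad = rep(TRUE, nDyadPairs),
                        stringsAsFactors = FALSE)
    used <- character(0)
    while (nrow(pairs) < nPairs) {
        sm <- sample(sdf$sample_id, 2L)
        key <- paste(min(sm), max(sm), sep = "\r")
        if (key %in% dyKey || key %in% used) next
        used <- c(used, key)
        pairs <- rbind(pairs, data.frame(sample_1 = sm[1L],
                                         sample_2 = sm[2L],
                                         is_dyad = FALSE,
                                         stringsAsFactors = FALSE))
    }

    rec <- as.data.frame(sim$db@records)
    nextIdx <- setNames(vapply(labs, function(d)
        sum(rec$database == d), 1L) + 1L, labs)
    newRec <- manRows <- hitRows <- list()
    glenRange <- seq(cfg$genomeLengthRange[1L], cfg$genomeLengthRange[2L])
    counter <- table(sim$hits$sample_id)
    nextRead <- setNames(rep(0L, nrow(sdf)), sdf$sample_id)
    nextRead[names(counter)] <- as.integer(counter)
    for (i in seq_len(nPairs)) {
        dbl <- labs[((i - 1L) %% length(labs)) + 1L]
        pid <- paste0(dbl, "_", nextIdx[[dbl]])
        nextIdx[[dbl]] <- nextIdx[[dbl]] + 1L
        gl <- sample(glenRange, 1L)
        newRec[[i]] <- data.frame(phage_id = pid, genome_length = gl,
                                  database = dbl, stringsAsFactors = FALSE)
        for (sm in c(pairs$sample_1[i], pairs$sample_2[i])) {
            k <- sample(seq(cfg$readsPerTruePhage[1L],
                            cfg$readsPerTruePhage[2L]), 1L)
            plant <- plantReads(k, gl, cfg, "spread")
            rid <- sprintf("%s_R%06d", sm, nextRead[[sm]] + seq_len(k))
            nextRead[[sm]] <- nextRead[[sm]] + k
            cov <- sum(width(reduce(IRanges(plant$subject_start,
                                            plant$subject_end))))
            manRows[[length(manRows) + 1L]] <- data.frame(
                sample_id = sm, database = dbl, phage_id = pid,
                kind = "pair", planted_reads = k,
                planted_unique_reads = k, planted_coverage_bp = cov,
                expect_called = TRUE, stringsAsFactors = FALSE)
            h <- data.frame(sample_id = sm, read_id = rid, phage_id = pid,
                            database = dbl,
                            plant[, c("subject_start", "subject_end",
                                      "align_length", "fragment_length",
                                      "strand")],
                            multimap = FALSE, stringsAsFactors = FALSE)
            n <- nrow(h)
            h$percent_identity <- round(runif(n, 90, 100), 2)
            h$mismatches <- as.integer(round((100 - h$percent_identity) /
                                             100 * h$align_length))
            h$gap_opens <- 0L
            h$query_start <- 1L
            h$query_end <- h$align_length
            h$evalue <- 10^runif(n, -30, log10(4.9e-4))
            h$bitscore <- round(runif(n, 100, 150), 1)
            hitRows[[length(hitRows) + 1L]] <- h
        }
    }
    newRec <- do.call(rbind, newRec)
    sim$db <- PhageDb(c(rec$phage_id, newRec$phage_id),
                      c(rec$genome_length, newRec$genome_length),
                      c(rec$database, newRec$database),
                      host_genus = c(rec$host_genus,
                                     rep(NA_character_, nrow(newRec))),
                      morphology = c(rec$morphology,
                                     rep(NA_character_, nrow(newRec))),
                      source_habitat = c(rec$source_habitat,
                                         rep(NA_character_, nrow(newRec))))
    sim$hits <- rbind(sim$hits, do.call(rbind, hitRows))
    rownames(sim$hits) <- NULL
    newMan <- do.call(rbind, manRows)
    man <- rbind(sim$manifest, newMan)
    attr(man, "N") <- attr(sim$manifest, "N")
    attr(man, "D") <- attr(sim$manifest, "D")
    sim$manifest <- man
    pairs$phage <- paste(newRec$database, newRec$phage_id, sep = "::")
    sim$plantedPairs <- pairs[, c("phage", "sample_1", "sample_2", "is_dyad")]
    sim
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the artifact formats the readers consume: one hit table
#' per (sample, database) named `<sample>__<database>.tsv`, the sample
#' sheet as `samples.csv`, database metadata as `metadata.tsv`, and one
#' FASTA per database with random sequence content of the recorded
#' lengths.
#'
#' @param sim a `phageCohortSim`.
#' @param dir output directory (created if needed).
#' @param fasta also write FASTA files (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir, fasta = TRUE) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sdf <- as.data.frame(sim$sheet)
    utils::write.csv(sdf, file.path(dir, "samples.csv"), row.names = FALSE)
    rec <- as.data.frame(sim$db@records)
    writeResultTable(rec[, c("database", "phage_id", "host_genus",
                             "morphology", "source_habitat")],
                     file.path(dir, "metadata.tsv"))
    for (sm in sdf$sample_id) {
        for (dbl in unique(rec$database)) {
            sub <- sim$hits[sim$hits$sample_id == sm &
                            sim$hits$database == dbl, , drop = FALSE]
            writeHitTable(sub, file.path(dir,
                                         paste0(sm, "__", dbl, ".tsv")))
        }
    }
    if (fasta) {
        set.seed(subSeed(sim$config$seed, 7L))
        for (dbl in unique(rec$database)) {
            sub <- rec[rec$database == dbl, ]
            seqs <- DNAStringSet(vapply(sub$genome_length, function(L)
                paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = ""), ""))
            names(seqs) <- sub$phage_id
            writeXStringSet(seqs, file.path(dir, paste0(dbl, ".fasta")))
        }
    }
    invisible(dir)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir directory path.
#' @param fasta read genome lengths from the FASTA files (default) rather
#'   than trusting `metadata.tsv` alone.
#' @return a list with `db`, `sheet` and `hits` in the in-memory layout
#'   of [simulateCohort()].
#' @export
readCohort <- function(dir, fasta = TRUE) {
    sheet <- readSampleSheet(file.path(dir, "samples.csv"))
    meta <- readPhageMetadata(file.path(dir, "metadata.tsv"))
    dbs <- unique(meta$database)
    if (fasta) {
        files <- setNames(file.path(dir, paste0(dbs, ".fasta")), dbs)
        db <- addPhageMetadata(readPhageDb(files), meta)
    } else stop("metadata.tsv carries no genome lengths; FASTA required")
    parts <- list()
    for (sm in sampleIds(sheet)) {
        for (dbl in dbs) {
            f <- file.path(dir, paste0(sm, "__", dbl, ".tsv"))
            if (!file.exists(f)) next
            h <- readHitTable(f, dbl)
            if (nrow(h)) h$sample_id <- sm
            else h$sample_id <- character(0)
            parts[[length(parts) + 1L]] <- h
        }
    }
    hits <- do.call(rbind, parts)
    rownames(hits) <- NULL
    list(db = db, sheet = sheet, hits = hits)
}
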