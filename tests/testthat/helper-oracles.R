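# Independent oracles, deliberately naive and coded straight from the
# procedure definitions rather than sharing any code with the package.

# Greedy multimapper resolution, literal transcription: tallies of
# uniquely mapping reads are fixed up front; each round the phage holding
# unresolved multimapping reads with the highest tally (ties: more total
# mapping reads, then alphabetically first) absorbs its reads.
oracleResolve <- function(pairs) {
  pairs <- unique(pairs[, c("read_id", "phage_id")])
  assignment <- list()
  reads <- unique(pairs$read_id)
  phagesOf <- function(r) pairs$phage_id[pairs$read_id == r]
  uniqueTally <- c()
  totalTally <- c()
  for (ph in unique(pairs$phage_id)) {
    rs <- pairs$read_id[pairs$phage_id == ph]
    uniqueTally[ph] <- sum(vapply(rs, function(r) length(phagesOf(r)) == 1, NA))
    totalTally[ph] <- length(rs)
  }
  for (r in reads)
    if (length(phagesOf(r)) == 1) assignment[[r]] <- phagesOf(r)
  pool <- reads[vapply(reads, function(r) length(phagesOf(r)) > 1, NA)]
  while (length(pool) > 0) {
    cands <- sort(unique(unlist(lapply(pool, phagesOf))))
    best <- cands[1]
    for (ph in cands) {
      if (uniqueTally[ph] > uniqueTally[best]) best <- ph
      else if (uniqueTally[ph] == uniqueTally[best] &&
               totalTally[ph] > totalTally[best]) best <- ph
    }
    taken <- pool[vapply(pool, function(r) best %in% phagesOf(r), NA)]
    for (r in taken) assignment[[r]] <- best
    pool <- setdiff(pool, taken)
  }
  out <- data.frame(read_id = names(assignment),
                    phage_id = unlist(assignment),
                    stringsAsFactors = FALSE)
  out[order(out$read_id), ]
}

# Breadth of coverage by marking positions off a genome-length vector.
oracleCoverage <- function(starts, ends, genomeLength) {
  covered <- rep(FALSE, genomeLength)
  for (i in seq_along(starts)) {
    a <- min(starts[i], ends[i]); b <- max(starts[i], ends[i])
    covered[a:b] <- TRUE
  }
  sum(covered)
}

# Random multimapping instance: hit rows over <= nPhages phages and
# <= nReads reads, single sample and database.
randomInstance <- function(nPhages, nReads) {
  phages <- paste0("P", seq_len(sample(nPhages, 1)))
  reads <- paste0("R", seq_len(sample(nReads, 1)))
  rows <- lapply(reads, function(r) {
    k <- sample(length(phages), 1)
    data.frame(read_id = r, phage_id = sample(phages, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$database <- "SIMDB"
  out$evalue <- 1e-10
  out
}

# Hit rows for a single (sample, phage): distinct read IDs, arbitrary
# subject intervals.
makeHits <- function(starts, ends, readIds = NULL, evalue = 1e-10,
                     database = "DB", phage = "P1", sample = "S1") {
  n <- length(starts)
  if (is.null(readIds)) readIds <- sprintf("r%03d", seq_len(n))
  data.frame(sample_id = rep_len(sample, n), read_id = readIds,
             phage_id = rep_len(phage, n),
             database = rep_len(database, n),
             percent_identity = rep_len(98, n),
             align_length = abs(ends - starts) + 1L,
             mismatches = rep_len(0L, n), gap_opens = rep_len(0L, n),
             query_start = rep_len(1L, n),
             query_end = abs(ends - starts) + 1L,
             subject_start = as.integer(pmin(starts, ends)),
             subject_end = as.integer(pmax(starts, ends)),
             evalue = rep_len(evalue, n), bitscore = rep_len(140, n),
             strand = ifelse(starts <= ends, "+", "-"),
             stringsAsFactors = FALSE)
}

# Hit rows with exactly nReads distinct reads/start sites whose interval
# union spans exactly covBp (contiguous block from position 1).
fixtureCallHits <- function(nReads, covBp, ...) {
  starts <- round(seq(1, covBp, length.out = nReads + 1L))[seq_len(nReads)]
  ends <- c(starts[-1L] - 1L + 10L, covBp)  # overlap neighbours, end at covBp
  ends <- pmin(ends, covBp)
  makeHits(as.integer(starts), as.integer(ends), ...)
}
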