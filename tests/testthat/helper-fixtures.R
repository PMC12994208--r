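# fixtures are built in code: count tables, metadata and alignments are
# tiny and constructed per test

makeSE <- function(counts, ranks = "genus", native = TRUE, metadata = NULL,
                   dropEmpty = FALSE) {
  taxonomy <- data.frame(taxon = rownames(counts), rank = ranks,
                         native_europe = native)
  SedimentExperiment(counts, taxonomy = taxonomy, metadata = metadata,
                     dropEmpty = dropEmpty)
}

countMatrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

# alignment rows (named character vector of equal-length strings) -> object
makeAlignment <- function(rows, ancient = "ancient", minGapRun = 5L) {
  ConcatAlignment(Biostrings::DNAStringSet(rows), ancient, minGapRun)
}

# independent per-column enumeration of exclusively shared SNPs, used as
# the brute-force oracle against cladeSupportCounts()
bruteForceCladeCounts <- function(aln) {
  m <- alignmentMatrix(aln)
  anc <- ancientName(aln)
  refs <- setdiff(rownames(m), anc)
  counts <- setNames(integer(length(refs)), refs)
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(ncol(m))) {
    a <- m[anc, j]
    if (!a %in% bases) next
    st <- m[refs, j]
    covered <- st %in% bases
    if (length(unique(c(a, st[covered]))) < 2) next
    sharers <- refs[covered & st == a]
    if (length(sharers) == 1) counts[sharers] <- counts[sharers] + 1L
  }
  counts
}

# dense-grid Riemann oracle for the Beta overlap coefficient
riemannBetaOverlap <- function(c1, t1, c2, t2, n = 200001) {
  g <- seq(1e-7, 1 - 1e-7, length.out = n)
  f1 <- dbeta(g, 1 + c1, t1 - c1 + 1)
  f2 <- dbeta(g, 1 + c2, t2 - c2 + 1)
  sum(pmin(f1, f2)) * (g[2] - g[1])
}
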