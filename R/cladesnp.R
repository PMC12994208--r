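#' Construct / read a gap-concatenated alignment
#'
#' @param alignment a [Biostrings::DNAStringSet] of equal-width named rows
#'   (for `ConcatAlignment`) or a FASTA path (for `readConcatAlignment`).
#' @param ancient name of the ancient (sedaDNA consensus) row.
#' @param minGapRun gap-run length separating ancient read blocks (5).
#' @return a [ConcatAlignment-class].
#' @export
ConcatAlignment <- function(alignment, ancient, minGapRun = 5L) {
  if (is.character(alignment))
    alignment <- Biostrings::DNAStringSet(alignment)
  methods::new("ConcatAlignment", alignment = alignment,
               ancient = ancient, minGapRun = as.integer(minGapRun))
}

#' @rdname ConcatAlignment
#' @param file FASTA path.
#' @export
readConcatAlignment <- function(file, ancient, minGapRun = 5L) {
  ConcatAlignment(Biostrings::readDNAStringSet(file), ancient, minGapRun)
}

#' Write an alignment (e.g. after masking) as FASTA
#' @param x a [ConcatAlignment-class].
#' @param file output path.
#' @export
writeConcatAlignment <- function(x, file) {
  Biostrings::writeXStringSet(x@alignment, file)
  invisible(file)
}

#' Ancient read blocks of a concatenated alignment
#'
#' Reads of the ancient row were concatenated with runs of `minGapRun`
#' (five) or more gaps between them; those runs (and any leading/trailing
#' gaps) delimit the read blocks.  Shorter internal gap runs stay inside a
#' block.
#'
#' @param x a [ConcatAlignment-class].
#' @return data.frame with 1-based inclusive `start`, `end` per block.
#' @export
ancientReadBlocks <- function(x) {
  ch <- alignmentMatrix(x)[ancientName(x), ]
  n <- length(ch)
  isGap <- ch == "-"
  r <- rle(isGap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sep <- r$values & (r$lengths >= x@minGapRun | starts == 1L | ends == n)
  blocks <- NULL
  open <- NA_integer_
  for (k in seq_along(r$lengths)) {
    if (sep[k]) {
      if (!is.na(open))
        blocks <- rbind(blocks, c(open, starts[k] - 1L))
      open <- NA_integer_
    } else if (is.na(open)) open <- starts[k]
  }
  if (!is.na(open)) blocks <- rbind(blocks, c(open, n))
  if (is.null(blocks))
    return(data.frame(start = integer(0), end = integer(0)))
  out <- data.frame(start = blocks[, 1], end = blocks[, 2])
  ## blocks never open or close on a gap run by construction, but a short
  ## gap run can sit flush against a separator at the sequence edge
  out[out$end >= out$start, , drop = FALSE]
}

.BASES <- c("A", "C", "G", "T")
.isTransition <- function(a, b)
  (a == "C" & b == "T") | (a == "T" & b == "C") |
  (a == "G" & b == "A") | (a == "A" & b == "G")

#' SNP sites of a concatenated alignment
#'
#' A SNP site is an alignment column where the ancient row is covered
#' (A/C/G/T; gaps and N are missing) and at least two distinct states
#' occur among the covered rows.  Each site is annotated with the set of
#' reference taxa sharing the ancient state, whether the ancient state is
#' a singleton (shared by no reference), and whether it differs from the
#' plurality reference state by a transition (C<->T / G<->A, the changes
#' confounded with cytosine-deamination damage).  Plurality ties leave
#' `plurality_state` (and hence `is_transition`) `NA`.
#'
#' @param x a [ConcatAlignment-class].
#' @return data.frame (one row per site): `position` (1-based),
#'   `ancient_state`, `sharing` (comma-separated taxa), `n_sharing`,
#'   `is_singleton`, `plurality_state`, `is_transition`; reference taxon
#'   names attached as attribute `"refTaxa"`.
#' @export
findSnpSites <- function(x) {
  m <- alignmentMatrix(x)
  anc <- ancientName(x)
  refs <- setdiff(rownames(m), anc)
  a <- m[anc, ]
  R <- m[refs, , drop = FALSE]
  ancCovered <- a %in% .BASES

  rows <- lapply(which(ancCovered), function(j) {
    st <- R[, j]
    covered <- st %in% .BASES
    states <- unique(c(a[j], st[covered]))
    if (length(states) < 2) return(NULL)
    sharers <- refs[covered & st == a[j]]
    tab <- table(st[covered])
    plural <- NA_character_
    if (length(tab)) {
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1) plural <- top
    }
    data.frame(position = j, ancient_state = a[j],
               sharing = paste(sharers, collapse = ","),
               n_sharing = length(sharers),
               is_singleton = length(sharers) == 0,
               plurality_state = plural,
               is_transition = if (is.na(plural)) NA
                 else a[j] != plural && .isTransition(a[j], plural))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(0), ancient_state = character(0),
                      sharing = character(0), n_sharing = integer(0),
                      is_singleton = logical(0),
                      plurality_state = character(0),
                      is_transition = logical(0))
  attr(out, "refTaxa") <- refs
  out
}

#' Exclusively-shared SNP counts per reference taxon
#'
#' For each reference taxon, the number of SNP sites whose sharing set is
#' exactly that taxon — sites where the ancient sequence and that taxon
#' alone carry the same state, the clade-support currency of the analysis.
#'
#' @param sites output of [findSnpSites()].
#' @param taxa reference taxon names (defaults to the `"refTaxa"`
#'   attribute of `sites`).
#' @return named integer vector of counts (zeros included).
#' @export
cladeSupportCounts <- function(sites, taxa = attr(sites, "refTaxa")) {
  if (is.null(taxa)) stop("reference taxa unknown; pass `taxa`")
  excl <- sites[sites$n_sharing == 1, , drop = FALSE]
  tab <- table(factor(excl$sharing, levels = taxa))
  setNames(as.integer(tab), taxa)
}

#' Damage/quality filter chain for the ancient row
#'
#' Applies, in order: (1) clipping — `clip` bases masked at each end of
#' every ancient read block, removing terminal deamination artefacts
#' (blocks of length <= 2 * clip are wholly masked, with a message);
#' (2) singleton masking — sites whose ancient state is shared by no
#' reference are candidate base modifications; (3) transition masking —
#' sites where the ancient state differs from the plurality reference
#' state by C<->T / G<->A (plurality ties masked, conservatively);
#' (4) optionally, completeness — sites where any reference row is gap/N.
#' Masking writes N into the ancient row, so masked columns cease to be
#' SNP sites.
#'
#' @param x a [ConcatAlignment-class].
#' @param clip bases masked from each block end (5); 0 disables.
#' @param dropSingletons,dropTransitions,requireComplete stage switches.
#' @return a masked [ConcatAlignment-class].
#' @export
filterAlignment <- function(x, clip = 5, dropSingletons = TRUE,
                            dropTransitions = TRUE,
                            requireComplete = FALSE) {
  m <- alignmentMatrix(x)
  anc <- ancientName(x)
  refs <- setdiff(rownames(m), anc)
  mask <- function(pos) if (length(pos)) m[anc, pos] <<- "N"

  if (clip > 0) {
    blocks <- ancientReadBlocks(x)
    for (b in seq_len(nrow(blocks))) {
      s <- blocks$start[b]; e <- blocks$end[b]
      if (e - s + 1 <= 2 * clip) {
        message("read block ", s, "-", e, " shorter than 2 * clip; ",
                "fully masked")
        mask(s:e)
      } else mask(c(s:(s + clip - 1), (e - clip + 1):e))
    }
  }
  rebuild <- function() {
    seqs <- Biostrings::DNAStringSet(apply(m, 1, paste, collapse = ""))
    names(seqs) <- rownames(m)
    ConcatAlignment(seqs, anc, x@minGapRun)
  }
  if (dropSingletons) {
    sites <- findSnpSites(rebuild())
    mask(sites$position[sites$is_singleton])
  }
  if (dropTransitions) {
    sites <- findSnpSites(rebuild())
    mask(sites$position[is.na(sites$is_transition) | sites$is_transition])
  }
  if (requireComplete) {
    covered <- m[anc, ] %in% .BASES
    refCov <- matrix(m[refs, , drop = FALSE] %in% .BASES,
                     nrow = length(refs))
    incomplete <- colSums(!refCov) > 0
    mask(which(covered & incomplete))
  }
  rebuild()
}

#' Per-stage clade-support report
#'
#' Convenience wrapper reporting exclusive-share counts at each stage of
#' the filter chain: raw, clipped, clipped + singletons removed,
#' + transitions removed, + complete-data only.
#'
#' @param x a [ConcatAlignment-class].
#' @param clip see [filterAlignment()].
#' @return data.frame of counts, one row per reference taxon, one column
#'   per stage.
#' @export
cladeSupportByStage <- function(x, clip = 5) {
  stages <- list(
    raw = x,
    clipped = filterAlignment(x, clip = clip, dropSingletons = FALSE,
                              dropTransitions = FALSE),
    no_singletons = filterAlignment(x, clip = clip,
                                    dropTransitions = FALSE),
    no_transitions = filterAlignment(x, clip = clip),
    complete_only = filterAlignment(x, clip = clip, requireComplete = TRUE))
  counts <- lapply(stages, function(a) cladeSupportCounts(findSnpSites(a)))
  as.data.frame(counts)
}
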