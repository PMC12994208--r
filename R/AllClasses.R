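#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor cmdscale dbeta pbeta dist kmeans uniroot
#'   pbinom rmultinom runif rgamma rnorm setNames median sd
#' @importFrom utils read.delim write.table
NULL

#' Container for a sedaDNA taxon-by-sample read-count table
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one `counts` assay (taxa in rows, samples in columns).  Row metadata
#' carries the taxonomic record for each taxon (`rank`, `native_europe`);
#' column metadata carries the sample record (core id, depth, sediment
#' class, laminated flag, calibrated age, security label, domain).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("SedimentExperiment", contains = "SummarizedExperiment")

.RANKS <- c("class", "order", "family", "tribe", "genus", "other")
.SEDIMENTS <- c("clay", "silt", "fine_sand", "medium_sand", "coarse_sand",
                "other")
.SECURITY <- c("secure", "insecure", "unknown")
.DOMAINS <- c("marine", "terrestrial", "unknown")

setValidity("SedimentExperiment", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    x <- SummarizedExperiment::assay(object, "counts")
    if (any(x < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(x != round(x))) msg <- c(msg, "counts must be integers")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon names must be unique")
  rd <- SummarizedExperiment::rowData(object)
  if ("rank" %in% colnames(rd) && !all(rd$rank %in% .RANKS))
    msg <- c(msg, sprintf("rank must be one of: %s",
                          paste(.RANKS, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' A set of co-occurrence plant guilds over a fixed taxon list
#'
#' Produced by [hypercubeCluster()] and annotated by [classifyGuildType()].
#' Each taxon belongs to at most one guild; taxa in no guild (singletons at
#' clustering time, or excluded for zero variance) have membership `NA` and
#' are tallied in the `unassigned` bucket of downstream guild profiles.
#'
#' @slot membership named integer vector, one element per taxon; `NA` means
#'   unassigned.
#' @slot guildType named character vector over guild ids: `"simple"` when
#'   every member pair is significantly associated, else `"complex"`;
#'   `NA` until [classifyGuildType()] has run.
#' @slot anchor named character vector over guild ids; for complex guilds,
#'   the member with the most significant pairings; `NA` for simple guilds.
#' @export
setClass("GuildSet",
  representation(membership = "integer",
                 guildType = "character",
                 anchor = "character"))

setValidity("GuildSet", function(object) {
  msg <- NULL
  m <- object@membership
  if (is.null(names(m)) || anyDuplicated(names(m)))
    msg <- c(msg, "membership must be named by unique taxon")
  sz <- table(m[!is.na(m)])
  if (length(sz) && any(sz < 2))
    msg <- c(msg, "guilds must have at least 2 members")
  gt <- object@guildType
  if (length(gt) && !all(is.na(gt) | gt %in% c("simple", "complex")))
    msg <- c(msg, "guildType must be 'simple' or 'complex'")
  if (length(gt) && length(object@anchor)) {
    simple <- !is.na(gt) & gt == "simple"
    if (any(simple & !is.na(object@anchor[names(gt)])))
      msg <- c(msg, "simple guilds carry no anchor")
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-sample guild proportion profiles
#'
#' Rows are samples, columns guilds; `unassigned` holds the read fraction
#' of taxa outside every guild so that each row plus its unassigned
#' fraction sums to one.  Guild distances (the paper-field's profile
#' distance, a Euclidean norm over guild coordinates) are computed by
#' [guildDistance()] / [guildDistanceMatrix()].
#'
#' @slot proportions numeric matrix, samples x guilds, entries in [0, 1].
#' @slot unassigned named numeric vector, one entry per sample.
#' @export
setClass("GuildProfileMatrix",
  representation(proportions = "matrix", unassigned = "numeric"))

setValidity("GuildProfileMatrix", function(object) {
  p <- object@proportions
  u <- object@unassigned
  msg <- NULL
  if (any(p < -1e-9) || any(p > 1 + 1e-9))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (length(u) != nrow(p))
    msg <- c(msg, "one unassigned fraction per sample is required")
  else if (any(abs(rowSums(p) + u - 1) > 1e-6))
    msg <- c(msg, "guild proportions plus unassigned must sum to 1")
  if (is.null(msg)) TRUE else msg
})

#' Result of fitting the sediment-influx depositional model
#'
#' Stores the best parameter combination found by [monteCarloFit()] for one
#' sediment type, together with the observed and predicted mean adjacent
#' pair guild distances and bookkeeping about the search.
#'
#' @slot sedimentType sediment class the fit refers to.
#' @slot params named numeric: `e1`, `e2` (rate modifiers in [-1, 1]),
#'   `cl` (local compositional proportion), `cs` (= 1 - cl), `dxloc`
#'   (local change), `id` (inter-sediment guild difference).
#' @slot fit non-negative fit score; 0 iff predictions match observations
#'   (including the ratio term).
#' @slot predicted,observed named numeric vectors with elements `d1`, `d2`.
#' @slot nChains,nEvaluations,seed search bookkeeping.
#' @slot eq7 which algebraic reading of the sediment-influx term was used
#'   (`"fraction"` or `"product"`).
#' @slot ratioOmitted logical; `TRUE` when the ratio term of the fit score
#'   was dropped because a denominator was zero.
#' @export
setClass("DepositionFit",
  representation(sedimentType = "character", params = "numeric",
                 fit = "numeric", predicted = "numeric",
                 observed = "numeric", nChains = "integer",
                 nEvaluations = "numeric", seed = "integer",
                 eq7 = "character", ratioOmitted = "logical"))

setValidity("DepositionFit", function(object) {
  msg <- NULL
  need <- c("e1", "e2", "cl", "cs", "dxloc", "id")
  if (!all(need %in% names(object@params)))
    msg <- c(msg, sprintf("params must contain %s",
                          paste(need, collapse = ", ")))
  else {
    p <- object@params
    if (abs(p["cl"] + p["cs"] - 1) > 1e-9) msg <- c(msg, "cl + cs must be 1")
    if (p["cl"] < 0 || p["cl"] > 1) msg <- c(msg, "cl must lie in [0, 1]")
    if (any(abs(p[c("e1", "e2")]) > 1 + 1e-9))
      msg <- c(msg, "e1, e2 must lie in [-1, 1]")
  }
  if (length(object@fit) && object@fit < 0)
    msg <- c(msg, "fit must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Gap-concatenated multi-taxon alignment with one ancient row
#'
#' Wraps a [Biostrings::DNAStringSet] of equal-length aligned rows.  One
#' row is the ancient (sedaDNA) consensus built from reads concatenated
#' with runs of five or more gaps between them; those gap runs delimit the
#' ancient read blocks used by the damage-filter chain.
#'
#' @slot alignment `DNAStringSet` of equal-width rows.
#' @slot ancient name of the ancient row.
#' @slot minGapRun minimum gap-run length separating ancient read blocks.
#' @export
setClass("ConcatAlignment",
  representation(alignment = "ANY", ancient = "character",
                 minGapRun = "integer"))

setValidity("ConcatAlignment", function(object) {
  msg <- NULL
  aln <- object@alignment
  if (!methods::is(aln, "DNAStringSet"))
    msg <- c(msg, "alignment must be a DNAStringSet")
  else {
    if (length(unique(Biostrings::width(aln))) > 1)
      msg <- c(msg, "all rows must have equal length")
    if (is.null(names(aln)) || anyDuplicated(names(aln)))
      msg <- c(msg, "rows must carry unique names")
    if (!(object@ancient %in% names(aln)))
      msg <- c(msg, "ancient row not found in alignment")
  }
  if (is.null(msg)) TRUE else msg
})
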