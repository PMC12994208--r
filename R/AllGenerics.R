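#' Accessors for sedaTaph classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("guildMembership", function(x, ...) standardGeneric("guildMembership"))

#' @rdname accessors
#' @export
setGeneric("guildIds", function(x, ...) standardGeneric("guildIds"))

#' @rdname accessors
#' @export
setGeneric("guildType", function(x, ...) standardGeneric("guildType"))

#' @rdname accessors
#' @export
setGeneric("guildAnchor", function(x, ...) standardGeneric("guildAnchor"))

#' @rdname accessors
#' @export
setGeneric("guildProportions", function(x, ...) standardGeneric("guildProportions"))

#' @rdname accessors
#' @export
setGeneric("unassignedFraction", function(x, ...) standardGeneric("unassignedFraction"))

#' @rdname accessors
#' @export
setGeneric("fitScore", function(x, ...) standardGeneric("fitScore"))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(x, ...) standardGeneric("fitParams"))

#' @rdname accessors
#' @export
setGeneric("ancientName", function(x, ...) standardGeneric("ancientName"))

#' @rdname accessors
#' @export
setGeneric("alignmentMatrix", function(x, ...) standardGeneric("alignmentMatrix"))

## ---- GuildSet ----

#' @rdname accessors
#' @export
setMethod("guildMembership", "GuildSet", function(x, ...) x@membership)

#' @rdname accessors
#' @export
setMethod("guildIds", "GuildSet", function(x, ...)
  sort(unique(x@membership[!is.na(x@membership)])))

#' @rdname accessors
#' @export
setMethod("guildType", "GuildSet", function(x, ...) x@guildType)

#' @rdname accessors
#' @export
setMethod("guildAnchor", "GuildSet", function(x, ...) x@anchor)

setMethod("show", "GuildSet", function(object) {
  m <- object@membership
  ids <- sort(unique(m[!is.na(m)]))
  cat("GuildSet with", length(ids), "guilds over", length(m), "taxa\n")
  cat("  assigned taxa:", sum(!is.na(m)),
      " unassigned:", sum(is.na(m)), "\n")
  if (length(object@guildType) && !all(is.na(object@guildType)))
    cat("  types:", sum(object@guildType == "simple", na.rm = TRUE),
        "simple /", sum(object@guildType == "complex", na.rm = TRUE),
        "complex\n")
})

## ---- GuildProfileMatrix ----

#' @rdname accessors
#' @export
setMethod("guildProportions", "GuildProfileMatrix", function(x, ...)
  x@proportions)

#' @rdname accessors
#' @export
setMethod("unassignedFraction", "GuildProfileMatrix", function(x, ...)
  x@unassigned)

setMethod("show", "GuildProfileMatrix", function(object) {
  cat("GuildProfileMatrix:", nrow(object@proportions), "samples x",
      ncol(object@proportions), "guilds (+ unassigned)\n")
  cat("  mean unassigned fraction:",
      signif(mean(object@unassigned), 3), "\n")
})

## ---- DepositionFit ----

#' @rdname accessors
#' @export
setMethod("fitScore", "DepositionFit", function(x, ...) x@fit)

#' @rdname accessors
#' @export
setMethod("fitParams", "DepositionFit", function(x, ...) x@params)

setMethod("show", "DepositionFit", function(object) {
  cat("DepositionFit [", object@sedimentType, "]\n", sep = "")
  p <- signif(object@params, 4)
  cat("  cl =", p["cl"], " dxloc =", p["dxloc"], " id =", p["id"],
      " e1 =", p["e1"], " e2 =", p["e2"], "\n")
  cat("  fit =", signif(object@fit, 4),
      " predicted (d1, d2) = (", signif(object@predicted["d1"], 4), ",",
      signif(object@predicted["d2"], 4), ")",
      " observed = (", signif(object@observed["d1"], 4), ",",
      signif(object@observed["d2"], 4), ")\n")
  cat("  chains:", object@nChains, " grid evaluations:",
      format(object@nEvaluations, big.mark = ","), "\n")
})

## ---- ConcatAlignment ----

#' @rdname accessors
#' @export
setMethod("ancientName", "ConcatAlignment", function(x, ...) x@ancient)

#' @rdname accessors
#' @export
setMethod("alignmentMatrix", "ConcatAlignment", function(x, ...) {
  m <- t(vapply(as.character(x@alignment),
                function(s) strsplit(s, "", fixed = TRUE)[[1]],
                character(Biostrings::width(x@alignment)[1])))
  rownames(m) <- names(x@alignment)
  toupper(m)
})

setMethod("show", "ConcatAlignment", function(object) {
  cat("ConcatAlignment:", length(object@alignment), "rows x",
      Biostrings::width(object@alignment)[1], "columns\n")
  cat("  ancient row:", object@ancient, "\n")
  blocks <- ancientReadBlocks(object)
  cat("  ancient read blocks:", nrow(blocks), "\n")
})

setMethod("show", "SedimentExperiment", function(object) {
  methods::callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  if ("core_id" %in% colnames(cd))
    cat("cores:", length(unique(cd$core_id)), "\n")
})
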