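#' Simpson's index for one sample
#'
#' lambda_s = sum of squared read proportions; its reciprocal 1/lambda_s
#' is the effective number of taxa used as the diversity value.
#'
#' @param counts non-negative taxon count vector with positive total.
#' @return lambda_s, in [1/k, 1] for k observed taxa.
#' @examples
#' simpsonLambda(c(10, 30, 60))   # 0.46
#' @export
simpsonLambda <- function(counts) {
  tot <- sum(counts)
  if (length(counts) == 0 || tot <= 0) stop("sample has no reads")
  p <- counts / tot
  sum(p^2)
}

#' Marine vs terrestrial domain from a guild profile
#'
#' A sample is marine when the marine guild (in the original study, the
#' seagrass Zostera guild marking post-inundation conditions) has the
#' strictly largest proportion in its profile; otherwise terrestrial.
#'
#' @param profile named numeric vector of guild proportions.
#' @param marineGuild id (name) of the marine guild.
#' @return `"marine"` or `"terrestrial"`.
#' @export
classifyDomain <- function(profile, marineGuild) {
  marineGuild <- as.character(marineGuild)
  if (!marineGuild %in% names(profile))
    stop("marine guild ", marineGuild, " absent from profile")
  pm <- profile[[marineGuild]]
  others <- profile[setdiff(names(profile), marineGuild)]
  if (length(others) && pm > max(others)) "marine" else "terrestrial"
}

#' Sliding-window diversity time series
#'
#' Eligible samples are secure, carry a numeric age, and have total read
#' counts over `minReads`.  Windows of width `window` years are centred on
#' multiples of `step` spanning the eligible age range; a sample belongs
#' to a window when |age - centre| <= window / 2.  Within each window and
#' domain the mean of 1/lambda_s over member samples is reported; empty
#' windows are omitted.
#'
#' @param se a [SedimentExperiment-class] whose colData carries `age_calBP`
#'   and `security` (and optionally `domain`).
#' @param profiles optional [GuildProfileMatrix-class] used to compute the
#'   domain (via [classifyDomain()]) for samples whose metadata domain is
#'   missing or `"unknown"`; metadata wins when present.
#' @param marineGuild marine guild id for [classifyDomain()].
#' @param window window width in years (1000).
#' @param step step between window centres in years (500).
#' @param minReads strict lower bound on sample total reads (50).
#' @return data.frame: window_center_calBP, domain, mean_diversity,
#'   n_samples.
#' @export
diversitySeries <- function(se, profiles = NULL, marineGuild = NULL,
                            window = 1000, step = 500, minReads = 50) {
  md <- as.data.frame(SummarizedExperiment::colData(se))
  counts <- SummarizedExperiment::assay(se, "counts")
  tot <- colSums(counts)
  age <- md$age_calBP
  sec <- if ("security" %in% colnames(md)) md$security else "unknown"
  eligible <- !is.na(age) & sec == "secure" & tot > minReads
  if (!any(eligible)) return(data.frame())
  idx <- which(eligible)

  domain <- rep("unknown", ncol(se))
  if ("domain" %in% colnames(md))
    domain <- ifelse(is.na(md$domain), "unknown", md$domain)
  needs <- idx[domain[idx] == "unknown"]
  if (length(needs) && !is.null(profiles) && !is.null(marineGuild)) {
    p <- guildProportions(profiles)
    for (i in needs) {
      sid <- colnames(se)[i]
      if (sid %in% rownames(p))
        domain[i] <- classifyDomain(p[sid, ], marineGuild)
    }
  }

  div <- vapply(idx, function(i) 1 / simpsonLambda(counts[, i]), numeric(1))
  ages <- age[idx]
  doms <- domain[idx]
  centers <- seq(floor((min(ages) - window / 2) / step) * step,
                 ceiling((max(ages) + window / 2) / step) * step, by = step)
  out <- NULL
  for (ct in centers) {
    inWin <- abs(ages - ct) <= window / 2
    for (dm in unique(doms[inWin])) {
      sel <- inWin & doms == dm
      out <- rbind(out, data.frame(window_center_calBP = ct, domain = dm,
                                   mean_diversity = mean(div[sel]),
                                   n_samples = sum(sel)))
    }
  }
  out[order(out$window_center_calBP, out$domain), , drop = FALSE]
}
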