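#' Overlap of two Beta posteriors for a taxon's proportion
#'
#' Each observed (count, total) pair induces Beta(1 + count,
#' total - count + 1) — the posterior of the underlying proportion under a
#' uniform prior.  The overlap coefficient, the integral over [0, 1] of
#' the pointwise minimum of the two densities, serves as the probability
#' that both counts were drawn from a shared underlying proportion.  It is
#' computed exactly from incomplete-Beta differences after locating the
#' (at most two) density crossing points, to well within 1e-6.
#'
#' @param c1,t1 taxon count and sample total for sample 1.
#' @param c2,t2 taxon count and sample total for sample 2.
#' @return overlap in [0, 1]; 1 iff the parameter pairs coincide.
#' @export
betaOverlap <- function(c1, t1, c2, t2) {
  if (t1 <= 0 || t2 <= 0) stop("totals must be positive")
  if (c1 < 0 || c2 < 0 || c1 > t1 || c2 > t2)
    stop("counts must lie in [0, total]")
  a1 <- 1 + c1; b1 <- t1 - c1 + 1
  a2 <- 1 + c2; b2 <- t2 - c2 + 1
  if (a1 == a2 && b1 == b2) return(1)
  ## log density difference h(t) = log f1 - log f2 =
  ##   const + (a1-a2) log t + (b1-b2) log(1-t): at most two roots in (0,1)
  konst <- lbeta(a2, b2) - lbeta(a1, b1)
  h <- function(t) konst + (a1 - a2) * log(t) + (b1 - b2) * log1p(-t)
  eps <- 1e-12
  grid <- seq(eps, 1 - eps, length.out = 4001)
  hv <- h(grid)
  flip <- which(diff(sign(hv)) != 0)
  roots <- vapply(flip, function(i)
    uniroot(h, lower = grid[i], upper = grid[i + 1], tol = 1e-12)$root,
    numeric(1))
  cuts <- c(0, sort(unique(roots)), 1)
  total <- 0
  for (k in seq_len(length(cuts) - 1)) {
    lo <- cuts[k]; hi <- cuts[k + 1]
    mid <- (lo + hi) / 2
    if (h(mid) <= 0)  # f1 smaller on this piece
      total <- total + (pbeta(hi, a1, b1) - pbeta(lo, a1, b1))
    else
      total <- total + (pbeta(hi, a2, b2) - pbeta(lo, a2, b2))
  }
  min(1, max(0, total))
}

#' Stratification test between two adjacent samples
#'
#' Per taxon present in either sample, the Beta-overlap of its two
#' (count, total) observations is computed; the pair is called stratified
#' when at least one taxon's overlap falls below `alpha` — evidence that
#' compositions differ and post-depositional homogenisation has not
#' erased the stratigraphic signal.  Pairs whose summed read count is not
#' above `minPairReads` (50) are flagged not evaluable.
#'
#' @param s1,s2 named integer count vectors over a shared taxon list.
#' @param alpha significance level (0.05).
#' @param minPairReads minimum summed read count of the two samples.
#' @return list with `evaluable`, `stratified`, `overlap` (named per
#'   taxon), `minOverlapTaxon`.
#' @export
testStratified <- function(s1, s2, alpha = 0.05, minPairReads = 50) {
  taxa <- union(names(s1)[s1 > 0], names(s2)[s2 > 0])
  t1 <- sum(s1); t2 <- sum(s2)
  if (t1 + t2 <= minPairReads || length(taxa) == 0)
    return(list(evaluable = FALSE, stratified = NA,
                overlap = setNames(numeric(0), character(0)),
                minOverlapTaxon = NA_character_))
  ov <- vapply(taxa, function(tx)
    betaOverlap(ifelse(tx %in% names(s1), s1[[tx]], 0), t1,
                ifelse(tx %in% names(s2), s2[[tx]], 0), t2),
    numeric(1))
  names(ov) <- taxa
  list(evaluable = TRUE,
       stratified = any(ov < alpha),
       overlap = ov,
       minOverlapTaxon = taxa[which.min(ov)])
}

#' Diffusion decay rate for one taxon between two depths
#'
#' Under a one-parameter unidirectional approximation of diffusion through
#' a porous medium, a taxon observed at proportion p2 in the donor sample
#' and p1 at distance x cm away implies lambda = -log(p1 / p2) / x
#' (natural log).  With the donor taken as the larger proportion,
#' lambda >= 0; shallower curves (small lambda) mean more complete
#' diffusion.
#'
#' @param p1,p2 read-count proportions of the taxon in the two samples;
#'   p2 is the donor.  Zero proportions give `NA` (undefined).
#' @param x separation in cm, > 0.
#' @return lambda in 1/cm (vectorised).
#' @export
lambdaForTaxon <- function(p1, p2, x) {
  if (any(x <= 0)) stop("x must be positive")
  lam <- -log(p1 / p2) / x
  lam[p1 <= 0 | p2 <= 0] <- NA_real_
  lam
}

#' Universal diffusion rate from per-taxon estimates
#'
#' Per-taxon lambda values mix true environmental change with any shared
#' diffusion process; the highest-valued cluster of the distribution
#' bounds the fastest decay consistent with the data, so its mean is the
#' minimum possible universal lambda.  Values are clustered in 1-D by
#' k-means (on log lambda by default) with k chosen by the largest average
#' silhouette width over k in 2..kMax; k = 1 is used when no multi-cluster
#' solution attains positive silhouette or fewer than 3 distinct values
#' exist.
#'
#' @param lambdas numeric vector of per-taxon estimates (non-finite values
#'   dropped).
#' @param kMax largest number of clusters tried (5).
#' @param useLog cluster on log(lambda) (zeros kept aside and attached to
#'   the lowest cluster).
#' @return mean of the highest-valued cluster.
#' @export
estimateUniversalLambda <- function(lambdas, kMax = 5, useLog = TRUE) {
  x <- lambdas[is.finite(lambdas)]
  if (!length(x)) stop("no finite lambda values")
  if (length(unique(x)) == 1) return(x[1])
  pos <- x[x > 0]
  y <- if (useLog) log(pos) else pos
  if (length(unique(y)) < 3) return(mean(sort(x, decreasing = TRUE)[
    seq_len(sum(x == max(x)))]))
  best <- NULL; bestSil <- 0
  dmat <- dist(y)
  for (k in 2:min(kMax, length(unique(y)) - 1)) {
    km <- kmeans(y, centers = k, nstart = 10)
    sil <- cluster::silhouette(km$cluster, dmat)
    avg <- mean(sil[, "sil_width"])
    if (avg > bestSil) { bestSil <- avg; best <- km }
  }
  if (is.null(best)) return(mean(x))     # k = 1: one cluster, its mean
  topCluster <- which.max(tapply(pos, best$cluster, mean))
  mean(pos[best$cluster == as.integer(topCluster)])
}

#' Reads attributable to diffusion from a donor sample
#'
#' Applies the fitted decay rate: per taxon the expected diffused count in
#' sample 1 is C_diff = exp(-lambda x) * p2 * s1_total, where p2 is the
#' taxon's proportion in donor sample 2.  The summed C_diff as a
#' percentage of sample 1's total reads (capped at 100) bounds the
#' fraction of the signal explicable by diffusion alone.
#'
#' @param s1,s2 named count vectors (sample 1 = receiver, sample 2 =
#'   donor).
#' @param lambda decay rate, >= 0.
#' @param x separation in cm, > 0.
#' @return list with `cDiff` (named expected reads per donor taxon) and
#'   `percent`.
#' @export
diffusionFraction <- function(s1, s2, lambda, x) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (x <= 0) stop("x must be positive")
  t1 <- sum(s1)
  p2 <- s2 / sum(s2)
  cDiff <- exp(-lambda * x) * p2 * t1
  list(cDiff = cDiff,
       percent = min(100, 100 * sum(cDiff) / t1))
}

## consecutive-depth pairs within each core, as a data.frame of indices
.adjacentPairs <- function(metadata) {
  out <- NULL
  for (core in unique(metadata$core_id)) {
    rows <- which(metadata$core_id == core)
    rows <- rows[order(metadata$depth_cm[rows])]
    if (length(rows) < 2) {
      message("core ", core, " has fewer than 2 samples; skipped")
      next
    }
    out <- rbind(out, data.frame(i = rows[-length(rows)], j = rows[-1]))
  }
  out
}

#' Stratification scan over all adjacent pairs of a core set
#'
#' @param se a [SedimentExperiment-class] whose colData carries `core_id`
#'   and `depth_cm`.
#' @param alpha,minPairReads see [testStratified()].
#' @return data.frame: sample ids, core, x_cm, evaluable, stratified,
#'   min overlap and its taxon.
#' @export
stratifyCores <- function(se, alpha = 0.05, minPairReads = 50) {
  md <- as.data.frame(SummarizedExperiment::colData(se))
  md$sample_id <- colnames(se)
  counts <- SummarizedExperiment::assay(se, "counts")
  pairs <- .adjacentPairs(md)
  if (is.null(pairs)) return(data.frame())
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    st <- testStratified(counts[, i], counts[, j],
                         alpha = alpha, minPairReads = minPairReads)
    data.frame(sample1 = md$sample_id[i], sample2 = md$sample_id[j],
               core_id = md$core_id[i],
               x_cm = abs(md$depth_cm[j] - md$depth_cm[i]),
               evaluable = st$evaluable, stratified = st$stratified,
               min_overlap = if (length(st$overlap)) min(st$overlap) else NA,
               min_overlap_taxon = st$minOverlapTaxon)
  })
  do.call(rbind, res)
}

#' Diffusion scan over all adjacent pairs of a core set
#'
#' For each consecutive-depth pair with more than `minPairReads` summed
#' reads, per-taxon lambdas are estimated (donor = larger proportion), the
#' universal lambda taken as the mean of the highest cluster
#' ([estimateUniversalLambda()]), and the percentage of sample 1's reads
#' attributable to diffusion from sample 2 computed.
#'
#' @param se a [SedimentExperiment-class] with `core_id`/`depth_cm`.
#' @param minPairReads pair read-count threshold (50).
#' @param kMax,useLog passed to [estimateUniversalLambda()].
#' @return data.frame: sample ids, x_cm, n_taxa used, universal lambda,
#'   percent attributable.
#' @export
diffusionScan <- function(se, minPairReads = 50, kMax = 5, useLog = TRUE) {
  md <- as.data.frame(SummarizedExperiment::colData(se))
  md$sample_id <- colnames(se)
  counts <- SummarizedExperiment::assay(se, "counts")
  pairs <- .adjacentPairs(md)
  if (is.null(pairs)) return(data.frame())
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    s1 <- counts[, i]; s2 <- counts[, j]
    x <- abs(md$depth_cm[j] - md$depth_cm[i])
    if (sum(s1) + sum(s2) <= minPairReads || sum(s1) == 0 || sum(s2) == 0)
      return(data.frame(sample1 = md$sample_id[i], sample2 = md$sample_id[j],
                        x_cm = x, n_taxa = 0L, universal_lambda = NA,
                        percent_attributable = NA))
    p1 <- s1 / sum(s1); p2 <- s2 / sum(s2)
    both <- p1 > 0 & p2 > 0
    lam <- lambdaForTaxon(pmin(p1[both], p2[both]),
                          pmax(p1[both], p2[both]), x)
    lam <- lam[is.finite(lam)]
    if (!length(lam))
      return(data.frame(sample1 = md$sample_id[i], sample2 = md$sample_id[j],
                        x_cm = x, n_taxa = 0L, universal_lambda = NA,
                        percent_attributable = NA))
    uni <- estimateUniversalLambda(lam, kMax = kMax, useLog = useLog)
    pct <- diffusionFraction(s1, s2, uni, x)$percent
    data.frame(sample1 = md$sample_id[i], sample2 = md$sample_id[j],
               x_cm = x, n_taxa = length(lam), universal_lambda = uni,
               percent_attributable = pct)
  })
  do.call(rbind, res)
}
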