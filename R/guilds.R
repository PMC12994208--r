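#' Pairwise Pearson co-occurrence of taxa
#'
#' Correlates the per-sample relative frequencies (count / sample total) of
#' every taxon pair across all samples — the similarity measure behind
#' guild construction.  Taxa with zero variance across samples have
#' undefined correlations: their rows/columns are `NA`, they are reported
#' in the `"excluded"` attribute and skipped by downstream clustering.
#'
#' @param se a [SedimentExperiment-class] with at least 3 samples.
#' @return symmetric correlation matrix (taxa x taxa) with unit diagonal
#'   and an `"excluded"` attribute listing zero-variance taxa.
#' @export
pairwisePmcc <- function(se) {
  if (ncol(se) < 3) stop("need at least 3 samples to correlate taxa")
  f <- sampleFrequencies(se)                 # samples x taxa
  v <- apply(f, 2, stats::var)
  excluded <- colnames(f)[v == 0]
  if (length(excluded))
    message("excluding ", length(excluded),
            " zero-variance taxa from correlation: ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ...")
  cc <- suppressWarnings(cor(f))
  cc[excluded, ] <- NA
  cc[, excluded] <- NA
  diag(cc) <- 1
  attr(cc, "excluded") <- excluded
  cc
}

#' Correlation to co-occurrence distance
#'
#' Maps a correlation on [-1, 1] to a distance on [0, 1] via
#' d = 1 - (pmcc + 1) / 2, so perfect co-occurrence is distance 0 and
#' perfect avoidance distance 1.
#'
#' @param cc correlation matrix (or numeric vector).
#' @return distances of the same shape; diagonal forced to exactly 0 for
#'   matrices.
#' @export
corrToDistance <- function(cc) {
  d <- 1 - (cc + 1) / 2
  if (is.matrix(d)) diag(d) <- 0
  attr(d, "excluded") <- attr(cc, "excluded")
  d
}

#' Inverse of [corrToDistance()]
#' @param d distance matrix or vector on [0, 1].
#' @return correlations on [-1, 1].
#' @export
distanceToCorr <- function(d) 1 - 2 * d

#' Classical multidimensional scaling of the guild distance matrix
#'
#' Torgerson metric scaling: the squared-distance matrix is double
#' centered, eigendecomposed, and eigenvectors scaled by the square root
#' of their eigenvalues give taxon coordinates.  Dimensions are ordered by
#' non-increasing eigenvalue; axes whose eigenvalues are non-positive are
#' zero-filled with a warning.  For reproducibility each axis is oriented
#' so its largest-magnitude loading is positive.
#'
#' @param d symmetric distance matrix (taxa x taxa); `NA` rows (excluded
#'   taxa) are dropped first.
#' @param dims number of dimensions, default 10; must be at most
#'   `n taxa - 1`.
#' @return list with `points` (taxa x dims coordinate matrix) and `eig`
#'   (all eigenvalues).
#' @export
embedMDS <- function(d, dims = 10) {
  excluded <- attr(d, "excluded")
  if (length(excluded)) {
    keep <- setdiff(rownames(d), excluded)
    d <- d[keep, keep]
  }
  n <- nrow(d)
  if (is.null(n) || n < 3) stop("need at least 3 taxa to embed")
  if (dims > n - 1) stop("dims must be at most n taxa - 1")
  mds <- cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  pts <- mds$points
  if (ncol(pts) < dims) {
    warning("only ", ncol(pts), " positive eigenvalues; ",
            "remaining axes zero-filled")
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  }
  # orient: largest-|loading| positive per axis
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("D", seq_len(dims))
  list(points = pts, eig = mds$eig)
}

## section index per dimension: three (or `sections`) equal-width bins over
## the globally observed [min, max]; interior boundaries belong to the lower
## section ((a, b] bins with the first closed at the bottom).
.sectionIndex <- function(x, lo, hi, sections) {
  if (hi <= lo) return(rep(1L, length(x)))
  w <- (hi - lo) / sections
  idx <- ceiling((x - lo) / w)
  idx[idx < 1L] <- 1L
  idx[idx > sections] <- sections
  as.integer(idx)
}

.sectionKey <- function(pts, dims, lo, hi, sections) {
  keys <- vapply(seq_len(dims), function(j)
    .sectionIndex(pts[, j], lo[j], hi[j], sections), integer(nrow(pts)))
  if (is.null(dim(keys))) keys <- matrix(keys, nrow = nrow(pts))
  apply(keys, 1, paste, collapse = ".")
}

#' Hypercube clustering of the MDS embedding into guilds
#'
#' Each dimensional axis is divided into `sections` equal sections (over
#' the axis's observed range across all taxa); taxa sharing the same
#' section on every considered dimension share a hypercube.  Starting from
#' `startDims` dimensions, each group is tested by adding one dimension at
#' a time: a group is stable — a guild — when the extra dimension either
#' produces no subgroup of size >= 2 outside the largest subgroup, or the
#' largest subgroup retains at least `stability` of the members.  Unstable
#' groups are replaced by their subgroups and refined further.  Singleton
#' groups become unassigned taxa, not guilds.
#'
#' @param embedding output of [embedMDS()].
#' @param startDims number of dimensions for the initial grouping (3).
#' @param sections sections per axis (3).
#' @param stability retained fraction above which a split is ignored (0.9).
#' @param scale `"global"` (default) sections every axis over the common
#'   coordinate range of the whole embedding, so hypercubes are true cubes
#'   and near-degenerate axes (negligible eigenvalue, hence negligible
#'   spread) do not shred tight clusters; `"per-dimension"` sections each
#'   axis over its own observed range.
#' @return a [GuildSet-class] (guild types unset; see
#'   [classifyGuildType()]).
#' @export
hypercubeCluster <- function(embedding, startDims = 3, sections = 3,
                             stability = 0.9,
                             scale = c("global", "per-dimension")) {
  scale <- match.arg(scale)
  pts <- embedding$points
  maxDims <- ncol(pts)
  if (maxDims < startDims) stop("embedding has fewer than startDims dimensions")
  if (scale == "global") {
    lo <- rep(min(pts), maxDims)
    hi <- rep(max(pts), maxDims)
  } else {
    lo <- apply(pts, 2, min)
    hi <- apply(pts, 2, max)
  }

  splitAt <- function(taxa, k) {
    key <- .sectionKey(pts[taxa, , drop = FALSE], k, lo, hi, sections)
    unname(split(taxa, key))
  }
  refine <- function(taxa, k) {
    if (length(taxa) < 2 || k >= maxDims) return(list(taxa))
    sub <- splitAt(taxa, k + 1)
    sizes <- sort(vapply(sub, length, integer(1)), decreasing = TRUE)
    stable <- sizes[1] >= stability * length(taxa) ||
      all(sizes[-1] < 2)
    if (stable) return(list(taxa))
    unlist(lapply(sub, refine, k = k + 1), recursive = FALSE)
  }

  groups <- splitAt(rownames(pts), startDims)
  groups <- unlist(lapply(groups, refine, k = startDims), recursive = FALSE)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]

  membership <- rep(NA_integer_, nrow(pts))
  names(membership) <- rownames(pts)
  ## deterministic guild numbering: by first member in row order
  if (length(groups)) {
    ord <- order(vapply(groups, function(g) min(match(g, rownames(pts))),
                        integer(1)))
    groups <- groups[ord]
    for (i in seq_along(groups)) membership[groups[[i]]] <- i
  }
  gids <- as.character(seq_along(groups))
  methods::new("GuildSet", membership = membership,
               guildType = setNames(rep(NA_character_, length(groups)), gids),
               anchor = setNames(rep(NA_character_, length(groups)), gids))
}

#' Permutation P values for pairwise taxon association
#'
#' One-sided permutation test for a positive co-occurrence correlation:
#' sample labels are permuted independently per taxon and the pmcc
#' recomputed; p = (1 + #\{permuted pmcc >= observed\}) / (1 + nPerm).
#' Constant taxa get p = 1 against every partner.  This stands in for the
#' external negative-binomial GLM used in the original analysis; the
#' binomial enrichment layer on top of it is [guildEnrichment()].
#'
#' @param se a [SedimentExperiment-class].
#' @param nPerm number of permutations, at least 99.
#' @param seed integer seed (mandatory for reproducibility).
#' @return symmetric matrix of p values (diagonal `NA`).
#' @export
pairAssociationPvalues <- function(se, nPerm = 999, seed) {
  if (nPerm < 99) stop("nPerm must be at least 99")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  f <- sampleFrequencies(se)
  nS <- nrow(f)
  constant <- apply(f, 2, function(x) stats::var(x) == 0)
  obs <- suppressWarnings(cor(f))
  count <- matrix(0L, ncol(f), ncol(f))
  for (b in seq_len(nPerm)) {
    fp <- apply(f, 2, function(x) x[sample.int(nS)])
    pc <- suppressWarnings(cor(fp))
    count <- count + (!is.na(pc) & !is.na(obs) & pc >= obs)
  }
  p <- (1 + count) / (1 + nPerm)
  p[constant, ] <- 1
  p[, constant] <- 1
  diag(p) <- NA
  dimnames(p) <- dimnames(obs)
  p
}

#' Classify guilds as simple or complex
#'
#' A guild is simple when every member pair is significantly associated
#' (p < `alpha`); otherwise it is complex and is anchored on the member
#' with the largest number of significant pairings (ties broken
#' lexicographically).
#'
#' @param guilds a [GuildSet-class].
#' @param pvalues symmetric pair p-value matrix covering all members
#'   (from [pairAssociationPvalues()]).
#' @param alpha significance level, default 0.05.
#' @return the [GuildSet-class] with `guildType` and `anchor` filled.
#' @export
classifyGuildType <- function(guilds, pvalues, alpha = 0.05) {
  m <- guildMembership(guilds)
  gt <- guilds@guildType
  an <- guilds@anchor
  for (g in guildIds(guilds)) {
    members <- sort(names(m)[!is.na(m) & m == g])
    if (!all(members %in% rownames(pvalues)))
      stop("p values missing for guild members: ",
           paste(setdiff(members, rownames(pvalues)), collapse = ", "))
    sub <- pvalues[members, members, drop = FALSE]
    pairP <- sub[upper.tri(sub)]
    if (anyNA(pairP)) stop("missing pair p value within guild ", g)
    gid <- as.character(g)
    if (all(pairP < alpha)) {
      gt[gid] <- "simple"
      an[gid] <- NA_character_
    } else {
      gt[gid] <- "complex"
      nsig <- rowSums(sub < alpha, na.rm = TRUE)
      an[gid] <- members[which.max(nsig)]   # which.max: first = lexicographic
    }
  }
  methods::initialize(guilds, guildType = gt, anchor = an)
}

#' Binomial enrichment of significant pairings within a guild
#'
#' Upper-tail probability P(X >= x) with X ~ Bin(m, p0): the chance of
#' seeing at least `x` significant member-pair correlations among `m`
#' tested pairs when significance arises only at the false-discovery rate
#' `p0` (0.05 or 0.01 in practice).
#'
#' @param m number of pairs tested (for a guild of k members,
#'   k(k-1)/2 by default interpretation).
#' @param x observed number of significant pairs, 0 <= x <= m.
#' @param p0 false-discovery rate, in (0, 1).
#' @return the upper-tail probability.
#' @examples
#' guildEnrichment(10, 10, 0.05)   # 0.05^10
#' @export
guildEnrichment <- function(m, x, p0) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (x < 0 || x > m) stop("x must lie in [0, m]")
  pbinom(x - 1, size = m, prob = p0, lower.tail = FALSE)
}

#' Number of member pairs in a guild of k taxa
#' @param k member count.
#' @return k(k-1)/2.
#' @export
guildPairCount <- function(k) k * (k - 1) / 2

#' Per-sample guild proportion profiles
#'
#' For each sample, the proportion of its (filtered) reads belonging to
#' the taxa of each guild; reads of unassigned taxa fill the `unassigned`
#' bucket so each profile sums to one.
#'
#' @param se a [SedimentExperiment-class] filtered to analysis scope.
#' @param guilds a [GuildSet-class] over (a subset of) the table's taxa.
#' @return a [GuildProfileMatrix-class].
#' @export
guildProfiles <- function(se, guilds) {
  counts <- SummarizedExperiment::assay(se, "counts")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  m <- guildMembership(guilds)
  gids <- guildIds(guilds)
  prop <- matrix(0, ncol(counts), length(gids),
                 dimnames = list(colnames(counts), as.character(gids)))
  for (g in gids) {
    members <- intersect(names(m)[!is.na(m) & m == g], rownames(counts))
    if (length(members))
      prop[, as.character(g)] <-
        colSums(counts[members, , drop = FALSE]) / tot
  }
  methods::new("GuildProfileMatrix", proportions = prop,
               unassigned = setNames(pmax(0, 1 - rowSums(prop)),
                                     colnames(counts)))
}

#' Guild-profile distance between two samples
#'
#' The Euclidean norm over guild coordinates,
#' \eqn{\partial = \sqrt{\sum_i (p_{1i} - p_{2i})^2}}; for proportion
#' vectors this lies in [0, sqrt(2)].  The `unassigned` bucket is not a
#' guild and does not enter the sum.
#'
#' @param p1,p2 named numeric vectors of guild proportions over the same
#'   guild list.
#' @return the distance.
#' @export
guildDistance <- function(p1, p2) {
  if (length(p1) != length(p2) ||
      (!is.null(names(p1)) && !is.null(names(p2)) &&
       !identical(names(p1), names(p2))))
    stop("profiles must cover the same guild list")
  sqrt(sum((p1 - p2)^2))
}

#' All pairwise guild-profile distances
#'
#' @param profiles a [GuildProfileMatrix-class].
#' @return symmetric samples x samples matrix of distances.
#' @export
guildDistanceMatrix <- function(profiles) {
  p <- guildProportions(profiles)
  as.matrix(stats::dist(p))
}

#' Build guilds from a count table in one call
#'
#' Convenience pipeline: [pairwisePmcc()] -> [corrToDistance()] ->
#' [embedMDS()] -> [hypercubeCluster()] -> [pairAssociationPvalues()] ->
#' [classifyGuildType()].
#'
#' @param se a [SedimentExperiment-class].
#' @param dims MDS dimensions (10).
#' @param startDims,sections,stability see [hypercubeCluster()].
#' @param nPerm,seed see [pairAssociationPvalues()].
#' @param alpha significance level for guild typing.
#' @return a classified [GuildSet-class].
#' @export
buildGuilds <- function(se, dims = 10, startDims = 3, sections = 3,
                        stability = 0.9, nPerm = 999, seed, alpha = 0.05) {
  cc <- pairwisePmcc(se)
  d <- corrToDistance(cc)
  emb <- embedMDS(d, dims = dims)
  guilds <- hypercubeCluster(emb, startDims = startDims,
                             sections = sections, stability = stability)
  pv <- pairAssociationPvalues(se, nPerm = nPerm, seed = seed)
  classifyGuildType(guilds, pv, alpha = alpha)
}

#' Write / read guild definitions as TSV
#'
#' Layout: columns `guild_id`, `taxon`, `guild_type`, `anchor_flag`.
#' Unassigned taxa are written with an empty guild id.
#'
#' @param guilds a [GuildSet-class].
#' @param file path.
#' @return `readGuilds` returns a [GuildSet-class].
#' @export
writeGuilds <- function(guilds, file) {
  m <- guildMembership(guilds)
  gt <- guildType(guilds)
  an <- guildAnchor(guilds)
  gid <- ifelse(is.na(m), "", as.character(m))
  df <- data.frame(
    guild_id = gid, taxon = names(m),
    guild_type = ifelse(gid == "", "", gt[gid]),
    anchor_flag = !is.na(m) & names(m) == an[as.character(m)] &
      !is.na(an[as.character(m)]))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeGuilds
#' @export
readGuilds <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  membership <- setNames(as.integer(df$guild_id), df$taxon)
  gids <- as.character(sort(unique(membership[!is.na(membership)])))
  gt <- setNames(rep(NA_character_, length(gids)), gids)
  an <- setNames(rep(NA_character_, length(gids)), gids)
  for (g in gids) {
    rows <- !is.na(membership) & membership == as.integer(g)
    ty <- unique(df$guild_type[rows])
    ty <- ty[!is.na(ty)]
    if (length(ty)) gt[g] <- ty[1]
    a <- df$taxon[rows & df$anchor_flag %in% TRUE]
    if (length(a)) an[g] <- a[1]
  }
  methods::new("GuildSet", membership = membership, guildType = gt,
               anchor = an)
}

#' Write / read guild profiles as TSV
#'
#' Layout: `sample_id`, one column per guild, then `unassigned`.
#'
#' @param profiles a [GuildProfileMatrix-class].
#' @param file path.
#' @export
writeGuildProfiles <- function(profiles, file) {
  p <- guildProportions(profiles)
  df <- data.frame(sample_id = rownames(p), p,
                   unassigned = unassignedFraction(profiles),
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeGuildProfiles
#' @export
readGuildProfiles <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  p <- as.matrix(df[, setdiff(colnames(df), c("sample_id", "unassigned")),
                    drop = FALSE])
  rownames(p) <- df$sample_id
  methods::new("GuildProfileMatrix", proportions = p,
               unassigned = setNames(df$unassigned, df$sample_id))
}
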