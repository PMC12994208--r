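#' Configuration for the synthetic sedaDNA landscape
#'
#' The defaults state the simulated world used throughout the test suite:
#' 4 guild blocks over 40 taxa, 6 cores of 10 samples sequenced to a depth
#' of 5,000 reads, a silt/coarse-sand sediment sequence with local
#' compositional proportions spanning the fine-to-coarse range, no
#' diffusion, and a linear age model.
#'
#' @param nCores number of cores (6).
#' @param samplesPerCore samples per core (10).
#' @param nTaxa number of taxa (40); must be divisible by `nGuilds`.
#' @param nGuilds planted guild blocks (4).
#' @param depth multinomial read depth per sample (5000).
#' @param clBySediment named local-proportion map per sediment class.
#' @param lambdaDiffusion diffusion decay rate in 1/cm; 0 disables (0).
#' @param driftRate Dirichlet concentration of the guild-weight random
#'   walk; larger = slower environmental turnover.  The default (60)
#'   keeps one-step guild-weight change under ~10% of the simplex scale
#'   — a genuinely autocorrelated local environment at the sampling
#'   interval, as gradual vegetation change over the ~150 y between
#'   samples would be — while leaving enough within-core variation for
#'   co-occurrence structure to be estimable.
#' @param influxLag minimum reworking age, in samples, of the distal
#'   (influx) material (3); each sample's influx is the local
#'   environment lagged by a random offset in [influxLag, 8 * influxLag].
#' @param sedimentSequence per-core sediment classes, recycled to
#'   `samplesPerCore`; default half silt, half coarse sand.
#' @param depthSpacing cm between consecutive samples (10).
#' @param ageAtSurface,yearsPerCm linear age model: age = ageAtSurface +
#'   yearsPerCm * depth_cm (6000 cal BP, 15 y/cm).
#' @param seed integer seed, mandatory.
#' @return a `simConfig` list.
#' @export
simConfig <- function(nCores = 6, samplesPerCore = 10, nTaxa = 40,
                      nGuilds = 4, depth = 5000,
                      clBySediment = c(clay = 0.95, silt = 0.95,
                                       fine_sand = 0.75, medium_sand = 0.55,
                                       coarse_sand = 0.4),
                      lambdaDiffusion = 0, driftRate = 60, influxLag = 3,
                      sedimentSequence = NULL, depthSpacing = 10,
                      ageAtSurface = 6000, yearsPerCm = 15, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (nTaxa %% nGuilds != 0)
    stop("nTaxa must be divisible by nGuilds")
  if (any(clBySediment < 0 | clBySediment > 1))
    stop("clBySediment values must lie in [0, 1]")
  if (is.null(sedimentSequence))
    sedimentSequence <- rep(c("silt", "coarse_sand"),
                            each = ceiling(samplesPerCore / 2))
  structure(list(nCores = nCores, samplesPerCore = samplesPerCore,
                 nTaxa = nTaxa, nGuilds = nGuilds, depth = depth,
                 clBySediment = clBySediment,
                 lambdaDiffusion = lambdaDiffusion, driftRate = driftRate,
                 influxLag = influxLag,
                 sedimentSequence = rep(sedimentSequence,
                                        length.out = samplesPerCore),
                 depthSpacing = depthSpacing, ageAtSurface = ageAtSurface,
                 yearsPerCm = yearsPerCm, seed = as.integer(seed)),
            class = "simConfig")
}

#' Simulate a sedaDNA landscape with known ground truth
#'
#' Generates cores of multinomial read-count samples with the statistical
#' structure the depositional analyses assume: taxa are grouped into
#' disjoint guild blocks whose archetype compositions are Dirichlet draws;
#' each core's latent local environment is a temporally autocorrelated
#' random walk over guild weights; the influx (distal) environment is the
#' local one lagged by `influxLag` steps; the observed composition mixes
#' the two as cl * local + (1 - cl) * influx with cl set by the sample's
#' sediment class; optional diffusion mixes adjacent samples with weight
#' exp(-lambda * spacing); counts are multinomial at the configured depth.
#' Per-core substreams are derived from the seed, so outputs are
#' reproducible and stable under core reordering.
#'
#' @param cfg a [simConfig()].
#' @return list with `se` (a [SedimentExperiment-class] with full
#'   metadata; security labels are derived from the true cl against the
#'   default 0.85/0.5 bands) and `truth` (planted guild membership, latent
#'   local and influx compositions, realised cl per sample, lambda).
#' @export
simulateLandscape <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  blockSize <- cfg$nTaxa / cfg$nGuilds
  taxa <- sprintf("taxon%02d", seq_len(cfg$nTaxa))
  guildOf <- setNames(rep(seq_len(cfg$nGuilds), each = blockSize), taxa)

  ## guild archetypes: Dirichlet within disjoint blocks, zero elsewhere
  arch <- matrix(0, cfg$nTaxa, cfg$nGuilds, dimnames = list(taxa, NULL))
  for (g in seq_len(cfg$nGuilds)) {
    idx <- which(guildOf == g)
    arch[idx, g] <- .rdirichlet(1, rep(5, blockSize))
  }

  nS <- cfg$nCores * cfg$samplesPerCore
  counts <- matrix(0L, cfg$nTaxa, nS, dimnames = list(taxa, NULL))
  localComp <- matrix(0, cfg$nTaxa, nS)
  influxComp <- matrix(0, cfg$nTaxa, nS)
  obsComp <- matrix(0, cfg$nTaxa, nS)
  md <- NULL
  clReal <- numeric(nS)
  col <- 0L

  for (core in seq_len(cfg$nCores)) {
    set.seed((cfg$seed + 7919L * core) %% .Machine$integer.max)
    T <- cfg$samplesPerCore
    lag <- cfg$influxLag
    maxLag <- 8L * lag
    ## guild-weight walk, with older burn-in states feeding the influx
    ## source; each sample's influx is the local environment lagged by a
    ## reworking age drawn from [lag, 8 lag], so the influx signal is
    ## erratic between adjacent samples the way reworked sediment is
    w <- matrix(0, T + maxLag, cfg$nGuilds)
    w[1, ] <- .rdirichlet(1, rep(2, cfg$nGuilds))
    for (t in 2:(T + maxLag))
      w[t, ] <- .rdirichlet(1, cfg$driftRate * w[t - 1, ] + 0.1)
    localW <- w[(maxLag + 1):(maxLag + T), , drop = FALSE]
    lagT <- sample(lag:maxLag, T, replace = TRUE)
    influxW <- w[maxLag + seq_len(T) - lagT, , drop = FALSE]

    obs <- matrix(0, cfg$nTaxa, T)
    loc <- arch %*% t(localW)
    infl <- arch %*% t(influxW)
    sed <- cfg$sedimentSequence
    cl <- cfg$clBySediment[sed]
    for (t in seq_len(T)) obs[, t] <- cl[t] * loc[, t] + (1 - cl[t]) * infl[, t]

    if (cfg$lambdaDiffusion > 0) {
      wD <- exp(-cfg$lambdaDiffusion * cfg$depthSpacing)
      mixed <- obs
      for (t in seq_len(T)) {
        nb <- obs[, c(max(1, t - 1), min(T, t + 1)), drop = FALSE]
        m <- obs[, t] + wD * rowMeans(nb)
        mixed[, t] <- m / sum(m)
      }
      obs <- mixed
    }

    for (t in seq_len(T)) {
      col <- col + 1L
      counts[, col] <- rmultinom(1, cfg$depth, obs[, t])
      localComp[, col] <- loc[, t]
      influxComp[, col] <- infl[, t]
      obsComp[, col] <- obs[, t]
      clReal[col] <- cl[t]
      depth_cm <- t * cfg$depthSpacing
      md <- rbind(md, data.frame(
        sample_id = sprintf("core%02d_s%02d", core, t),
        core_id = sprintf("core%02d", core),
        depth_cm = depth_cm, sediment_class = sed[t],
        laminated = FALSE,
        age_calBP = cfg$ageAtSurface + cfg$yearsPerCm * depth_cm,
        age_sd = 50,
        security = if (cl[t] >= 0.85) "secure"
                   else if (cl[t] <= 0.5) "insecure" else "unknown",
        domain = "unknown"))
    }
  }
  colnames(counts) <- md$sample_id
  colnames(localComp) <- colnames(influxComp) <- colnames(obsComp) <-
    md$sample_id
  rownames(localComp) <- rownames(influxComp) <- rownames(obsComp) <- taxa

  taxonomy <- data.frame(taxon = taxa, rank = "genus", native_europe = TRUE)
  se <- SedimentExperiment(counts, taxonomy = taxonomy, metadata = md,
                           dropEmpty = FALSE)
  list(se = se,
       truth = list(guildOf = guildOf, archetypes = arch,
                    localComposition = localComp,
                    influxComposition = influxComp,
                    observedComposition = obsComp,
                    clRealized = setNames(clReal, md$sample_id),
                    lambda = cfg$lambdaDiffusion,
                    metadata = md))
}

#' Ground-truth guild profiles from planted membership
#'
#' Convenience for tests of the depositional fit: guild profiles computed
#' with the planted (true) guild blocks rather than recovered ones.
#'
#' @param se a [SedimentExperiment-class] from [simulateLandscape()].
#' @param guildOf named integer vector of planted membership.
#' @return a [GuildProfileMatrix-class].
#' @export
trueGuildProfiles <- function(se, guildOf) {
  gs <- methods::new("GuildSet", membership = guildOf,
                     guildType = setNames(character(0), character(0)),
                     anchor = setNames(character(0), character(0)))
  guildProfiles(se, gs)
}

.TRANSVERSION <- c(A = "C", C = "A", G = "T", T = "G")

#' Simulate a gap-concatenated alignment with planted clade support
#'
#' Builds reference rows as mutated copies of a random backbone, an
#' ancient row covering `nReads` read blocks separated by five-gap runs,
#' and plants, for each named taxon, the requested number of
#' exclusively-shared SNPs: interior alignment columns where the ancient
#' row and that taxon alone carry a transversion-derived state (so the
#' planted signal survives the clip, singleton and transition filters).
#' Optional deamination-like noise flips ancient C->T (5' end) and G->A
#' (3' end) within the terminal `clip` bases of each block, emulating the
#' damage the clipping stage removes.
#'
#' @param nTaxa number of reference taxa (6).
#' @param nReads ancient read blocks (20).
#' @param readLen block length in bases (60).
#' @param plantedShares named integer vector: exclusive SNPs to plant per
#'   reference taxon.
#' @param refDivergence per-base mutation rate of each reference relative
#'   to the backbone (0.03).
#' @param endDeamination per-base probability of terminal deamination
#'   flips in the ancient row (0 disables).
#' @param margin interior margin, in bases, kept between planted sites and
#'   block ends (5, matching the default clip).
#' @param seed integer seed, mandatory.
#' @return list with `alignment` (a [ConcatAlignment-class]) and `truth`
#'   (planted positions per taxon).
#' @export
simulateAlignment <- function(nTaxa = 6, nReads = 20, readLen = 60,
                              plantedShares = integer(0),
                              refDivergence = 0.03, endDeamination = 0,
                              margin = 5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  refs <- sprintf("taxon%s", LETTERS[seq_len(nTaxa)])
  if (length(plantedShares) && !all(names(plantedShares) %in% refs))
    stop("plantedShares names must be among ", paste(refs, collapse = ", "))
  gap <- 5L
  L <- nReads * readLen + (nReads - 1L) * gap
  backbone <- sample(.BASES, L, replace = TRUE)

  M <- matrix(rep(backbone, nTaxa + 1), nrow = nTaxa + 1, byrow = TRUE)
  rownames(M) <- c(refs, "ancient")
  for (i in seq_len(nTaxa)) {
    mut <- which(runif(L) < refDivergence)
    if (length(mut))
      M[i, mut] <- vapply(backbone[mut], function(b)
        sample(setdiff(.BASES, b), 1), character(1))
  }

  blockStart <- (seq_len(nReads) - 1L) * (readLen + gap) + 1L
  blockEnd <- blockStart + readLen - 1L
  covered <- unlist(lapply(seq_len(nReads),
                           function(k) blockStart[k]:blockEnd[k]))
  ancient <- rep("-", L)
  ancient[covered] <- backbone[covered]

  interior <- unlist(lapply(seq_len(nReads), function(k)
    (blockStart[k] + margin):(blockEnd[k] - margin)))
  if (sum(lengths(list(interior))) < sum(plantedShares))
    stop("infeasible plant: more planted sites than interior positions")
  planted <- list()
  pool <- interior
  for (tx in names(plantedShares)) {
    need <- plantedShares[[tx]]
    if (need > length(pool)) stop("infeasible plant for ", tx)
    pos <- sort(sample(pool, need))
    pool <- setdiff(pool, pos)
    for (j in pos) {
      b <- backbone[j]
      d <- .TRANSVERSION[[b]]
      ancient[j] <- d
      M[tx, j] <- d
      M[setdiff(refs, tx), j] <- b     # keep the share exclusive
    }
    planted[[tx]] <- pos
  }

  if (endDeamination > 0) {
    for (k in seq_len(nReads)) {
      head5 <- blockStart[k]:(blockStart[k] + margin - 1)
      tail3 <- (blockEnd[k] - margin + 1):blockEnd[k]
      flip5 <- head5[ancient[head5] == "C" & runif(margin) < endDeamination]
      flip3 <- tail3[ancient[tail3] == "G" & runif(margin) < endDeamination]
      ancient[flip5] <- "T"
      ancient[flip3] <- "A"
    }
  }

  M["ancient", ] <- ancient
  seqs <- Biostrings::DNAStringSet(apply(M, 1, paste, collapse = ""))
  names(seqs) <- rownames(M)
  list(alignment = ConcatAlignment(seqs, "ancient", gap),
       truth = list(planted = planted, backbone = backbone,
                    blocks = data.frame(start = blockStart,
                                        end = blockEnd)))
}
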