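test_that("pairwise pmcc is Pearson correlation of sample frequencies", {
  # sample totals differ, so frequencies (not raw counts) matter
  cts <- countMatrix(a = c(10L, 40L, 90L, 80L),
                     b = c(10L, 40L, 90L, 80L),
                     c = c(80L, 20L, 10L, 20L),
                     d = c(0L, 40L, 100L, 100L))
  se <- makeSE(cts)
  cc <- pairwisePmcc(se)
  expect_equal(cc["a", "b"], 1)
  f <- sampleFrequencies(se)
  # textbook Pearson on the frequency vectors, written out by hand
  pearson <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  expect_equal(cc["a", "d"], pearson(f[, "a"], f[, "d"]), tolerance = 1e-12)
  expect_equal(cc["c", "d"], pearson(f[, "c"], f[, "d"]), tolerance = 1e-12)
  expect_equal(cc, t(cc))
})

test_that("exactly anti-linear frequency vectors give pmcc -1", {
  # equal sample totals so frequencies are (0.1,0.2,0.3) vs (0.3,0.2,0.1)
  cts <- countMatrix(up = c(10L, 20L, 30L), down = c(30L, 20L, 10L),
                     rest = c(60L, 60L, 60L))
  cc <- pairwisePmcc(makeSE(cts))
  expect_equal(cc["up", "down"], -1)
})

test_that("zero-variance taxa are excluded from correlation with a log", {
  cts <- countMatrix(a = c(10L, 20L, 30L), flat = c(10L, 10L, 10L),
                     b = c(5L, 10L, 40L))
  # 'flat' has constant frequency only if totals are equal; make them so
  cts <- rbind(cts, filler = as.integer(100 - colSums(cts)))
  se <- makeSE(cts)
  expect_message(cc <- pairwisePmcc(se), "zero-variance")
  expect_true("flat" %in% attr(cc, "excluded"))
  expect_true(all(is.na(cc["flat", setdiff(colnames(cc), "flat")])))
})

test_that("correlation-to-distance map hits its fixed points and inverts", {
  expect_equal(corrToDistance(1), 0)
  expect_equal(corrToDistance(-1), 1)
  expect_equal(corrToDistance(0), 0.5)
  set.seed(1)
  r <- runif(100, -1, 1)
  expect_equal(distanceToCorr(corrToDistance(r)), r, tolerance = 1e-12)
})

test_that("classical MDS reproduces Euclidean-realizable distances", {
  # equilateral triangle, side 1
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  emb <- embedMDS(d3, dims = 2)
  got <- as.matrix(dist(emb$points))
  expect_equal(got, d3, tolerance = 1e-9, ignore_attr = TRUE)
  # embedding is invariant (up to per-axis sign) under taxon reordering:
  # pairwise embedded distances must not change
  set.seed(4)
  pts <- matrix(rnorm(12 * 5), 12, 5,
                dimnames = list(paste0("t", 1:12), NULL))
  dm <- as.matrix(dist(pts))
  perm <- sample(rownames(dm))
  d1 <- as.matrix(dist(embedMDS(dm, dims = 6)$points))
  d2 <- as.matrix(dist(embedMDS(dm[perm, perm], dims = 6)$points))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-8)
  expect_error(embedMDS(d3, dims = 3), "at most")
})

test_that("hypercube clustering groups by joint section membership", {
  # all taxa at identical coordinates -> a single guild
  pts <- matrix(0.3, 6, 4, dimnames = list(paste0("t", 1:6), NULL))
  g <- hypercubeCluster(list(points = pts), startDims = 3)
  expect_length(guildIds(g), 1)
  expect_true(all(guildMembership(g) == 1))
  # two tight blobs separated by more than a third of the range on dim 1
  set.seed(7)
  pts2 <- rbind(matrix(c(rnorm(10, 0, 0.01)), 5, 2),
                matrix(c(rnorm(10, 1, 0.01)), 5, 2))
  pts2 <- cbind(pts2, matrix(rnorm(20, 0, 0.005), 10, 2))
  rownames(pts2) <- paste0("t", 1:10)
  g2 <- hypercubeCluster(list(points = pts2), startDims = 3)
  expect_length(guildIds(g2), 2)
  m <- guildMembership(g2)
  expect_length(unique(m[1:5]), 1)
  expect_length(unique(m[6:10]), 1)
  expect_false(m[1] == m[6])
  # partition property: no taxon in two guilds is structural (one label
  # per taxon), and every guild has >= 2 members
  expect_true(all(table(m[!is.na(m)]) >= 2))
})

test_that("permutation pair p-values detect association and need a seed", {
  # 8 samples: enough distinct label permutations (8! = 40320) for the
  # permutation p of a near-perfect association to resolve below 0.01
  cts <- countMatrix(a = c(10L, 40L, 90L, 20L, 60L, 30L, 75L, 15L),
                     b = c(11L, 41L, 88L, 19L, 61L, 29L, 74L, 16L),
                     c = c(80L, 20L, 10L, 70L, 30L, 60L, 15L, 80L))
  se <- makeSE(cts)
  p <- pairAssociationPvalues(se, nPerm = 999, seed = 5)
  expect_lte(p["a", "b"], 0.01)       # near-identical co-occurrence
  expect_gt(p["a", "c"], 0.5)         # anti-correlated: one-sided test
  expect_equal(p, t(p))
  expect_error(pairAssociationPvalues(se, nPerm = 0, seed = 1), "99")
  expect_error(pairAssociationPvalues(se, nPerm = 999), "seed")
  # deterministic given seed
  expect_identical(p, pairAssociationPvalues(se, nPerm = 999, seed = 5))
})

test_that("null permutation p-values are uniform (KS calibration)", {
  set.seed(11)
  cts <- matrix(rpois(30 * 20, 40), nrow = 30,
                dimnames = list(paste0("t", 1:30), paste0("s", 1:20)))
  se <- makeSE(cts)   # 30 independent taxa x 20 samples
  p <- pairAssociationPvalues(se, nPerm = 999, seed = 12)
  # disjoint pairs (t1-t2, t3-t4, ...) are independent; pairs sharing a
  # taxon are not, and would distort the KS null
  pv <- vapply(seq(1, 29, 2), function(i) p[i, i + 1], numeric(1))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("guild typing separates simple from anchored complex guilds", {
  mk <- function(members) {
    membership <- setNames(rep(1L, length(members)), members)
    methods::new("GuildSet", membership = membership,
                 guildType = c("1" = NA_character_),
                 anchor = c("1" = NA_character_))
  }
  pm <- function(vals, taxa) {
    m <- matrix(1, length(taxa), length(taxa), dimnames = list(taxa, taxa))
    m[lower.tri(m)] <- vals; m[upper.tri(m)] <- t(m)[upper.tri(m)]
    diag(m) <- NA
    m
  }
  # all three pairs significant -> simple
  g <- classifyGuildType(mk(c("A", "B", "C")),
                         pm(c(0.01, 0.02, 0.03), c("A", "B", "C")))
  expect_identical(unname(guildType(g)["1"]), "simple")
  expect_true(is.na(guildAnchor(g)["1"]))
  # A-B and A-C significant, B-C not -> complex anchored on A
  g2 <- classifyGuildType(mk(c("A", "B", "C")),
                          pm(c(0.01, 0.02, 0.50), c("A", "B", "C")))
  expect_identical(unname(guildType(g2)["1"]), "complex")
  expect_identical(unname(guildAnchor(g2)["1"]), "A")
  # 2-member guild, only pair non-significant -> complex, lexicographic tie
  g3 <- classifyGuildType(mk(c("B", "A")), pm(0.2, c("A", "B")))
  expect_identical(unname(guildType(g3)["1"]), "complex")
  expect_identical(unname(guildAnchor(g3)["1"]), "A")
  # missing pair p value -> error
  bad <- pm(c(0.01, 0.02, NA), c("A", "B", "C"))
  expect_error(classifyGuildType(mk(c("A", "B", "C")), bad), "missing")
})

test_that("binomial enrichment matches its closed form and guards p0", {
  expect_equal(guildEnrichment(10, 10, 0.05), 0.05^10)
  expect_equal(guildEnrichment(10, 0, 0.05), 1.0)
  expect_equal(guildEnrichment(10, 1, 0.05), 1 - 0.95^10)
  expect_error(guildEnrichment(10, 3, 0), "p0")
  expect_error(guildEnrichment(10, 11, 0.05), "x must")
  expect_equal(guildPairCount(5), 10)
})

test_that("guild profiles partition sample reads with an unassigned bucket", {
  cts <- countMatrix(a = c(30L, 100L), b = c(20L, 0L), c = c(50L, 0L),
                     d = c(0L, 0L), stray = c(0L, 25L))
  se <- makeSE(cts)
  membership <- c(a = 1L, b = 1L, c = 2L, d = 2L, stray = NA)
  gs <- methods::new("GuildSet", membership = membership,
                     guildType = c("1" = NA_character_, "2" = NA_character_),
                     anchor = c("1" = NA_character_, "2" = NA_character_))
  gp <- guildProfiles(se, gs)
  p <- guildProportions(gp)
  expect_equal(unname(p["s1", ]), c(0.5, 0.5))       # (30+20)/100, 50/100
  expect_equal(unname(p["s2", ]), c(0.8, 0))         # all guild-1 reads
  expect_equal(unname(unassignedFraction(gp)["s2"]), 0.2)
  expect_equal(unname(unassignedFraction(gp)["s1"]), 0)
  # zero-total sample errors
  cts0 <- countMatrix(a = c(1L, 0L), b = c(2L, 0L))
  expect_error(guildProfiles(makeSE(cts0), gs), "zero-total")
})

test_that("guild distance is the Euclidean norm over guild coordinates", {
  expect_equal(guildDistance(c(g1 = 0.4, g2 = 0.6), c(g1 = 0.4, g2 = 0.6)), 0)
  expect_equal(guildDistance(c(g1 = 1, g2 = 0), c(g1 = 0, g2 = 1)), sqrt(2))
  expect_equal(guildDistance(c(g1 = 0.5, g2 = 0.5), c(g1 = 0.25, g2 = 0.75)),
               sqrt(0.125))
  expect_error(guildDistance(c(g1 = 1), c(g1 = 0.5, g2 = 0.5)), "same guild")
})

test_that("guild and profile TSV round trips preserve structure", {
  membership <- c(oak = 1L, elm = 1L, sedge = 2L, reed = 2L, fern = NA)
  gs <- methods::new("GuildSet", membership = membership,
                     guildType = c("1" = "simple", "2" = "complex"),
                     anchor = c("1" = NA_character_, "2" = "reed"))
  f <- tempfile(fileext = ".tsv")
  writeGuilds(gs, f)
  back <- readGuilds(f)
  expect_identical(guildMembership(back), membership)
  expect_identical(guildType(back), guildType(gs))
  expect_identical(guildAnchor(back), guildAnchor(gs))

  p <- matrix(c(0.2, 0.5, 0.7, 0.1), 2, 2,
              dimnames = list(c("s1", "s2"), c("1", "2")))
  gp <- methods::new("GuildProfileMatrix", proportions = p,
                     unassigned = c(s1 = 0.1, s2 = 0.4))
  f2 <- tempfile(fileext = ".tsv")
  writeGuildProfiles(gp, f2)
  back2 <- readGuildProfiles(f2)
  expect_equal(guildProportions(back2), p)
  expect_equal(unassignedFraction(back2), unassignedFraction(gp))
})
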