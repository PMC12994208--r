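mkProfiles <- function(p, samples = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(p)))
  dimnames(p) <- list(samples, as.character(seq_len(ncol(p))))
  methods::new("GuildProfileMatrix", proportions = p,
               unassigned = setNames(pmax(0, 1 - rowSums(p)), samples))
}

test_that("sediment pair stats split same-type and type-change pairs", {
  # single core, all silt, identical profiles: d1 = 0, no change pairs
  gp <- mkProfiles(matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 3, 2))
  md <- data.frame(sample_id = paste0("s", 1:3), core_id = "c1",
                   depth_cm = c(10, 20, 30), sediment_class = "silt")
  st <- sedimentPairStats(gp, md)
  expect_equal(st$mean_d1[st$sediment_type == "silt"], 0)
  expect_equal(st$n2[st$sediment_type == "silt"], 0)

  # silt -> sand with orthogonal profiles: d2 = sqrt(2) for both types
  gp2 <- mkProfiles(matrix(c(1, 0, 0, 1), 2, 2))
  md2 <- data.frame(sample_id = paste0("s", 1:2), core_id = "c1",
                    depth_cm = c(10, 20),
                    sediment_class = c("silt", "coarse_sand"))
  st2 <- sedimentPairStats(gp2, md2)
  expect_equal(st2$mean_d2, rep(sqrt(2), 2))
  expect_equal(st2$n1, c(0L, 0L))

  # 4-sample toy, hand enumeration: pairs (1,2) silt-silt, (2,3)
  # silt-sand, (3,4) sand-sand
  p <- matrix(c(1, 0.8, 0.1, 0.3,
                0, 0.2, 0.9, 0.7), 4, 2)
  gp3 <- mkProfiles(p)
  md3 <- data.frame(sample_id = paste0("s", 1:4), core_id = "c1",
                    depth_cm = 1:4 * 10,
                    sediment_class = c("silt", "silt", "fine_sand",
                                       "fine_sand"))
  st3 <- sedimentPairStats(gp3, md3)
  d <- function(i, j) sqrt(sum((p[i, ] - p[j, ])^2))
  expect_equal(st3$mean_d1[st3$sediment_type == "silt"], d(1, 2))
  expect_equal(st3$mean_d1[st3$sediment_type == "fine_sand"], d(3, 4))
  expect_equal(st3$mean_d2[st3$sediment_type == "silt"], d(2, 3))
  expect_equal(st3$mean_d2[st3$sediment_type == "fine_sand"], d(2, 3))
})

test_that("model prediction follows the depositional algebra", {
  # pure local: cs = 0 kills both influx terms
  expect_equal(unname(modelPredict(0.5, 0.5, cl = 1, dxloc = 0.3, id = 1.5)),
               c(0.3, 0.3))
  # e1 = -1 removes the same-type influx term
  p <- modelPredict(-1, 0, cl = 0.6, dxloc = 0.4, id = 0.5)
  expect_equal(unname(p["d1"]), 0.4)
  # hand evaluation under the fraction reading
  p2 <- modelPredict(0, 0, cl = 0.8, dxloc = 0.3, id = 0.5)
  expect_equal(unname(p2), c(0.3 + (0.3 / 0.8) * 0.2, 0.3 + 0.5 * 0.2))
  # product reading
  p3 <- modelPredict(0, 0, cl = 0.8, dxloc = 0.3, id = 0.5, eq7 = "product")
  expect_equal(unname(p3["d1"]), 0.3 + 0.3 * 0.8 * 0.2)
  expect_error(modelPredict(0, 0, cl = 0, dxloc = 0.3, id = 0.5), "cl")
})

test_that("fit metric sums squared errors plus the ratio term", {
  expect_equal(as.numeric(fitMetric(c(0.3, 0.4), c(0.3, 0.4))), 0)
  # equal ratios: third term zero
  expect_equal(as.numeric(fitMetric(c(0.4, 0.5), c(0.2, 0.25))), 0.1025)
  # differing ratios
  expect_equal(as.numeric(fitMetric(c(0.2, 0.4), c(0.2, 0.2))), 1.04)
  # zero observed d1: ratio omitted and flagged
  f <- fitMetric(c(0.1, 0.2), c(0, 0.2))
  expect_true(attr(f, "ratioOmitted"))
  expect_equal(as.numeric(f), 0.01)
})

test_that("inner grid matches the stated four-million-point scale", {
  expect_equal(innerGridSize(0.01), 100 * 201 * 201)
})

test_that("degenerate zero observations are fitted exactly", {
  fit <- monteCarloFit(0, 0, nChains = 3, seed = 3)
  expect_equal(fitScore(fit), 0)
  p <- fitParams(fit)
  expect_equal(unname(p["dxloc"]), 0)
  expect_equal(unname(p["id"] * p["cs"] * (1 + p["e2"])), 0)
  expect_error(monteCarloFit(0.1, 0.2, n1 = 0L, seed = 1), "pair classes")
  expect_error(monteCarloFit(0.1, 0.2, nChains = 3), "seed")
})

test_that("independent searches agree on the best fit score", {
  # "varied little": two seeds on the same off-grid observations
  f1 <- monteCarloFit(0.118, 0.171, nChains = 30, seed = 21)
  f2 <- monteCarloFit(0.118, 0.171, nChains = 30, seed = 1007)
  expect_lt(abs(fitScore(f1) - fitScore(f2)), 1e-6)
  # and each reproduces the observations within grid resolution
  for (f in list(f1, f2))
    expect_lt(sum(abs(f@predicted - f@observed[c("d1", "d2")])), 0.05)
})

test_that("security labels combine fitted cl with sediment context", {
  fits <- list(
    silt = methods::new("DepositionFit", sedimentType = "silt",
      params = c(e1 = 0, e2 = 0, cl = 0.93, cs = 0.07, dxloc = 0.1,
                 id = 0.2),
      fit = 0, predicted = c(d1 = 0.1, d2 = 0.1),
      observed = c(d1 = 0.1, d2 = 0.1, n1 = 5, n2 = 2), nChains = 1L,
      nEvaluations = 0, seed = 1L, eq7 = "fraction", ratioOmitted = FALSE),
    coarse_sand = methods::new("DepositionFit", sedimentType = "coarse_sand",
      params = c(e1 = 0, e2 = 0, cl = 0.30, cs = 0.70, dxloc = 0.1,
                 id = 0.2),
      fit = 0, predicted = c(d1 = 0.1, d2 = 0.1),
      observed = c(d1 = 0.1, d2 = 0.1, n1 = 5, n2 = 2), nChains = 1L,
      nEvaluations = 0, seed = 1L, eq7 = "fraction", ratioOmitted = FALSE),
    medium_sand = methods::new("DepositionFit", sedimentType = "medium_sand",
      params = c(e1 = 0, e2 = 0, cl = 0.70, cs = 0.30, dxloc = 0.1,
                 id = 0.2),
      fit = 0, predicted = c(d1 = 0.1, d2 = 0.1),
      observed = c(d1 = 0.1, d2 = 0.1, n1 = 5, n2 = 2), nChains = 1L,
      nEvaluations = 0, seed = 1L, eq7 = "fraction", ratioOmitted = FALSE))
  md <- data.frame(
    sample_id = paste0("s", 1:5),
    sediment_class = c("silt", "coarse_sand", "medium_sand", "clay",
                       "fine_sand"),
    laminated = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  lab <- classifySecurity(md, fits)
  expect_identical(unname(lab["s1"]), "secure")     # laminated silt, cl .93
  expect_identical(unname(lab["s2"]), "insecure")   # coarse sand, cl .30
  expect_identical(unname(lab["s3"]), "unknown")    # cl .70 between bands
  expect_identical(unname(lab["s4"]), "secure")     # laminated clay, no fit
  expect_identical(unname(lab["s5"]), "unknown")    # no fit, not laminated
})
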