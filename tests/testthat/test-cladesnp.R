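test_that("read blocks are delimited by runs of five or more gaps", {
  # two blocks; the 3-gap run inside block 2 does not split it
  rows <- c(taxonA = "ACGTACGTACGTACGTACGTACGT",
            taxonB = "ACGTACGTACGTACGTACGTACGT",
            ancient = "ACGT-----ACGTACG---TACGT")
  aln <- makeAlignment(rows)
  blocks <- ancientReadBlocks(aln)
  expect_equal(blocks$start, c(1L, 10L))
  expect_equal(blocks$end, c(4L, 24L))
  # leading/trailing gaps of any length also delimit
  rows2 <- c(taxonA = "ACGTACGTAC", ancient = "--GTACGT--")
  blocks2 <- ancientReadBlocks(makeAlignment(rows2))
  expect_equal(blocks2, data.frame(start = 3L, end = 8L))
})

test_that("SNP sites require ancient coverage and two states", {
  # all identical -> no sites
  rows <- c(taxonA = "ACGT", taxonB = "ACGT", ancient = "ACGT")
  expect_equal(nrow(findSnpSites(makeAlignment(rows))), 0)
  # one column where ancient = taxonA = T, others C; one where ancient
  # is '-' (not a site despite reference polymorphism)
  rows2 <- c(taxonA = "ATGA", taxonB = "ACGC", taxonC = "ACGC",
             ancient = "ATG-")
  sites <- findSnpSites(makeAlignment(rows2))
  expect_equal(sites$position, 2L)
  expect_identical(sites$sharing, "taxonA")
  expect_false(sites$is_singleton)
  # ancient-private state is a singleton
  rows3 <- c(taxonA = "AC", taxonB = "AC", ancient = "AT")
  s3 <- findSnpSites(makeAlignment(rows3))
  expect_true(s3$is_singleton)
  expect_identical(s3$sharing, "")
})

test_that("exclusive clade support counts match planted toys", {
  # three planted exclusive-share columns for taxonB
  rows <- c(taxonA = "AAACCCGGGTTT",
            taxonB = "ATACTCGGTTTT",
            taxonC = "AAACCCGGGTTT",
            ancient = "ATACTCGGTTTT")
  cnt <- cladeSupportCounts(findSnpSites(makeAlignment(rows)))
  expect_equal(unname(cnt["taxonB"]), 3L)
  expect_equal(unname(cnt["taxonA"]), 0L)
  # no polymorphism -> all zeros
  rows0 <- c(taxonA = "ACGT", taxonB = "ACGT", ancient = "ACGT")
  expect_true(all(cladeSupportCounts(findSnpSites(makeAlignment(rows0)))
                  == 0L))
})

test_that("filter chain masks clipped ends, singletons and transitions", {
  # 10-base single block with clip 5 -> fully masked
  rows <- c(taxonA = "ACGTACGTAC", taxonB = "ACGTACGTCC",
            ancient = "ACGTACGTCC")
  expect_message(out <- filterAlignment(makeAlignment(rows), clip = 5),
                 "fully masked")
  expect_equal(nrow(findSnpSites(out)), 0)

  # singleton + transition: ancient T vs all-reference C -> masked
  rows2 <- c(taxonA = "AAACAAAAAAAA", taxonB = "AAACAAAAAAAA",
             ancient = "AAATAAAAAAAA")
  f2 <- filterAlignment(makeAlignment(rows2), clip = 0)
  expect_equal(nrow(findSnpSites(f2)), 0)

  # shared transversion survives: ancient G = taxonA, others T
  rows3 <- c(taxonA = "AAAGAAAAAAAA", taxonB = "AAATAAAAAAAA",
             taxonC = "AAATAAAAAAAA", ancient = "AAAGAAAAAAAA")
  f3 <- filterAlignment(makeAlignment(rows3), clip = 0)
  s3 <- findSnpSites(f3)
  expect_equal(nrow(s3), 1)
  expect_identical(s3$sharing, "taxonA")

  # shared transition (ancient A vs plurality G) is masked
  rows4 <- c(taxonA = "AAAAAAAAAAAA", taxonB = "AAAGAAAAAAAA",
             taxonC = "AAAGAAAAAAAA", ancient = "AAAAAAAAAAAA")
  f4 <- filterAlignment(makeAlignment(rows4), clip = 0)
  expect_equal(nrow(findSnpSites(f4)), 0)

  # completeness stage masks sites with reference gaps
  rows5 <- c(taxonA = "AAAGAAAAAAAA", taxonB = "AAA----AAAAA",
             taxonC = "AAATAAAAAAAA", taxonD = "AAATAAAAAAAA",
             ancient = "AAAGAAAAAAAA")
  f5a <- filterAlignment(makeAlignment(rows5), clip = 0)
  f5b <- filterAlignment(makeAlignment(rows5), clip = 0,
                         requireComplete = TRUE)
  expect_equal(nrow(findSnpSites(f5a)), 1)
  expect_equal(nrow(findSnpSites(f5b)), 0)
})

test_that("filtering is monotone: stricter filters keep fewer sites", {
  set.seed(31)
  sim <- simulateAlignment(nTaxa = 6, nReads = 8, readLen = 40,
                           plantedShares = c(taxonB = 5, taxonD = 2),
                           endDeamination = 0.5, seed = 31)
  aln <- sim$alignment
  posAt <- function(a) findSnpSites(a)$position
  stages <- list(
    filterAlignment(aln, clip = 5, dropSingletons = FALSE,
                    dropTransitions = FALSE),
    filterAlignment(aln, clip = 5, dropTransitions = FALSE),
    filterAlignment(aln, clip = 5),
    filterAlignment(aln, clip = 5, requireComplete = TRUE))
  for (k in 2:length(stages))
    expect_true(all(posAt(stages[[k]]) %in% posAt(stages[[k - 1]])))
})

test_that("clade counts equal per-column brute force on random alignments", {
  for (seed in c(5, 17, 23)) {
    sim <- simulateAlignment(nTaxa = 6, nReads = 8, readLen = 50,
                             plantedShares = c(taxonC = 6),
                             refDivergence = 0.06, seed = seed)
    got <- cladeSupportCounts(findSnpSites(sim$alignment))
    expect_identical(got, bruteForceCladeCounts(sim$alignment))
  }
})

test_that("alignment FASTA round trip preserves the masked rows", {
  sim <- simulateAlignment(nReads = 4, readLen = 30,
                           plantedShares = c(taxonA = 2), seed = 9)
  f <- tempfile(fileext = ".fasta")
  writeConcatAlignment(sim$alignment, f)
  back <- readConcatAlignment(f, "ancient")
  expect_identical(alignmentMatrix(back), alignmentMatrix(sim$alignment))
  expect_identical(cladeSupportCounts(findSnpSites(back)),
                   cladeSupportCounts(findSnpSites(sim$alignment)))
})
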