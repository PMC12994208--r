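## Dirichlet draws via normalised gammas; alpha recycled over columns.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  x / rowSums(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 for identical partitions, ~0 for independent ones.  Used to score
#' recovery of planted guild blocks by the clustering pipeline.
#'
#' @param a,b label vectors of equal length (`NA`s allowed; such objects
#'   are dropped pairwise).
#' @return the adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no jointly labelled objects")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxIdx <- (ai + bj) / 2
  if (maxIdx == expected) return(1)
  (nij - expected) / (maxIdx - expected)
}
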