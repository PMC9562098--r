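# Shared fixtures: compact phantoms keep the suite fast while leaving
# plenty of axial room for ridges up to 600 um above a 200 um baseline.

smallPhantomParams <- function(ridgeHeightUm = 300, speckleSnr = Inf,
                               nAxial = 300L, nFast = 48L, nSlow = 48L, ...) {
  phantomParams(
    nAxial = nAxial, nFast = nFast, nSlow = nSlow,
    ridgeHeightUm = ridgeHeightUm, speckleSnr = speckleSnr, ...
  )
}

smallPhantom <- function(ridgeHeightUm = 300, speckleSnr = Inf, seed = 1L,
                         ...) {
  generatePhantomVolume(
    smallPhantomParams(ridgeHeightUm = ridgeHeightUm,
      speckleSnr = speckleSnr, ...),
    seed = seed
  )
}

# truth surface rows sampled at (possibly fractional) en face positions,
# nearest-neighbour; positions are 0-based (slow, fast)
truthAt <- function(surface, positions) {
  i <- round(positions[, 1L]) + 1L
  j <- round(positions[, 2L]) + 1L
  surface[cbind(i, j)]
}

# independent sort-based oracle for the top-n statistic
topNOracle <- function(values, n = 10L) {
  sel <- rev(sort(values))[seq_len(min(n, length(values)))]
  list(mean = sum(sel) / length(sel),
       sd = sqrt(mean((sel - mean(sel))^2)),
       n = length(sel))
}

# independent weighted-kappa oracle straight from the contingency table
kappaOracle <- function(a, b, quadratic = FALSE) {
  lev <- sort(union(a, b))
  k <- length(lev)
  O <- matrix(0, k, k)
  for (i in seq_along(a)) {
    O[match(a[i], lev), match(b[i], lev)] <- O[match(a[i], lev), match(b[i], lev)] + 1
  }
  O <- O / sum(O)
  E <- outer(rowSums(O), colSums(O))
  W <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  if (quadratic) W <- W^2
  1 - sum(W * O) / sum(W * E)
}
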