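# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results by brute force / full dynamic
# programming, not by calling the code paths they verify.

# Full Gotoh affine-gap DP. A gap of length L costs open + ext * L.
# Returns the optimal global alignment score.
dpAlignScore <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  E <- matrix(NEG, n + 1, m + 1)  # ends in gap in A (consumes B)
  F <- matrix(NEG, n + 1, m + 1)  # ends in gap in B (consumes A)
  M[1, 1] <- 0
  for (j in seq_len(m)) E[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) F[i + 1, 1] <- -(open + ext * i)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], E[i, j], F[i, j]) + s
    E[i + 1, j + 1] <- max(E[i + 1, j] - ext,
                           M[i + 1, j] - open - ext,
                           F[i + 1, j] - open - ext)
    F[i + 1, j + 1] <- max(F[i, j + 1] - ext,
                           M[i, j + 1] - open - ext,
                           E[i, j + 1] - open - ext)
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

# Brute-force tandem clustering: transitive closure of the pairwise
# predicate |rank_i - rank_j| <= maxd over SRCR ranks, via explicit
# union-find over all pairs.
bruteForceClusters <- function(srcrRanks, maxd) {
  n <- length(srcrRanks)
  if (n == 0) return(list(clusters = list(), scattered = integer(0)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && abs(srcrRanks[i] - srcrRanks[j]) <= maxd) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(srcrRanks, comp)
  sc <- unlist(groups[lengths(groups) == 1], use.names = FALSE)
  list(clusters = unname(lapply(groups[lengths(groups) >= 2], sort)),
       scattered = if (is.null(sc)) integer(0) else as.integer(sort(sc)))
}

# Per-base projection oracle: walks the spliced CDS one nucleotide at a
# time through the CDS segments and collects the genomic positions covered
# by an amino-acid interval.
perBaseProjection <- function(models, gene_id, start_aa, end_aa) {
  cd <- geneCds(models)[[gene_id]]
  gpos <- integer(0)
  for (j in seq_along(cd)) {
    s <- GenomicRanges::start(cd)[j]; e <- GenomicRanges::end(cd)[j]
    gpos <- c(gpos, if (as.character(BiocGenerics::strand(cd)[j]) == "-")
      seq(e, s) else seq(s, e))
  }
  nt <- (3 * (start_aa - 1) + 1):(3 * end_aa)
  sort(gpos[nt])
}

# Exhaustive duplication-unit oracle: enumerates segmentations into blocks
# of sizes 1/2 from a precomputed identity matrix, scoring the mean identity
# over same-size block pairs, ties to more blocks, and derives the type.
oracleDuplicationType <- function(idm, theta = 60) {
  n <- nrow(idm)
  if (n < 2) return(NA_character_)
  segs <- list()
  grow <- function(blocks, used) {
    if (used == n) { segs[[length(segs) + 1]] <<- blocks; return(invisible()) }
    grow(c(blocks, list(used + 1)), used + 1)
    if (used + 2 <= n) grow(c(blocks, list(c(used + 1, used + 2))), used + 2)
  }
  grow(list(), 0)
  score <- function(seg) {
    v <- c()
    for (i in seq_along(seg)) for (j in seq_len(i - 1)) {
      if (length(seg[[i]]) == length(seg[[j]]))
        v <- c(v, mean(idm[cbind(seg[[i]], seg[[j]])]))
    }
    if (length(v)) mean(v) else -Inf
  }
  sc <- vapply(segs, score, numeric(1))
  nb <- vapply(segs, length, integer(1))
  best <- order(-sc, -nb)[1]
  if (!is.finite(sc[best]) || sc[best] < theta) return(NA_character_)
  sz <- lengths(segs[[best]])
  if (all(sz == 1)) "Type1" else if (all(sz == 2)) "Type2" else "Type3/4"
}
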