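# Independent per-base brute-force liftOver oracle: walks every query base
# through every chain's block arithmetic and applies the same best-chain
# rule (most mapped bases, then score, then input order) as mapInterval.
bruteForceMap <- function(q, chains, minMappedFraction = 0.95) {
  qs0 <- GenomicRanges::start(q) - 1L
  qe0 <- GenomicRanges::end(q)
  w <- qe0 - qs0
  best <- NULL
  for (ci in seq_along(chains@chains)) {
    ch <- chains[[ci]]
    if (ch@sChrom != as.character(GenomicRanges::seqnames(q))) next
    b <- ch@blocks
    tpos <- c()
    for (base in qs0:(qe0 - 1L)) {
      sPos <- ch@sStart; tP <- ch@tStart
      for (i in seq_len(nrow(b))) {
        if (base >= sPos && base < sPos + b$size[i]) {
          tt <- tP + (base - sPos)
          if (ch@tStrand == "-") tt <- ch@tSize - 1L - tt
          tpos <- c(tpos, tt)
          break
        }
        sPos <- sPos + b$size[i] + b$dt[i]
        tP <- tP + b$size[i] + b$dq[i]
      }
    }
    if (length(tpos) == 0L) next
    cand <- list(n = length(tpos), score = ch@score, ord = ci,
                 chrom = ch@tChrom, lo = min(tpos), hi = max(tpos) + 1L)
    if (is.null(best) || cand$n > best$n ||
        (cand$n == best$n && cand$score > best$score) ||
        (cand$n == best$n && cand$score == best$score && cand$ord < best$ord))
      best <- cand
  }
  if (is.null(best) || best$n / w < minMappedFraction)
    return(list(status = "unmapped"))
  list(status = "full", chrom = best$chrom, start = best$lo + 1L,
       end = best$hi)
}

# exhaustive upper-tail hypergeometric oracle from first principles
hyperUpperEnum <- function(k, K, n, N) {
  js <- k:min(K, n)
  js <- js[js >= max(0L, n - (N - K))]
  if (length(js) == 0L) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# exhaustive Fisher exact (two-sided, minimum-likelihood) oracle on a
# 2x2 table with fixed margins, probabilities from first principles
fisherEnum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  as <- max(0L, c1 - (n - r1)):min(r1, c1)
  pr <- vapply(as, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), numeric(1))
  pObs <- pr[match(a, as)]
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# small convenience constructor for hand-built chains
makeChain <- function(sChrom, sSize, sStart, tChrom, tSize, tStart,
                      blocks, tStrand = "+", score = 1000, id = "1") {
  blocks <- as.data.frame(blocks)
  new("Chain", score = score, sChrom = sChrom, sSize = sSize,
      sStart = sStart, sEnd = sStart + sum(blocks$size + blocks$dt),
      tChrom = tChrom, tSize = tSize, tStrand = tStrand,
      tStart = tStart, tEnd = tStart + sum(blocks$size + blocks$dq),
      blocks = blocks, id = id)
}

oneBlock <- function(size) data.frame(size = size, dt = 0L, dq = 0L)
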