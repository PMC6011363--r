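# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force enumeration, union-find, and
# closed-form log-pmfs.

# Base-level NAT classification oracle: test which transcript terminal
# bases (5'/3' on each strand) fall inside the overlap interval.
# Coordinates 1-based closed; P on "+", M on "-".
oracleClassify <- function(pS, pE, mS, mE) {
  oS <- max(pS, mS); oE <- min(pE, mE)
  stopifnot(oS <= oE)
  inside <- function(x) x >= oS & x <= oE
  p5 <- pS; p3 <- pE       # + strand: 5' = leftmost base
  m5 <- mE; m3 <- mS       # - strand: 5' = rightmost base
  if ((inside(p5) && inside(p3)) || (inside(m5) && inside(m3)))
    return("fully_overlapping")
  if (inside(p5) && inside(m5)) return("head_to_head")
  if (inside(p3) && inside(m3)) return("tail_to_tail")
  stop("oracle: unclassifiable geometry")
}

# Connected components of the brute-force O(n^2) span-overlap graph,
# via union-find.  Returns component labels renumbered in first-seen order.
oracleComponents <- function(chr, st, en, minOverlap = 1L) {
  n <- length(st)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (chr[i] != chr[j]) next
    ov <- min(en[i], en[j]) - max(st[i], st[j]) + 1L
    if (ov >= minOverlap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# All-pairs opposite-strand overlap filter (ignores units entirely).
oracleNatPairs <- function(ts, minOverlap = 1L) {
  sp <- txSpans(ts)
  st <- GenomicRanges::start(sp); en <- GenomicRanges::end(sp)
  chr <- as.character(GenomicRanges::seqnames(sp))
  str <- as.character(GenomicRanges::strand(sp))
  ids <- names(sp)
  out <- list()
  for (i in which(str == "+")) for (j in which(str == "-")) {
    if (chr[i] != chr[j]) next
    ov <- min(en[i], en[j]) - max(st[i], st[j]) + 1L
    if (ov < minOverlap) next
    out[[length(out) + 1L]] <- data.frame(
      plus_tx = ids[i], minus_tx = ids[j],
      nat_class = oracleClassify(st[i], en[i], st[j], en[j]))
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$plus_tx, df$minus_tx), , drop = FALSE]
}

# Closed-form log-pmf of a pooled group count (sum of n iid NB(mu, phi)),
# written from the gamma-function definition, independent of dnbinom.
oracleLogPmfPooled <- function(k, mu, n, phi) {
  if (phi == 0) return(k * log(mu) - mu - lgamma(k + 1))
  r <- n / phi                       # pooled size parameter
  p <- r / (r + mu)                  # success prob; mean mu
  lgamma(k + r) - lgamma(r) - lgamma(k + 1) + r * log(p) + k * log1p(-p)
}

# Exhaustive conditional exact test over all splits of the total.
oracleNBExact <- function(a, b, nA, nB, phi) {
  t <- a + b
  if (t == 0) return(1)
  ap <- 0:t
  muA <- t * nA / (nA + nB)
  muB <- t * nB / (nA + nB)
  lp <- oracleLogPmfPooled(ap, muA, nA, phi) +
        oracleLogPmfPooled(t - ap, muB, nB, phi)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[a + 1L] * (1 + 1e-10)]))
}

# Upper-tail hypergeometric probability by direct summation of
# choose-products.
oracleHyper <- function(N, K, n, k) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Random multi-exon transcripts for round-trip and junction tests.
randomTranscriptSet <- function(n, seed, chroms = c("chr1", "chr2"),
                                maxExons = 4L) {
  set.seed(seed)
  exl <- list()
  gene <- character(0)
  for (i in seq_len(n)) {
    nex <- sample.int(maxExons, 1)
    st <- integer(nex); en <- integer(nex)
    pos <- sample.int(1e6, 1)
    for (k in seq_len(nex)) {
      st[k] <- pos
      en[k] <- pos + sample(50:300, 1)
      pos <- en[k] + sample(30:500, 1) + 1L
    }
    id <- sprintf("tx%04d", i)
    exl[[id]] <- GenomicRanges::GRanges(
      sample(chroms, 1), IRanges::IRanges(st, en),
      strand = sample(c("+", "-"), 1))
    gene <- c(gene, sprintf("g%04d", (i + 1) %/% 2))
  }
  TranscriptSet(GenomicRanges::GRangesList(exl), geneIds = gene)
}

# Random overlapping opposite-strand span pair (1-based closed).
randomOverlappingPair <- function() {
  pS <- sample.int(10000L, 1)
  pE <- pS + sample.int(2000L, 1)
  oS <- sample(pS:pE, 1)             # force one shared base
  mS <- oS - sample.int(1500L, 1) + 1L
  mE <- oS + sample.int(1500L, 1) - 1L
  c(pS = pS, pE = pE, mS = mS, mE = mE)
}
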