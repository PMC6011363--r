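mkTs <- function(st, en, strand, chrom = "chr1") {
  exl <- lapply(seq_along(st), function(i)
    GRanges(chrom[min(i, length(chrom))], IRanges(st[i], en[i]),
            strand = strand[i]))
  names(exl) <- sprintf("tx%02d", seq_along(st))
  TranscriptSet(GRangesList(exl))
}

test_that("transcript-unit clustering is single-linkage on span overlap", {
  # [1,100]+ and [51,150]- share a locus; [201,300]+ is separate
  ts <- mkTs(c(1, 51, 201), c(100, 150, 300), c("+", "-", "+"))
  u <- clusterTranscriptUnits(ts)
  expect_equal(unname(u), c(1, 1, 2))

  # pairwise-adjacent chain joins into one unit through transitive closure
  ts2 <- mkTs(c(1, 91, 191), c(100, 200, 300), c("+", "+", "+"))
  expect_equal(unname(clusterTranscriptUnits(ts2)), c(1, 1, 1))

  # with minOverlap = 20 the 10-nt links break
  expect_equal(length(unique(clusterTranscriptUnits(ts2, minOverlap = 20))),
               3L)
})

test_that("clustering equals brute-force overlap-graph components on 500 random spans", {
  set.seed(101)
  n <- 500
  chr <- sample(c("chr1", "chr2"), n, replace = TRUE)
  st <- sample.int(50000L, n, replace = TRUE)
  en <- st + sample(50:2000, n, replace = TRUE)
  exl <- lapply(seq_len(n), function(i)
    GRanges(chr[i], IRanges(st[i], en[i]),
            strand = sample(c("+", "-"), 1)))
  names(exl) <- sprintf("t%03d", seq_len(n))
  ts <- TranscriptSet(GRangesList(exl))
  for (minOv in c(1L, 25L)) {
    u <- clusterTranscriptUnits(ts, minOverlap = minOv)
    cc <- oracleComponents(chr, st, en, minOverlap = minOv)
    # same partition: units and components agree up to relabelling
    expect_equal(length(unique(u)), length(unique(cc)))
    expect_true(all(tapply(cc, u, function(v) length(unique(v))) == 1))
    expect_true(all(tapply(u, cc, function(v) length(unique(v))) == 1))
  }
})

test_that("classifyOverlap matches the staggered/containment taxonomy on worked cases", {
  # 0-based half-open P=[100,500), M=[50,300) is 1-based P=[101,500], M=[51,300]
  expect_equal(classifyOverlap(101, 500, 51, 300), "head_to_head")
  expect_equal(classifyOverlap(101, 500, 201, 300), "fully_overlapping")
  expect_equal(classifyOverlap(101, 500, 401, 700), "tail_to_tail")
  # identical spans: containment includes equality
  expect_equal(classifyOverlap(101, 500, 101, 500), "fully_overlapping")
  # plus containment inside minus
  expect_equal(classifyOverlap(201, 300, 101, 500), "fully_overlapping")
  expect_error(classifyOverlap(1, 100, 200, 300), "overlap")
})

test_that("classification agrees with the terminal-base oracle and is exclusive", {
  set.seed(7)
  for (rep in 1:500) {
    p <- randomOverlappingPair()
    got <- unname(classifyOverlap(p["pS"], p["pE"], p["mS"], p["mE"]))
    expect_equal(got, oracleClassify(p["pS"], p["pE"], p["mS"], p["mE"]),
                 info = paste(p, collapse = ","))
    expect_true(got %in% c("head_to_head", "tail_to_tail",
                           "fully_overlapping"))
  }
})

test_that("findNatPairs enumerates all opposite-strand pairs within units", {
  # one + and one - overlapping: exactly one pair
  ts <- mkTs(c(101, 51), c(500, 300), c("+", "-"))
  nps <- findNatPairs(ts)
  expect_equal(length(nps), 1L)
  df <- as.data.frame(nps)
  expect_equal(df$nat_class, "head_to_head")
  expect_equal(c(df$overlap_start, df$overlap_end), c(101, 300))
  expect_equal(df$overlap_len, 200)

  # 2 plus x 2 minus all mutually overlapping: 4 pairs
  ts2 <- mkTs(c(1, 51, 26, 76), c(200, 250, 220, 260),
              c("+", "+", "-", "-"))
  expect_equal(length(findNatPairs(ts2)), 4L)
})

test_that("pair calling equals the brute-force all-pairs filter on random loci", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    pos <- sample.int(5000L, 1)
    st <- pos + sample.int(3000L, n, replace = TRUE)
    en <- st + sample(100:1500, n, replace = TRUE)
    ts <- mkTs(st, en, sample(c("+", "-"), n, replace = TRUE))
    got <- as.data.frame(findNatPairs(ts, minOverlap = 50))
    want <- oracleNatPairs(ts, minOverlap = 50)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$plus_tx, want$plus_tx)
      expect_equal(got$minus_tx, want$minus_tx)
      expect_equal(got$nat_class, want$nat_class)
    }
  }
})

test_that("pair and class are invariant to generation order; lncNAT follows the noncoding flag", {
  g1 <- GRanges("chr1", IRanges(101, 500), strand = "+")
  g2 <- GRanges("chr1", IRanges(401, 700), strand = "-")
  a <- TranscriptSet(GRangesList(P = g1, M = g2),
                     noncoding = c(FALSE, TRUE))
  b <- TranscriptSet(GRangesList(M = g2, P = g1),
                     noncoding = c(TRUE, FALSE))
  da <- as.data.frame(findNatPairs(a))
  db <- as.data.frame(findNatPairs(b))
  expect_equal(da[c("plus_tx", "minus_tx", "nat_class", "overlap_len")],
               db[c("plus_tx", "minus_tx", "nat_class", "overlap_len")])
  expect_true(da$lnc_nat)
})

test_that("NAT pair TSV/BED outputs carry the documented columns", {
  ts <- mkTs(c(101, 51), c(500, 300), c("+", "-"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeNatPairs(findNatPairs(ts), tsv, bed)
  tab <- read.delim(tsv)
  expect_true(all(c("plus_tx", "minus_tx", "chrom", "overlap_start",
                    "overlap_end", "overlap_len", "nat_class", "lnc_nat")
                  %in% colnames(tab)))
  bl <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(bl[2]), 100L)  # BED is 0-based
  expect_equal(as.integer(bl[3]), 300L)
})
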