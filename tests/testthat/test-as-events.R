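iso <- function(st, en, strand = "+", chrom = "chr1")
  GRanges(chrom, IRanges(st, en), strand = strand)

twoIso <- function(a, b, strand = "+") {
  ts <- TranscriptSet(GRangesList(A = iso(a$st, a$en, strand),
                                  B = iso(b$st, b$en, strand)),
                      geneIds = c("g", "g"))
  ts
}

test_that("junction extraction deduplicates shared introns and matches re-enumeration", {
  ts <- TranscriptSet(GRangesList(
    A = iso(c(101, 301), c(200, 400)),
    B = iso(c(101, 301, 601), c(200, 400, 700))),
    geneIds = c("g", "g"))
  j <- extractJunctions(ts)
  expect_equal(nrow(j), 2L)              # shared intron counted once
  expect_equal(j$donor, c(200, 400))
  expect_equal(j$acceptor, c(300, 600))

  ts2 <- randomTranscriptSet(60, seed = 5)
  j2 <- extractJunctions(ts2)
  # brute-force re-enumeration of all exon gaps
  want <- unique(do.call(rbind, lapply(seq_len(length(ts2)), function(i) {
    g <- txExons(ts2)[[i]]
    if (length(g) < 2) return(NULL)
    data.frame(chrom = as.character(seqnames(g))[1],
               donor = head(end(g), -1), acceptor = start(g)[-1] - 1,
               strand = as.character(strand(g))[1])
  })))
  expect_equal(nrow(j2), nrow(want))
  expect_setequal(j2$key, junctionKey(want$chrom, want$donor + 1,
                                      want$acceptor, want$strand))
})

test_that("the four event types are detected from their defining geometries", {
  # IR: intron of A inside the single exon of B (0-based [100,200) plan)
  ir <- enumerateEvents(twoIso(list(st = c(1, 201), en = c(100, 300)),
                               list(st = 1, en = 300)))
  expect_equal(length(ir), 1L)
  dfi <- as.data.frame(ir)
  expect_equal(dfi$event_type, "IR")
  expect_equal(c(dfi$alt_start, dfi$alt_end), c(101, 200))
  expect_equal(dfi$inclusion_iso, "B")   # B retains the intron

  # ES: middle exon of A skipped by B
  es <- enumerateEvents(twoIso(
    list(st = c(1, 201, 401), en = c(100, 300, 500)),
    list(st = c(1, 401), en = c(100, 500))))
  dfe <- as.data.frame(es)
  expect_equal(dfe$event_type, "ES")
  expect_equal(c(dfe$alt_start, dfe$alt_end), c(201, 300))
  expect_equal(dfe$inclusion_iso, "A")

  # shared donor, shifted acceptor: AltA on +, AltD when the same
  # geometry sits on the - strand
  geomA <- list(st = c(1, 201), en = c(100, 300))
  geomB <- list(st = c(1, 251), en = c(100, 300))
  aa <- as.data.frame(enumerateEvents(twoIso(geomA, geomB, "+")))
  expect_equal(aa$event_type, "AltA")
  expect_equal(c(aa$alt_start, aa$alt_end), c(201, 250))
  ad <- as.data.frame(enumerateEvents(twoIso(geomA, geomB, "-")))
  expect_equal(ad$event_type, "AltD")

  # single isoform: empty result, not an error
  one <- TranscriptSet(GRangesList(A = iso(c(1, 201), c(100, 300))))
  expect_equal(length(enumerateEvents(one)), 0L)
})

test_that("event enumeration is symmetric in isoform order and translation-invariant", {
  a <- list(st = c(1, 201, 401), en = c(100, 300, 500))
  b <- list(st = c(1, 401), en = c(100, 500))
  e1 <- as.data.frame(enumerateEvents(twoIso(a, b)))
  ts2 <- TranscriptSet(GRangesList(B = iso(b$st, b$en),
                                   A = iso(a$st, a$en)),
                       geneIds = c("g", "g"))
  e2 <- as.data.frame(enumerateEvents(ts2))
  expect_equal(e1[c("event_type", "alt_start", "alt_end")],
               e2[c("event_type", "alt_start", "alt_end")])

  shift <- 10000L
  e3 <- as.data.frame(enumerateEvents(twoIso(
    lapply(a, `+`, shift), lapply(b, `+`, shift))))
  expect_equal(e3$alt_start, e1$alt_start + shift)
  expect_equal(e3$event_type, e1$event_type)
})

test_that("event support counting and PSI normalisation follow the definitions", {
  es <- enumerateEvents(twoIso(
    list(st = c(1, 201, 401), en = c(100, 300, 500)),
    list(st = c(1, 401), en = c(100, 500))))
  m <- S4Vectors::mcols(asEvents(es))
  incK <- strsplit(m$inclusion_junctions, ",")[[1]]
  jc <- do.call(rbind, lapply(
    list(c(incK[1], 10), c(incK[2], 12), c(m$exclusion_junctions, 11)),
    function(x) {
      p <- strsplit(x[1], ":")[[1]]
      da <- as.integer(strsplit(p[2], "-")[[1]])
      data.frame(chrom = p[1], donor = da[1], acceptor = da[2],
                 strand = p[3], sample = "s1",
                 count = as.integer(x[2]))
    }))
  evc <- countEventSupport(es, jc)
  expect_equal(evc$inclusion, 22)
  expect_equal(evc$exclusion, 11)
  # raw (unnormalised) inclusion fraction is 22/33
  expect_equal(evc$inclusion / (evc$inclusion + evc$exclusion), 2 / 3,
               tolerance = 1e-9)
  # effective-length normalised PSI divides by 2 inclusion junctions
  expect_equal(evc$psi, (22 / 2) / (22 / 2 + 11), tolerance = 1e-9)

  # all-zero support: PSI undefined
  jc0 <- jc; jc0$count <- 0L
  expect_true(is.na(countEventSupport(es, jc0)$psi))
})

test_that("PSI estimate is unbiased near a planted value at deep coverage", {
  cfg <- simulationConfig(seed = 33, nUnits = 0, nAsGenes = 40,
                          nFeatures = 0, fracDifferential = 0,
                          asFragments = 2000)
  ann <- generateAnnotation(cfg)
  sim <- simulateCounts(ann$truth, cfg)
  aes <- enumerateEvents(ann$transcripts)
  evc <- countEventSupport(aes, sim$junctionCounts, sim$regionCoverage,
                           readLength = cfg$readLength)
  df <- as.data.frame(aes)
  key <- paste(df$gene_id, df$alt_start)
  tkey <- paste(ann$truth$asEvents$gene_id, ann$truth$asEvents$region_start)
  planted <- ann$truth$asEvents$psi_a[match(key, tkey)]
  est <- tapply(evc$psi, factor(evc$event_id, df$event_id), mean,
                na.rm = TRUE)
  expect_true(all(abs(est - planted) < 0.05))
})

test_that("the pooled binomial LRT behaves at its boundary and separated cases", {
  evc <- data.frame(
    event_id = "e1", sample = c("a1", "a2", "b1", "b2"),
    inclusion = c(30, 30, 30, 30), exclusion = c(10, 10, 10, 10),
    psi = NA)
  cond <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expect_equal(testDifferentialAS(evc, cond)$p_value, 1)

  evc2 <- data.frame(event_id = "e1", sample = c("a1", "b1"),
                     inclusion = c(90, 10), exclusion = c(10, 90),
                     psi = NA)
  res <- testDifferentialAS(evc2, c(a1 = "A", b1 = "B"))
  expect_lt(res$p_value, 1e-6)

  # below the count floor: untestable, p = 1
  evc3 <- data.frame(event_id = "e1", sample = c("a1", "b1"),
                     inclusion = c(2, 0), exclusion = c(1, 3), psi = NA)
  expect_equal(testDifferentialAS(evc3, c(a1 = "A", b1 = "B"))$p_value, 1)
  expect_error(testDifferentialAS(evc3, c(a1 = "A", b1 = "A")),
               "two conditions")
})
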