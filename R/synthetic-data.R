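#' @include AllClasses.R AllGenerics.R quantify.R
NULL

#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: two conditions
#' (GA3 treatment vs H2O mock), three biological replicates each, dUTP
#' strand-specific libraries of 1e6 fragments, 125-nt reads, and an
#' annotation carrying cis-NAT pairs of all three overlap classes plus
#' two-isoform genes realising all four AS event types.
#'
#' @param seed Integer RNG seed; every generator output is a deterministic
#'   function of it.
#' @param nUnits Number of planted NAT loci (one opposite-strand pair each).
#' @param natClassMix Proportions over the three NAT classes (sum 1).
#' @param nAsGenes Number of planted two-isoform AS genes.
#' @param asTypeMix Proportions over IR/ES/AltA/AltD (sum 1).
#' @param nFeatures Target number of expression features; filler
#'   single-exon genes pad the annotation up to this.
#' @param fracDifferential Fraction of features (and of AS events) planted
#'   as differential.
#' @param log2fcMagnitude |log2 fold change| of differential features.
#' @param dispersion NB dispersion of simulated counts (0 = Poisson).
#' @param librarySize Fragments per library.
#' @param replicates Biological replicates per condition.
#' @param readLength Read length in nt (IR effective-length term).
#' @param deltaPsi PSI shift of differential AS events.
#' @param asFragments Junction-supporting fragments per event per
#'   condition.
#' @param chlNoiseSd Gaussian noise sd on simulated absorbances.
#' @param gasNoiseSd Gaussian noise sd on simulated net-photosynthesis
#'   targets.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nUnits = 30L,
                             natClassMix = c(head_to_head = 1/3,
                                             tail_to_tail = 1/3,
                                             fully_overlapping = 1/3),
                             nAsGenes = 40L,
                             asTypeMix = c(IR = 0.25, ES = 0.25,
                                           AltA = 0.25, AltD = 0.25),
                             nFeatures = 2000L, fracDifferential = 0.1,
                             log2fcMagnitude = 2, dispersion = 0.1,
                             librarySize = 1e6, replicates = 3L,
                             readLength = 125L, deltaPsi = 0.3,
                             asFragments = 200L, chlNoiseSd = 0.02,
                             gasNoiseSd = 0.8) {
  cfg <- list(seed = as.integer(seed), nUnits = as.integer(nUnits),
              natClassMix = natClassMix, nAsGenes = as.integer(nAsGenes),
              asTypeMix = asTypeMix, nFeatures = as.integer(nFeatures),
              fracDifferential = fracDifferential,
              log2fcMagnitude = log2fcMagnitude, dispersion = dispersion,
              librarySize = librarySize, replicates = as.integer(replicates),
              readLength = as.integer(readLength), deltaPsi = deltaPsi,
              asFragments = as.integer(asFragments),
              chlNoiseSd = chlNoiseSd, gasNoiseSd = gasNoiseSd)
  if (abs(sum(cfg$natClassMix) - 1) > 1e-8 ||
      abs(sum(cfg$asTypeMix) - 1) > 1e-8)
    stop("class/type mixes must each sum to 1")
  if (any(c(cfg$nUnits, cfg$nAsGenes, cfg$nFeatures, cfg$replicates) < 0))
    stop("counts must be >= 0")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  class(cfg) <- "SimulationConfig"
  cfg
}

# integer allocation of n over proportions p (largest-remainder-free,
# cumulative rounding keeps determinism and sums to n)
.allocate <- function(n, p) {
  cs <- round(cumsum(p) * n)
  diff(c(0, cs))
}

# planted AS-gene geometry for one type on one strand; s = left anchor.
# Returns exon chains for isoforms .1/.2 plus the truth row pieces.
.asGeometry <- function(type, strand, s, chrom) {
  e1 <- sample(80:150, 1); e2 <- sample(80:150, 1); e3 <- sample(80:150, 1)
  i1 <- sample(100:200, 1); i2 <- sample(100:200, 1)
  d <- sample(30:60, 1)
  jk <- function(is, ie) junctionKey(chrom, is, ie, strand)
  if (type == "IR") {
    a <- list(st = c(s, s + e1 + i1), en = c(s + e1 - 1, s + e1 + i1 + e2 - 1))
    b <- list(st = s, en = s + e1 + i1 + e2 - 1)
    rs <- s + e1; re <- s + e1 + i1 - 1
    list(a = a, b = b, rs = rs, re = re,
         incJ = "", excJ = jk(rs, re), incIso = 2L, excIso = 1L)
  } else if (type == "ES") {
    s2 <- s + e1 + i1; s3 <- s2 + e2 + i2
    a <- list(st = c(s, s2, s3), en = c(s + e1 - 1, s2 + e2 - 1, s3 + e3 - 1))
    b <- list(st = c(s, s3), en = c(s + e1 - 1, s3 + e3 - 1))
    list(a = a, b = b, rs = s2, re = s2 + e2 - 1,
         incJ = paste(jk(s + e1, s2 - 1), jk(s2 + e2, s3 - 1), sep = ","),
         excJ = jk(s + e1, s3 - 1), incIso = 1L, excIso = 2L)
  } else {
    # boundary-shift geometries; which genomic side shifts depends on the
    # planted type and the strand (AltA/AltD are named 5'->3')
    rightShift <- (type == "AltA" && strand == "+") ||
                  (type == "AltD" && strand == "-")
    s2 <- s + e1 + i1
    if (rightShift) {
      a <- list(st = c(s, s2), en = c(s + e1 - 1, s2 + d + e2 - 1))
      b <- list(st = c(s, s2 + d), en = c(s + e1 - 1, s2 + d + e2 - 1))
      list(a = a, b = b, rs = s2, re = s2 + d - 1,
           incJ = jk(s + e1, s2 - 1), excJ = jk(s + e1, s2 + d - 1),
           incIso = 1L, excIso = 2L)
    } else {
      a <- list(st = c(s, s2), en = c(s + e1 - 1, s2 + e2 - 1))
      b <- list(st = c(s, s2), en = c(s + e1 + d - 1, s2 + e2 - 1))
      list(a = a, b = b, rs = s + e1, re = s + e1 + d - 1,
           incJ = jk(s + e1 + d, s2 - 1), excJ = jk(s + e1, s2 - 1),
           incIso = 2L, excIso = 1L)
    }
  }
}

#' Generate a synthetic annotation with planted ground truth
#'
#' Lays out, on one synthetic chromosome (\code{"chrS"}), one opposite-
#' strand transcript pair per planted NAT locus with geometry realising
#' exactly the planted overlap class, one two-isoform gene per planted AS
#' event realising exactly the planted type, and single-exon filler genes
#' up to \code{nFeatures} features.  Loci are separated by >= 1 kb so no
#' unplanted overlaps arise.  Deterministic given \code{config$seed}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return list with \code{transcripts} (a \code{\link{TranscriptSet}}) and
#'   \code{truth} (planted NAT pairs, AS events with per-condition PSI,
#'   differential features with signed log2fc, feature lengths).
#' @export
generateAnnotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  chrom <- "chrS"
  gap <- 1000L
  cursor <- 1000L
  exl <- list(); gene <- character(0); nc <- logical(0)

  natClasses <- rep(NAT_CLASSES, .allocate(config$nUnits,
                                           config$natClassMix))
  natTruth <- list()
  for (u in seq_along(natClasses)) {
    cls <- natClasses[u]
    Lp <- sample(800:2000, 1)
    pS <- cursor + 600L; pE <- pS + Lp - 1L
    if (cls == "head_to_head") {
      ov <- sample(100:(Lp - 100), 1); ext <- sample(100:500, 1)
      mS <- pS - ext; mE <- pS + ov - 1L
    } else if (cls == "tail_to_tail") {
      ov <- sample(100:(Lp - 100), 1); ext <- sample(100:500, 1)
      mS <- pE - ov + 1L; mE <- pE + ext
    } else {
      a <- sample(50:200, 1); b <- sample(50:200, 1)
      mS <- pS + a; mE <- pE - b
    }
    pid <- sprintf("NATP%03d", u); mid <- sprintf("NATM%03d", u)
    exl[[pid]] <- GRanges(chrom, IRanges(pS, pE), strand = "+")
    exl[[mid]] <- GRanges(chrom, IRanges(mS, mE), strand = "-")
    gene <- c(gene, pid, mid)
    isNc <- stats::runif(1) < 0.5
    nc <- c(nc, FALSE, isNc)
    natTruth[[u]] <- data.frame(plus_tx = pid, minus_tx = mid,
                                nat_class = cls, lnc_nat = isNc)
    cursor <- max(pE, mE) + gap
  }

  asTypes <- rep(AS_TYPES, .allocate(config$nAsGenes, config$asTypeMix))
  nDiffAs <- round(config$fracDifferential * length(asTypes))
  diffAs <- if (length(asTypes))
    sample(seq_along(asTypes), nDiffAs) else integer(0)
  asTruth <- list()
  for (g in seq_along(asTypes)) {
    strand <- sample(c("+", "-"), 1)
    geo <- .asGeometry(asTypes[g], strand, cursor, chrom)
    gid <- sprintf("ASG%03d", g)
    id1 <- paste0(gid, ".1"); id2 <- paste0(gid, ".2")
    exl[[id1]] <- GRanges(chrom, IRanges(geo$a$st, geo$a$en), strand = strand)
    exl[[id2]] <- GRanges(chrom, IRanges(geo$b$st, geo$b$en), strand = strand)
    gene <- c(gene, gid, gid)
    nc <- c(nc, FALSE, FALSE)
    psiA <- stats::runif(1, 0.35, 0.65)
    psiB <- psiA
    if (g %in% diffAs)
      psiB <- if (psiA + config$deltaPsi <= 0.95)
        psiA + config$deltaPsi else psiA - config$deltaPsi
    asTruth[[g]] <- data.frame(
      gene_id = gid, event_type = asTypes[g], chrom = chrom,
      region_start = geo$rs, region_end = geo$re, strand = strand,
      inclusion_iso = c(id1, id2)[geo$incIso],
      exclusion_iso = c(id1, id2)[geo$excIso],
      inclusion_junctions = geo$incJ, exclusion_junctions = geo$excJ,
      psi_a = psiA, psi_b = psiB, differential = g %in% diffAs)
    cursor <- max(geo$a$en, geo$b$en) + gap
  }

  nFill <- max(0L, config$nFeatures - length(exl))
  for (f in seq_len(nFill)) {
    L <- sample(500:3000, 1)
    gid <- sprintf("G%05d", f)
    exl[[gid]] <- GRanges(chrom, IRanges(cursor, cursor + L - 1L),
                          strand = sample(c("+", "-"), 1))
    gene <- c(gene, gid)
    nc <- c(nc, FALSE)
    cursor <- cursor + L + gap
  }

  ts <- TranscriptSet(GRangesList(exl), geneIds = gene, noncoding = nc)
  ids <- txData(ts)$transcript_id
  lens <- vapply(seq_len(length(ts)),
                 function(i) sum(width(txExons(ts)[[i]])), numeric(1))
  rho <- stats::rlnorm(length(ids), meanlog = 0, sdlog = 1)
  rho <- rho / sum(rho)
  nDiff <- round(config$fracDifferential * length(ids))
  diffIdx <- sample(seq_along(ids), nDiff)
  lfc <- numeric(length(ids))
  lfc[diffIdx] <- sample(c(-1, 1), nDiff, replace = TRUE) *
    config$log2fcMagnitude
  feat <- data.frame(feature_id = ids, exonic_length = lens,
                     base_rel = rho, log2fc = lfc,
                     differential = seq_along(ids) %in% diffIdx)
  truth <- list(
    natPairs = if (length(natTruth)) do.call(rbind, natTruth) else NULL,
    asEvents = if (length(asTruth)) do.call(rbind, asTruth) else NULL,
    features = feat)
  list(transcripts = ts, truth = truth)
}

#' Simulate strand-specific fragment counts and junction support
#'
#' Feature counts are negative-binomial around means proportional to the
#' planted relative expression scaled to the library size, with condition-B
#' means shifted by the planted log2 fold changes (\code{dispersion = 0}
#' gives Poisson).  Junction support per AS event is binomial around the
#' planted per-condition PSI after effective-length weighting, so the PSI
#' estimator in \code{\link{countEventSupport}} is unbiased for the
#' planted value.  Samples are named \code{H2O_1..} and \code{GA3_1..}.
#'
#' @param truth Truth table from \code{\link{generateAnnotation}}.
#' @param config The same \code{\link{simulationConfig}}.
#' @return list: \code{se} (counts as \code{SummarizedExperiment}),
#'   \code{junctionCounts} and \code{regionCoverage} data.frames (inputs
#'   of \code{\link{countEventSupport}}).
#' @export
simulateCounts <- function(truth, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  R <- config$replicates
  samples <- c(paste0("H2O_", seq_len(R)), paste0("GA3_", seq_len(R)))
  condition <- setNames(rep(c("H2O", "GA3"), each = R), samples)
  feat <- truth$features
  muA <- feat$base_rel * config$librarySize
  mu <- cbind(matrix(rep(muA, R), ncol = R),
              matrix(rep(muA * 2^feat$log2fc, R), ncol = R))
  draw <- function(m) {
    if (config$dispersion == 0) stats::rpois(length(m), m)
    else stats::rnbinom(length(m), size = 1 / config$dispersion, mu = m)
  }
  cm <- apply(mu, 2, draw)
  dimnames(cm) <- list(feat$feature_id, samples)
  se <- countMatrix(cm, condition = condition,
                    librarySize = setNames(rep(config$librarySize, 2 * R),
                                           samples),
                    featureLength = feat$exonic_length)

  jrows <- list(); rrows <- list()
  ev <- truth$asEvents
  if (!is.null(ev) && nrow(ev)) {
    perSample <- .allocate(config$asFragments, rep(1 / R, R))
    for (i in seq_len(nrow(ev))) {
      incK <- strsplit(ev$inclusion_junctions[i], ",", fixed = TRUE)[[1L]]
      incK <- incK[nzchar(incK)]
      isIR <- ev$event_type[i] == "IR"
      wInc <- if (isIR)
        (ev$region_end[i] - ev$region_start[i] + 1) / config$readLength
        else length(incK)
      wExc <- 1
      for (s in seq_along(samples)) {
        psi <- if (condition[samples[s]] == "H2O") ev$psi_a[i] else ev$psi_b[i]
        Tn <- perSample[((s - 1L) %% R) + 1L]
        pRead <- wInc * psi / (wInc * psi + wExc * (1 - psi))
        inc <- stats::rbinom(1, Tn, pRead)
        exc <- Tn - inc
        if (isIR) {
          rrows[[length(rrows) + 1L]] <- data.frame(
            chrom = ev$chrom[i], start = ev$region_start[i],
            end = ev$region_end[i], sample = samples[s], count = inc)
        } else if (length(incK) == 1L) {
          jrows[[length(jrows) + 1L]] <-
            .junctionRow(incK, samples[s], inc)
        } else {
          split1 <- stats::rbinom(1, inc, 0.5)
          jrows[[length(jrows) + 1L]] <-
            .junctionRow(incK[1L], samples[s], split1)
          jrows[[length(jrows) + 1L]] <-
            .junctionRow(incK[2L], samples[s], inc - split1)
        }
        jrows[[length(jrows) + 1L]] <-
          .junctionRow(ev$exclusion_junctions[i], samples[s], exc)
      }
    }
  }
  jc <- if (length(jrows)) do.call(rbind, jrows) else
    data.frame(chrom = character(0), donor = integer(0),
               acceptor = integer(0), strand = character(0),
               sample = character(0), count = integer(0))
  rc <- if (length(rrows)) do.call(rbind, rrows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               sample = character(0), count = integer(0))
  list(se = se, junctionCounts = jc, regionCoverage = rc)
}

.junctionRow <- function(key, sample, count) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
  da <- as.integer(strsplit(parts[2L], "-", fixed = TRUE)[[1L]])
  data.frame(chrom = parts[1L], donor = da[1L], acceptor = da[2L],
             strand = parts[3L], sample = sample, count = count)
}

#' Simulate sequenced fragments for a handful of transcripts
#'
#' Small-n fragment-level generator for exercising
#' \code{\link{countFragments}}: draws the requested number of fragments
#' per transcript, each placed uniformly within a width-weighted random
#' exon, with the recorded strand following the library protocol
#' (\code{"reverse"}: opposite of the transcript strand, the dUTP
#' convention).
#'
#' @param ts A \code{\link{TranscriptSet}}.
#' @param nPerTx Named integer vector: fragments per transcript id.
#' @param sample Sample id stamped on the fragments.
#' @param mode Protocol, as in \code{\link{countFragments}}.
#' @param readLength Fragment length cap (default 125).
#' @return \code{GRanges} of fragments with \code{sample} column.
#' @export
simulateFragments <- function(ts, nPerTx, sample = "S1", mode = "reverse",
                              readLength = 125L) {
  stopifnot(is(ts, "TranscriptSet"))
  ex <- txExons(ts)
  out <- list()
  for (tx in names(nPerTx)) {
    g <- ex[[tx]]
    if (is.null(g)) stop("unknown transcript: ", tx)
    n <- nPerTx[[tx]]
    if (n == 0L) next
    ei <- sample.int(length(g), n, replace = TRUE, prob = width(g))
    L <- pmin(readLength, width(g)[ei])
    off <- floor(stats::runif(n) * (width(g)[ei] - L + 1))
    st <- start(g)[ei] + off
    txStrand <- as.character(strand(g))[1L]
    recStrand <- if (mode == "reverse") chartr("+-", "-+", txStrand)
                 else txStrand
    out[[length(out) + 1L]] <- GRanges(
      as.character(seqnames(g))[1L], IRanges(st, st + L - 1L),
      strand = recStrand, sample = sample)
  }
  if (!length(out)) {
    gr <- GRanges()
    mcols(gr)$sample <- character(0)
    return(gr)
  }
  unlist(GRangesList(out))
}

#' Simulate physiology readings with planted treatment effects
#'
#' Chlorophyll absorbances scale mock means by treatment factors ordered
#' PAC > mock (H2O) > GA3 (GA + PAC intermediate), mirroring the known
#' direction of the GA effect on chlorophyll; net-photosynthesis targets
#' are ordered H2O > GA_PAC > PAC > GA3 and inverted through the
#' gas-exchange formula to sample-cell CO2 concentrations.  Gaussian noise
#' with the configured sds; zero sds reproduce the planted means exactly.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param nPerTreatment Replicates per treatment (default 6).
#' @return list: \code{chlorophyll} and \code{gasExchange} reading tables,
#'   plus \code{planted} mean values per treatment.
#' @export
simulatePhysiology <- function(config, nPerTreatment = 6L) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  treatments <- c("H2O", "GA3", "PAC", "GA_PAC")
  chlFactor <- c(H2O = 1.0, GA3 = 0.7, PAC = 1.3, GA_PAC = 1.05)
  rateTarget <- c(H2O = 12, GA3 = 8, PAC = 9.5, GA_PAC = 10.5)
  V <- 10; W <- 0.1
  CO2R <- 400; H2OR <- 20; H2OS <- 25; fda <- 0.5
  chl <- do.call(rbind, lapply(treatments, function(tr) {
    n <- nPerTreatment
    data.frame(sample = paste0(tr, "_", seq_len(n)), treatment = tr,
               A645 = pmax(0, 0.5 * chlFactor[[tr]] +
                              stats::rnorm(n, 0, config$chlNoiseSd)),
               A663 = pmax(0, 0.8 * chlFactor[[tr]] +
                              stats::rnorm(n, 0, config$chlNoiseSd)),
               V = V, W = W)
  }))
  gas <- do.call(rbind, lapply(treatments, function(tr) {
    n <- nPerTreatment
    rate <- rateTarget[[tr]] + stats::rnorm(n, 0, config$gasNoiseSd)
    CO2S <- (CO2R - rate / fda) * (1000 - H2OS) / (1000 - H2OR)
    data.frame(sample = paste0(tr, "_", seq_len(n)), treatment = tr,
               CO2R = CO2R, CO2S = CO2S, H2OR = H2OR, H2OS = H2OS,
               fda = fda)
  }))
  planted <- data.frame(
    treatment = treatments,
    chlorophyll = chlorophyllContent(0.5 * chlFactor, 0.8 * chlFactor,
                                     V, W),
    photosynthesis = rateTarget)
  rownames(chl) <- rownames(gas) <- rownames(planted) <- NULL
  list(chlorophyll = chl, gasExchange = gas, planted = planted)
}
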