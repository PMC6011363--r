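#' @include AllClasses.R AllGenerics.R
NULL

#' Splice-junction key
#'
#' Canonical string for a splice junction.  \code{donor} and
#' \code{acceptor} follow the 0-based convention used in junction-count
#' TSVs: \code{donor} is the half-open end of the upstream exon and
#' \code{acceptor} the 0-based start of the downstream exon, so the intron
#' is \code{[donor, acceptor)}.  Internally introns are 1-based closed
#' \code{[donor + 1, acceptor]}.
#'
#' @param chrom Chromosome.
#' @param intronStart,intronEnd 1-based closed intron coordinates.
#' @param strand "+" or "-".
#' @return Character key \code{"chrom:donor-acceptor:strand"}.
#' @export
junctionKey <- function(chrom, intronStart, intronEnd, strand) {
  paste0(chrom, ":", intronStart - 1L, "-", intronEnd, ":", strand)
}

# 1-based closed introns of one exon chain (IRanges); empty when mono-exonic
.intronsOf <- function(exonStarts, exonEnds) {
  n <- length(exonStarts)
  if (n < 2L) return(IRanges())
  IRanges(exonEnds[-n] + 1L, exonStarts[-1L] - 1L)
}

#' Extract unique splice junctions
#'
#' Enumerates the intron of every exon gap across all transcripts and
#' deduplicates by (chrom, donor, acceptor, strand).  The number of unique
#' junctions is \code{nrow()} of the result.
#'
#' @param ts A \code{\link{TranscriptSet}}.
#' @return data.frame with columns \code{chrom}, \code{donor},
#'   \code{acceptor} (0-based convention, see \code{\link{junctionKey}}),
#'   \code{strand}, \code{key}.
#' @export
extractJunctions <- function(ts) {
  stopifnot(is(ts, "TranscriptSet"))
  ex <- txExons(ts)
  out <- list()
  for (i in seq_along(ex)) {
    g <- ex[[i]]
    ir <- .intronsOf(start(g), end(g))
    if (!length(ir)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = as.character(seqnames(g))[1L],
      donor = start(ir) - 1L, acceptor = end(ir),
      strand = as.character(strand(g))[1L])
  }
  if (!length(out))
    return(data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      key = character(0)))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$chrom, df$donor, df$acceptor, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df$key <- junctionKey(df$chrom, df$donor + 1L, df$acceptor, df$strand)
  df
}

# Compare one ordered isoform pair; returns a list of event rows.
# a/b: lists with fields id, st (exon starts), en (exon ends), chrom, strand.
.pairEvents <- function(a, b) {
  ev <- list()
  chrom <- a$chrom; strand <- a$strand
  jk <- function(s, e) junctionKey(chrom, s, e, strand)
  intrA <- .intronsOf(a$st, a$en)
  intrB <- .intronsOf(b$st, b$en)

  # IR: an intron of a fully inside an exon of b -> b retains it
  if (length(intrA)) {
    for (i in seq_along(intrA)) {
      is0 <- start(intrA)[i]; ie0 <- end(intrA)[i]
      if (any(b$st <= is0 & b$en >= ie0)) {
        ev[[length(ev) + 1L]] <- list(
          type = "IR", rs = is0, re = ie0,
          incIso = b$id, excIso = a$id,
          incJ = "", excJ = jk(is0, ie0))
      }
    }
  }

  # ES: internal exon k of a absent from b, with b splicing directly from
  # a's upstream to a's downstream exon (both junction anchors shared)
  nA <- length(a$st)
  if (nA >= 3L && length(intrB)) {
    for (k in 2L:(nA - 1L)) {
      bigS <- a$en[k - 1L] + 1L
      bigE <- a$st[k + 1L] - 1L
      if (any(start(intrB) == bigS & end(intrB) == bigE)) {
        ev[[length(ev) + 1L]] <- list(
          type = "ES", rs = a$st[k], re = a$en[k],
          incIso = a$id, excIso = b$id,
          incJ = paste(jk(bigS, a$st[k] - 1L), jk(a$en[k] + 1L, bigE),
                       sep = ","),
          excJ = jk(bigS, bigE))
      }
    }
  }

  # AltA / AltD: intron pair sharing exactly one boundary.  Named in
  # transcription direction: on "+" the acceptor is the genomic-right
  # intron boundary, on "-" it is the genomic-left one.  The shift region
  # must not swallow a whole exon of the shorter-intron isoform (that
  # geometry is an ES exclusion junction, handled above).
  if (length(intrA) && length(intrB)) {
    for (i in seq_along(intrA)) for (j in seq_along(intrB)) {
      s1 <- start(intrA)[i]; e1 <- end(intrA)[i]
      s2 <- start(intrB)[j]; e2 <- end(intrB)[j]
      if (s1 == s2 && e1 != e2) {          # right boundary shifts
        type <- if (strand == "+") "AltA" else "AltD"
        rs <- min(e1, e2) + 1L; re <- max(e1, e2)
        short <- if (e1 < e2) a else b     # shorter intron = more exon
        long <- if (e1 < e2) b else a
        if (any(short$st >= rs & short$en <= re)) next
        ev[[length(ev) + 1L]] <- list(
          type = type, rs = rs, re = re,
          incIso = short$id, excIso = long$id,
          incJ = jk(s1, min(e1, e2)), excJ = jk(s1, max(e1, e2)))
      } else if (e1 == e2 && s1 != s2) {   # left boundary shifts
        type <- if (strand == "+") "AltD" else "AltA"
        rs <- min(s1, s2); re <- max(s1, s2) - 1L
        short <- if (s1 > s2) a else b
        long <- if (s1 > s2) b else a
        if (any(short$st >= rs & short$en <= re)) next
        ev[[length(ev) + 1L]] <- list(
          type = type, rs = rs, re = re,
          incIso = short$id, excIso = long$id,
          incJ = jk(max(s1, s2), e1), excJ = jk(min(s1, s2), e1))
      }
    }
  }
  ev
}

#' Enumerate alternative-splicing events
#'
#' All ordered pairs of same-strand isoforms within each gene (or any other
#' grouping) are compared and every event matching one of the four type
#' definitions is emitted once:
#' \describe{
#'   \item{IR}{an intron of one isoform fully contained in an exon of the
#'     other (alt region = the retained intron);}
#'   \item{ES}{an internal exon of one isoform absent from the other, with
#'     both flanking junction anchors shared (alt region = the skipped
#'     exon);}
#'   \item{AltA}{two introns share their donor and differ in acceptor (alt
#'     region spans the two acceptors);}
#'   \item{AltD}{share the acceptor, differ in donor.}
#' }
#' AltA/AltD are named in transcription direction, so reflecting a gene and
#' flipping its strand swaps the two labels while IR/ES are unchanged.
#' Events are deduplicated by (type, alt region, junction sets); a single
#' isoform yields no events.
#'
#' @param ts A \code{\link{TranscriptSet}}.
#' @param groupBy Column of \code{txData(ts)} defining isoform groups
#'   (default \code{"gene_id"}).
#' @return An \code{\link{AsEventSet}} with deterministic event ids.
#' @export
enumerateEvents <- function(ts, groupBy = "gene_id") {
  stopifnot(is(ts, "TranscriptSet"))
  td <- txData(ts)
  ex <- txExons(ts)
  groups <- split(seq_len(length(ts)), td[[groupBy]])
  rows <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    if (length(idx) < 2L) next
    isos <- lapply(idx, function(i) {
      g <- ex[[i]]
      list(id = td$transcript_id[i], st = start(g), en = end(g),
           chrom = as.character(seqnames(g))[1L],
           strand = as.character(strand(g))[1L])
    })
    for (i in seq_along(isos)) for (j in seq_along(isos)) {
      if (i == j) next
      if (isos[[i]]$strand != isos[[j]]$strand) next
      for (e in .pairEvents(isos[[i]], isos[[j]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gname, event_type = e$type,
          chrom = isos[[i]]$chrom, rs = e$rs, re = e$re,
          strand = isos[[i]]$strand,
          inclusion_iso = e$incIso, exclusion_iso = e$excIso,
          inclusion_junctions = e$incJ, exclusion_junctions = e$excJ)
      }
    }
  }
  if (!length(rows)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(event_id = character(0), gene_id = character(0),
                           event_type = character(0),
                           inclusion_iso = character(0),
                           exclusion_iso = character(0),
                           inclusion_junctions = character(0),
                           exclusion_junctions = character(0))
    return(new("AsEventSet", events = gr))
  }
  df <- do.call(rbind, rows)
  key <- paste(df$event_type, df$chrom, df$rs, df$re,
               df$inclusion_junctions, df$exclusion_junctions)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$chrom, df$rs, df$re, df$event_type,
                 df$inclusion_junctions), , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$rs, df$re), strand = df$strand)
  mcols(gr) <- DataFrame(
    event_id = sprintf("AS%05d", seq_len(nrow(df))),
    gene_id = df$gene_id, event_type = df$event_type,
    inclusion_iso = df$inclusion_iso, exclusion_iso = df$exclusion_iso,
    inclusion_junctions = df$inclusion_junctions,
    exclusion_junctions = df$exclusion_junctions)
  new("AsEventSet", events = gr)
}

#' Count inclusion/exclusion support and PSI per event and sample
#'
#' Inclusion support is the summed fragment count over the event's
#' inclusion junctions (for IR, read coverage of the retained intron);
#' exclusion support sums the exclusion junctions.  PSI applies an
#' effective-length correction before the ratio: each side's count is
#' divided by its number of distinct supporting junction positions (for the
#' IR coverage term, by alt-region length / read length), so isoform
#' fractions are comparable across event shapes.  Raw counts are reported
#' alongside.  Junctions absent from the count table count as 0 (one
#' warning is emitted); events with zero total support get \code{NA} PSI.
#'
#' @param aes An \code{\link{AsEventSet}}.
#' @param junctionCounts data.frame with columns \code{chrom},
#'   \code{donor}, \code{acceptor} (0-based convention), \code{strand},
#'   \code{sample}, \code{count}.
#' @param regionCoverage Optional data.frame \code{chrom}, \code{start},
#'   \code{end} (1-based closed), \code{sample}, \code{count}: fragment
#'   coverage of IR alt regions.
#' @param readLength Read length in nt for the IR effective-length term
#'   (default 125).
#' @return data.frame: \code{event_id}, \code{sample}, \code{inclusion},
#'   \code{exclusion}, \code{psi}.
#' @export
countEventSupport <- function(aes, junctionCounts, regionCoverage = NULL,
                              readLength = 125) {
  stopifnot(is(aes, "AsEventSet"))
  stopifnot(all(junctionCounts$count >= 0))
  jkey <- junctionKey(junctionCounts$chrom, junctionCounts$donor + 1L,
                      junctionCounts$acceptor, junctionCounts$strand)
  samples <- sort(unique(as.character(junctionCounts$sample)))
  jc <- split(setNames(junctionCounts$count, jkey),
              as.character(junctionCounts$sample))
  rc <- NULL
  if (!is.null(regionCoverage)) {
    rkey <- paste0(regionCoverage$chrom, ":", regionCoverage$start, "-",
                   regionCoverage$end)
    rc <- split(setNames(regionCoverage$count, rkey),
                as.character(regionCoverage$sample))
    samples <- sort(unique(c(samples,
                             as.character(regionCoverage$sample))))
  }
  gr <- asEvents(aes)
  m <- mcols(gr)
  missing_any <- FALSE
  lookup <- function(tbl, keys) {
    v <- tbl[keys]
    if (anyNA(v)) missing_any <<- TRUE
    v[is.na(v)] <- 0
    sum(v)
  }
  out <- list()
  for (s in samples) {
    jt <- if (s %in% names(jc)) jc[[s]] else setNames(numeric(0), character(0))
    rt <- if (!is.null(rc) && s %in% names(rc)) rc[[s]] else NULL
    for (i in seq_along(gr)) {
      type <- m$event_type[i]
      excK <- strsplit(m$exclusion_junctions[i], ",", fixed = TRUE)[[1L]]
      exc <- lookup(jt, excK)
      if (type == "IR") {
        rkey <- paste0(as.character(seqnames(gr))[i], ":", start(gr)[i],
                       "-", end(gr)[i])
        inc <- if (!is.null(rt) && rkey %in% names(rt)) rt[[rkey]] else {
          missing_any <- TRUE; 0
        }
        wInc <- max(width(gr)[i] / readLength, 1e-9)
      } else {
        incK <- strsplit(m$inclusion_junctions[i], ",", fixed = TRUE)[[1L]]
        inc <- lookup(jt, incK)
        wInc <- length(incK)
      }
      wExc <- length(excK)
      incN <- inc / wInc
      excN <- exc / wExc
      psi <- if (inc + exc == 0) NA_real_ else incN / (incN + excN)
      out[[length(out) + 1L]] <- data.frame(
        event_id = m$event_id[i], sample = s,
        inclusion = inc, exclusion = exc, psi = psi)
    }
  }
  if (missing_any)
    warning("some junctions/regions absent from count tables; treated as 0")
  if (!length(out))
    return(data.frame(event_id = character(0), sample = character(0),
                      inclusion = numeric(0), exclusion = numeric(0),
                      psi = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Likelihood-ratio test for differential splicing
#'
#' Replicates are pooled within condition; the test compares a single
#' shared PSI (H0) with one PSI per condition (H1) under a binomial
#' likelihood on pooled inclusion/exclusion counts, with the statistic
#' referred to chi-square on 1 df.  No between-replicate overdispersion is
#' modelled (a documented simplification).  Events with total pooled count
#' below \code{minCount} are untestable and return p = 1.
#'
#' @param eventCounts data.frame from \code{\link{countEventSupport}}.
#' @param condition Named character vector mapping sample to condition
#'   (exactly two conditions required).
#' @param minCount Minimum total pooled count to test (default 10).
#' @param pThreshold Significance threshold on the raw p-value (default
#'   0.05).
#' @return data.frame per event: pooled PSI per condition, \code{delta_psi},
#'   \code{p_value}, \code{significant}.
#' @export
testDifferentialAS <- function(eventCounts, condition, minCount = 10,
                               pThreshold = 0.05) {
  conds <- unique(condition[as.character(eventCounts$sample)])
  conds <- conds[!is.na(conds)]
  if (length(conds) != 2L)
    stop("testDifferentialAS requires exactly two conditions")
  cond <- condition[as.character(eventCounts$sample)]
  ids <- sort(unique(as.character(eventCounts$event_id)))
  ef <- factor(as.character(eventCounts$event_id), levels = ids)
  isA <- cond == conds[1L]
  pool <- function(v, sel) {
    out <- setNames(rep(0, length(ids)), ids)
    if (any(sel)) {
      rs <- rowsum(v[sel], ef[sel])
      out[rownames(rs)] <- rs[, 1L]
    }
    out
  }
  ia <- pool(eventCounts$inclusion, isA)
  ea <- pool(eventCounts$exclusion, isA)
  ib <- pool(eventCounts$inclusion, !isA)
  eb <- pool(eventCounts$exclusion, !isA)
  tot <- ia + ea + ib + eb
  psiA <- ifelse(ia + ea > 0, ia / (ia + ea), NA_real_)
  psiB <- ifelse(ib + eb > 0, ib / (ib + eb), NA_real_)
  xlx <- function(k, p) ifelse(k > 0, k * log(p), 0)  # 0 log 0 = 0
  p0 <- ifelse(tot > 0, (ia + ib) / tot, NA_real_)
  ll0 <- xlx(ia, p0) + xlx(ea, 1 - p0) + xlx(ib, p0) + xlx(eb, 1 - p0)
  ll1 <- xlx(ia, psiA) + xlx(ea, 1 - psiA) +
         xlx(ib, psiB) + xlx(eb, 1 - psiB)
  stat <- pmax(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[tot < minCount | ia + ea == 0 | ib + eb == 0] <- 1
  out <- data.frame(event_id = ids, psi_a = psiA, psi_b = psiB,
                    delta_psi = psiB - psiA, p_value = p,
                    significant = p < pThreshold)
  rownames(out) <- NULL
  out
}

#' Write AS events as TSV and BED6
#'
#' @param aes An \code{\link{AsEventSet}}.
#' @param tsvPath Output TSV path.
#' @param bedPath Optional BED6 of alt regions (name = event_id:type),
#'   0-based half-open.
#' @return Invisibly, \code{tsvPath}.
#' @export
writeAsEvents <- function(aes, tsvPath, bedPath = NULL) {
  df <- as.data.frame(aes)
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bedPath) && nrow(df) == 0L) {
    file.create(bedPath)
  } else if (!is.null(bedPath)) {
    bed <- data.frame(df$chrom, df$alt_start - 1L, df$alt_end,
                      paste0(df$event_id, ":", df$event_type), 0, df$strand)
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsvPath)
}
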