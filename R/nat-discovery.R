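#' @include AllClasses.R AllGenerics.R
NULL

#' Cluster transcripts into transcript units
#'
#' Single-linkage clustering of transcript spans: two transcripts belong to
#' the same unit when their spans (introns included) overlap by at least
#' \code{minOverlap} nucleotides, directly or through a chain of such
#' overlaps.  Clustering is strand-blind so a unit holds both strands of a
#' locus — the within-unit scope for opposite-strand (cis-NAT) comparison.
#'
#' Implemented as a per-chromosome sweep over spans sorted by start: a span
#' joins the open cluster when it overlaps the cluster's rightmost end by
#' \code{>= minOverlap} nt, which for intervals is exactly single-linkage
#' transitive closure.
#'
#' @param ts A \code{\link{TranscriptSet}}.
#' @param minOverlap Minimum span overlap in nucleotides (default 1, the
#'   most permissive reading of coordinate overlap).
#' @return Integer vector of unit ids (1-based, ordered by chromosome then
#'   unit start), named by transcript id.
#' @export
clusterTranscriptUnits <- function(ts, minOverlap = 1L) {
  stopifnot(is(ts, "TranscriptSet"), minOverlap >= 1L)
  sp <- txSpans(ts)
  if (length(sp) == 0L) return(setNames(integer(0), character(0)))
  o <- order(as.character(seqnames(sp)), start(sp), end(sp))
  chr <- as.character(seqnames(sp))[o]
  st <- start(sp)[o]; en <- end(sp)[o]
  unit <- integer(length(sp))
  cur <- 0L; maxEnd <- -Inf; curChr <- ""
  for (i in seq_along(o)) {
    ov <- min(maxEnd, en[i]) - st[i] + 1L
    if (chr[i] != curChr || ov < minOverlap) {
      cur <- cur + 1L
      curChr <- chr[i]
      maxEnd <- en[i]
    } else {
      maxEnd <- max(maxEnd, en[i])
    }
    unit[o[i]] <- cur
  }
  setNames(unit, names(sp))
}

#' Classify an opposite-strand overlap
#'
#' Given the spans of a plus-strand transcript P and a minus-strand
#' transcript M that overlap, assigns the cis-NAT class:
#' \describe{
#'   \item{fully_overlapping}{one span contains the other (equality
#'     included — reserved staggered classes require staggered ends);}
#'   \item{head_to_head}{otherwise, when M starts left of P: the overlap
#'     covers P's 5' end and M's 5' end (divergent, 5'-5');}
#'   \item{tail_to_tail}{otherwise (M extends right of P): the overlap
#'     covers both 3' ends (convergent, 3'-3').}
#' }
#' Coordinates are 1-based closed.  Vectorised over pairs.
#'
#' @param pStart,pEnd Span of the + strand transcript.
#' @param mStart,mEnd Span of the - strand transcript.
#' @return Character vector of classes.
#' @export
classifyOverlap <- function(pStart, pEnd, mStart, mEnd) {
  n <- length(pStart)
  stopifnot(length(pEnd) == n, length(mStart) == n, length(mEnd) == n)
  ov <- pmin(pEnd, mEnd) - pmax(pStart, mStart) + 1L
  if (any(ov < 1L))
    stop("classifyOverlap requires overlapping spans")
  contained <- (mStart >= pStart & mEnd <= pEnd) |
               (pStart >= mStart & pEnd <= mEnd)
  ifelse(contained, "fully_overlapping",
         ifelse(mStart < pStart, "head_to_head", "tail_to_tail"))
}

#' Identify cis-NAT pairs
#'
#' Pairwise comparison of oppositely oriented transcripts inside each
#' transcript unit: every (+, -) pair whose spans overlap by at least
#' \code{minOverlap} nt becomes one cis-NAT pair, classified with
#' \code{\link{classifyOverlap}}.  A pair is labelled lncNAT when either
#' member carries the noncoding flag.  The exon-level intersection length
#' is reported as an auxiliary column (\code{exonic_overlap}) but does not
#' gate pair calling — pairing is span-level.
#'
#' @param ts A \code{\link{TranscriptSet}}.
#' @param minOverlap Minimum span overlap in nucleotides (default 1).
#' @param units Optional precomputed unit assignment from
#'   \code{\link{clusterTranscriptUnits}}; computed here when missing.
#' @return A \code{\link{NatPairSet}}, sorted by (plus_tx, minus_tx).
#' @export
findNatPairs <- function(ts, minOverlap = 1L, units = NULL) {
  stopifnot(is(ts, "TranscriptSet"))
  if (is.null(units)) units <- clusterTranscriptUnits(ts, minOverlap = 1L)
  sp <- txSpans(ts)
  td <- txData(ts)
  str <- as.character(strand(sp))
  res <- list()
  for (u in unique(units)) {
    idx <- which(units == u)
    ip <- idx[str[idx] == "+"]
    im <- idx[str[idx] == "-"]
    if (!length(ip) || !length(im)) next
    grid <- expand.grid(p = ip, m = im)
    pS <- start(sp)[grid$p]; pE <- end(sp)[grid$p]
    mS <- start(sp)[grid$m]; mE <- end(sp)[grid$m]
    ov <- pmin(pE, mE) - pmax(pS, mS) + 1L
    keep <- ov >= minOverlap
    if (!any(keep)) next
    grid <- grid[keep, , drop = FALSE]
    res[[length(res) + 1L]] <- data.frame(
      p = grid$p, m = grid$m,
      oS = pmax(pS, mS)[keep], oE = pmin(pE, mE)[keep],
      cls = classifyOverlap(pS[keep], pE[keep], mS[keep], mE[keep]),
      unit = u)
  }
  if (!length(res)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(plus_tx = character(0), minus_tx = character(0),
                           nat_class = character(0),
                           overlap_length = integer(0),
                           exonic_overlap = integer(0),
                           lnc_nat = logical(0), unit = integer(0))
    return(new("NatPairSet", pairs = gr))
  }
  tab <- do.call(rbind, res)
  ex <- txExons(ts)
  exOv <- mapply(function(i, j) {
    sum(width(IRanges::intersect(ranges(ex[[i]]), ranges(ex[[j]]))))
  }, tab$p, tab$m)
  gr <- GRanges(seqnames = seqnames(sp)[tab$p],
                ranges = IRanges(tab$oS, tab$oE), strand = "*")
  mcols(gr) <- DataFrame(
    plus_tx = td$transcript_id[tab$p],
    minus_tx = td$transcript_id[tab$m],
    nat_class = tab$cls,
    overlap_length = tab$oE - tab$oS + 1L,
    exonic_overlap = as.integer(exOv),
    lnc_nat = td$noncoding[tab$p] | td$noncoding[tab$m],
    unit = as.integer(tab$unit))
  gr <- gr[order(mcols(gr)$plus_tx, mcols(gr)$minus_tx)]
  new("NatPairSet", pairs = gr)
}

#' Write cis-NAT pairs as TSV and BED6
#'
#' The TSV mirrors \code{as.data.frame(natPairSet)}; the optional BED6
#' holds the overlap regions (name = plus_tx|minus_tx|class, score =
#' overlap length) for genome-browser inspection.  BED output is 0-based
#' half-open per the format.
#'
#' @param nps A \code{\link{NatPairSet}}.
#' @param tsvPath Output TSV path.
#' @param bedPath Optional BED6 path.
#' @return Invisibly, \code{tsvPath}.
#' @export
writeNatPairs <- function(nps, tsvPath, bedPath = NULL) {
  df <- as.data.frame(nps)
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bedPath)) {
    bed <- data.frame(df$chrom, df$overlap_start - 1L, df$overlap_end,
                      paste(df$plus_tx, df$minus_tx, df$nat_class,
                            sep = "|"),
                      df$overlap_len, ".")
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsvPath)
}
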