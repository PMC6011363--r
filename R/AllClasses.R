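#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- Rle
#' @importFrom IRanges IRanges ranges width start end
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand granges
NULL

NAT_CLASSES <- c("head_to_head", "tail_to_tail", "fully_overlapping")
AS_TYPES <- c("IR", "ES", "AltA", "AltD")

#' TranscriptSet: validated transcript models
#'
#' A set of stranded transcript models, each an ordered chain of exons on a
#' single chromosome and strand.  Exons are stored as a
#' \link[GenomicRanges]{GRangesList} named by transcript id (1-based closed
#' coordinates, the Bioconductor convention); per-transcript metadata
#' (\code{gene_id}, optional \code{noncoding} flag used to label lncNAT
#' pairs) live in a parallel \link[S4Vectors]{DataFrame}.
#'
#' Validity requires, for every transcript: strand \code{+} or \code{-}
#' (never \code{*}); exons sorted by start, pairwise disjoint with at least
#' a 1-nt intron between consecutive exons; a single chromosome.  Objects
#' violating these are rejected at construction, so downstream modules only
#' ever see validated transcripts.
#'
#' @slot exons GRangesList of exons, one element per transcript.
#' @slot txData DataFrame with columns \code{transcript_id},
#'   \code{gene_id}, \code{noncoding}.
#' @aliases TranscriptSet-class
#' @export
setClass("TranscriptSet",
         representation(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    return("exons and txData disagree in length")
  if (length(ex) == 0L) return(TRUE)
  if (!all(c("transcript_id", "gene_id", "noncoding") %in% colnames(td)))
    return("txData must have transcript_id, gene_id, noncoding columns")
  if (!identical(names(ex), as.character(td$transcript_id)))
    return("names(exons) must equal txData$transcript_id")
  if (anyDuplicated(td$transcript_id))
    return("duplicated transcript_id")
  if (length(ex) == 0L) return(TRUE)
  ustr <- unique(strand(ex))
  if (any(S4Vectors::elementNROWS(ustr) != 1L))
    return("a transcript mixes strands")
  s <- as.character(unlist(ustr))
  if (!all(s %in% c("+", "-")))
    return("transcript strand must be '+' or '-'")
  uchr <- unique(seqnames(ex))
  if (any(S4Vectors::elementNROWS(uchr) != 1L))
    return("a transcript spans multiple chromosomes")
  st <- start(ex); en <- end(ex)
  bad <- vapply(seq_along(ex), function(i) {
    s0 <- st[[i]]; e0 <- en[[i]]
    is.unsorted(s0) || (length(s0) > 1L && any(s0[-1L] - e0[-length(e0)] < 2L))
  }, logical(1L))
  if (any(bad))
    return(sprintf("exons unsorted/overlapping/adjacent in transcript(s): %s",
                   paste(names(ex)[bad][seq_len(min(3L, sum(bad)))],
                         collapse = ", ")))
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons Named \code{GRangesList} of exons (one element per
#'   transcript, 1-based closed).  Exons need not be pre-sorted; they are
#'   sorted by start here and then validated.
#' @param geneIds Character vector of gene ids parallel to \code{exons};
#'   defaults to the transcript ids (isoform GTFs often lack gene grouping
#'   and clustering recreates it).
#' @param noncoding Logical vector: \code{TRUE} marks a transcript as
#'   predicted noncoding (used only to flag lncNAT pairs). Default all
#'   \code{FALSE}.
#' @return A validated \code{TranscriptSet}.
#' @export
TranscriptSet <- function(exons, geneIds = names(exons),
                          noncoding = rep(FALSE, length(exons))) {
  if (is.null(names(exons)) && length(exons) > 0L)
    stop("exons must be a named GRangesList")
  exons <- GRangesList(lapply(exons, function(g) {
    g <- g[order(start(g))]
    mcols(g) <- NULL
    g
  }), compress = TRUE)
  if (is.null(geneIds)) geneIds <- names(exons)
  geneIds[is.na(geneIds)] <- names(exons)[is.na(geneIds)]
  td <- DataFrame(transcript_id = as.character(names(exons)),
                  gene_id = as.character(geneIds),
                  noncoding = as.logical(noncoding))
  rownames(td) <- td$transcript_id
  new("TranscriptSet", exons = exons, txData = td)
}

#' NatPairSet: classified cis-NAT pairs
#'
#' Each row is one opposite-strand overlapping transcript pair, carried as a
#' strand-\code{*} \code{GRanges} of the overlap region with metadata
#' columns: \code{plus_tx}, \code{minus_tx}, \code{nat_class} (one of
#' head_to_head / tail_to_tail / fully_overlapping), \code{overlap_length},
#' \code{exonic_overlap} (auxiliary: exon-level intersection length),
#' \code{lnc_nat}, \code{unit}.
#'
#' @slot pairs GRanges of overlap regions plus the metadata above.
#' @aliases NatPairSet-class
#' @export
setClass("NatPairSet", representation(pairs = "GRanges"))

setValidity("NatPairSet", function(object) {
  m <- mcols(object@pairs)
  need <- c("plus_tx", "minus_tx", "nat_class", "overlap_length",
            "exonic_overlap", "lnc_nat", "unit")
  if (!all(need %in% colnames(m)))
    return(paste("missing pair columns:",
                 paste(setdiff(need, colnames(m)), collapse = ", ")))
  if (!all(as.character(m$nat_class) %in% NAT_CLASSES))
    return("nat_class outside the three-class taxonomy")
  if (length(object@pairs) &&
      !all(m$overlap_length == width(object@pairs)))
    return("overlap_length inconsistent with overlap interval")
  TRUE
})

#' AsEventSet: alternative-splicing events
#'
#' One row per deduplicated AS event from pairwise isoform comparison.  The
#' \code{GRanges} holds the alternative region (retained intron, skipped
#' exon, or donor/acceptor shift region, stranded) with metadata:
#' \code{event_id}, \code{gene_id}, \code{event_type} (IR/ES/AltA/AltD),
#' \code{inclusion_iso}, \code{exclusion_iso}, and comma-separated junction
#' keys \code{inclusion_junctions} / \code{exclusion_junctions} (see
#' \code{\link{junctionKey}}).
#'
#' @slot events GRanges of alternative regions plus the metadata above.
#' @aliases AsEventSet-class
#' @export
setClass("AsEventSet", representation(events = "GRanges"))

setValidity("AsEventSet", function(object) {
  m <- mcols(object@events)
  need <- c("event_id", "gene_id", "event_type", "inclusion_iso",
            "exclusion_iso", "inclusion_junctions", "exclusion_junctions")
  if (!all(need %in% colnames(m)))
    return(paste("missing event columns:",
                 paste(setdiff(need, colnames(m)), collapse = ", ")))
  if (!all(as.character(m$event_type) %in% AS_TYPES))
    return("event_type outside the four-type taxonomy")
  if (anyDuplicated(m$event_id)) return("duplicated event_id")
  TRUE
})
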