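#' @include AllClasses.R
NULL

#' Accessors for TranscriptSet, NatPairSet and AsEventSet
#'
#' \code{exonsBy} returns the exon \code{GRangesList}; \code{txData} the
#' per-transcript metadata; \code{txSpans} a \code{GRanges} of transcript
#' spans (first exon start to last exon end, stranded, named by transcript);
#' \code{natPairs} / \code{asEvents} the underlying annotated \code{GRanges}
#' of a result set.
#'
#' @param x A \code{TranscriptSet}, \code{NatPairSet} or \code{AsEventSet}.
#' @return See details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))
#' @rdname accessors
#' @export
setGeneric("txData", function(x) standardGeneric("txData"))
#' @rdname accessors
#' @export
setGeneric("txSpans", function(x) standardGeneric("txSpans"))
#' @rdname accessors
#' @export
setGeneric("natPairs", function(x) standardGeneric("natPairs"))
#' @rdname accessors
#' @export
setGeneric("asEvents", function(x) standardGeneric("asEvents"))

#' @rdname accessors
#' @export
setMethod("txExons", "TranscriptSet", function(x) x@exons)

#' @rdname accessors
#' @export
setMethod("txData", "TranscriptSet", function(x) x@txData)

#' @rdname accessors
#' @export
setMethod("txSpans", "TranscriptSet", function(x) {
  if (length(x@exons) == 0L)
    return(GRanges())
  sp <- unlist(range(x@exons))
  names(sp) <- names(x@exons)
  sp
})

#' @rdname accessors
#' @export
setMethod("natPairs", "NatPairSet", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("asEvents", "AsEventSet", function(x) x@events)

#' @describeIn TranscriptSet Number of transcripts.
#' @param x A TranscriptSet.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @describeIn TranscriptSet Subset by index or transcript id.
#' @param i index
#' @param j,drop,... unused
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

#' @describeIn NatPairSet Number of pairs.
#' @param x A NatPairSet.
#' @export
setMethod("length", "NatPairSet", function(x) length(x@pairs))

#' @describeIn AsEventSet Number of events.
#' @param x An AsEventSet.
#' @export
setMethod("length", "AsEventSet", function(x) length(x@events))

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts,",
      length(unique(object@txData$gene_id)), "genes\n")
  if (length(object)) {
    nex <- S4Vectors::elementNROWS(object@exons)
    cat("  exons per transcript:", min(nex), "-", max(nex),
        "| noncoding:", sum(object@txData$noncoding), "\n")
  }
  invisible(NULL)
})

setMethod("show", "NatPairSet", function(object) {
  cat("NatPairSet with", length(object), "cis-NAT pairs\n")
  if (length(object)) {
    tab <- table(factor(mcols(object@pairs)$nat_class, levels = NAT_CLASSES))
    cat(" ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
    cat("  lncNAT pairs:", sum(mcols(object@pairs)$lnc_nat), "\n")
  }
  invisible(NULL)
})

setMethod("show", "AsEventSet", function(object) {
  cat("AsEventSet with", length(object), "events\n")
  if (length(object)) {
    tab <- table(factor(mcols(object@events)$event_type, levels = AS_TYPES))
    cat(" ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
  }
  invisible(NULL)
})

#' Coerce result sets to data.frame
#'
#' @param x A NatPairSet or AsEventSet.
#' @param row.names,optional,... passed through / ignored.
#' @return A base data.frame, one row per pair/event.
#' @export
as.data.frame.NatPairSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  gr <- x@pairs
  data.frame(plus_tx = mcols(gr)$plus_tx, minus_tx = mcols(gr)$minus_tx,
             chrom = as.character(seqnames(gr)),
             overlap_start = start(gr), overlap_end = end(gr),
             overlap_len = mcols(gr)$overlap_length,
             exonic_overlap = mcols(gr)$exonic_overlap,
             nat_class = as.character(mcols(gr)$nat_class),
             lnc_nat = mcols(gr)$lnc_nat,
             unit = mcols(gr)$unit,
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.NatPairSet
#' @export
as.data.frame.AsEventSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  gr <- x@events
  data.frame(event_id = mcols(gr)$event_id, gene_id = mcols(gr)$gene_id,
             event_type = as.character(mcols(gr)$event_type),
             chrom = as.character(seqnames(gr)),
             alt_start = start(gr), alt_end = end(gr),
             strand = as.character(strand(gr)),
             inclusion_iso = mcols(gr)$inclusion_iso,
             exclusion_iso = mcols(gr)$exclusion_iso,
             inclusion_junctions = mcols(gr)$inclusion_junctions,
             exclusion_junctions = mcols(gr)$exclusion_junctions,
             stringsAsFactors = FALSE)
}
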