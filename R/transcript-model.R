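#' @include AllClasses.R
NULL

#' Read transcript models from GTF
#'
#' Assembles \code{exon} rows of a GTF/GFF2 file into validated transcript
#' models.  GTF coordinates are 1-based inclusive and are kept as such in
#' the returned \code{GRangesList}-backed object.  Every exon row must carry
#' a \code{transcript_id} attribute; a missing \code{gene_id} defaults to
#' the transcript id (full-length isoform GTFs often lack gene grouping —
#' transcript-unit clustering recreates it).  An optional \code{noncoding}
#' attribute (\code{"TRUE"}/\code{"FALSE"}) marks predicted noncoding
#' transcripts for lncNAT labelling.
#'
#' Exons arriving out of order are sorted by start; records violating the
#' transcript invariants (mixed strands, overlapping exons, zero-length
#' introns) raise a validation error rather than propagating downstream.
#'
#' @param path Path to a GTF file.
#' @return A \code{\link{TranscriptSet}}.
#' @export
readGTF <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("malformed GTF record (fewer than 9 fields) at line ",
         lineno[which(nf < 9L)[1L]])
  feat <- vapply(fields, `[[`, "", 3L)
  is_exon <- feat == "exon"
  attr9 <- vapply(fields, `[[`, "", 9L)
  bad <- is_exon & !grepl("transcript_id\\s+\"[^\"]+\"", attr9)
  if (any(bad))
    stop("malformed attribute string (no transcript_id) at line ",
         lineno[which(bad)[1L]])
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    return(TranscriptSet(GRangesList()))
  tid <- as.character(mcols(gr)$transcript_id)
  gid <- if ("gene_id" %in% colnames(mcols(gr)))
    as.character(mcols(gr)$gene_id) else rep(NA_character_, length(gr))
  gid[is.na(gid) | !nzchar(gid)] <- tid[is.na(gid) | !nzchar(gid)]
  nc <- if ("noncoding" %in% colnames(mcols(gr)))
    as.logical(mcols(gr)$noncoding) else rep(FALSE, length(gr))
  nc[is.na(nc)] <- FALSE
  o <- order(tid)
  gr <- gr[o]; tid <- tid[o]; gid <- gid[o]; nc <- nc[o]
  mcols(gr) <- NULL
  exl <- split(gr, factor(tid, levels = unique(tid)))
  first <- !duplicated(tid)
  TranscriptSet(exl, geneIds = gid[first], noncoding = nc[first])
}

#' Write transcript models to GTF
#'
#' Emits one \code{exon} row per exon with \code{transcript_id},
#' \code{gene_id} and \code{noncoding} attributes; coordinates 1-based
#' inclusive.  \code{readGTF(writeGTF(x))} preserves every exon boundary.
#'
#' @param ts A \code{\link{TranscriptSet}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGTF <- function(ts, path) {
  stopifnot(is(ts, "TranscriptSet"))
  ex <- unlist(txExons(ts), use.names = FALSE)
  n <- S4Vectors::elementNROWS(txExons(ts))
  td <- txData(ts)
  if (length(ex)) {
    mcols(ex)$source <- "cisNATseq"
    mcols(ex)$type <- "exon"
    mcols(ex)$transcript_id <- rep(td$transcript_id, n)
    mcols(ex)$gene_id <- rep(td$gene_id, n)
    mcols(ex)$noncoding <- rep(td$noncoding, n)
  }
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

#' BED12 export / import of transcript models
#'
#' \code{writeBED} writes one BED12 line per transcript (0-based half-open,
#' the BED convention; blockCount/blockSizes/blockStarts mirror the exon
#' chain).  \code{readBED} reconstructs a \code{TranscriptSet} from such a
#' file; the BED name field is the transcript id and \code{gene_id}
#' defaults to it.  Round-tripping preserves exon structure exactly.
#'
#' @param ts A \code{\link{TranscriptSet}}.
#' @param path File path.
#' @return \code{writeBED}: invisibly \code{path}; \code{readBED}: a
#'   \code{TranscriptSet}.
#' @export
writeBED <- function(ts, path) {
  stopifnot(is(ts, "TranscriptSet"))
  if (length(ts) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  rtracklayer::export(txExons(ts), path, format = "bed")
  invisible(path)
}

#' @rdname writeBED
#' @export
readBED <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) return(TranscriptSet(GRangesList()))
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(mcols(gr)$blocks)) {
    exl <- S4Vectors::split(granges(gr), factor(gr$name, unique(gr$name)))
  } else {
    exl <- rtracklayer::blocks(gr)
    names(exl) <- gr$name
  }
  TranscriptSet(exl)
}
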