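#' @include AllClasses.R AllGenerics.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Build a count-matrix container
#'
#' Thin constructor around \link[SummarizedExperiment]{SummarizedExperiment}
#' enforcing the count-matrix contract: non-negative integer counts, one
#' condition label per sample, one library size (total mapped fragments,
#' which may exceed the assigned column sum) per sample.
#'
#' @param counts Integer matrix, features x samples.
#' @param condition Character vector or named map of sample -> condition.
#' @param librarySize Numeric vector of total mapped fragments per sample.
#' @param featureLength Optional exonic feature lengths (nt), stored in
#'   rowData for FPKM.
#' @return A \code{SummarizedExperiment}.
#' @export
countMatrix <- function(counts, condition, librarySize,
                        featureLength = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (!is.null(names(condition))) condition <- condition[colnames(counts)]
  if (!is.null(names(librarySize)))
    librarySize <- librarySize[colnames(counts)]
  if (length(condition) != ncol(counts) || anyNA(condition))
    stop("every sample needs a condition")
  if (any(librarySize <= 0)) stop("library sizes must be positive")
  cd <- DataFrame(condition = as.character(condition),
                  library_size = as.numeric(librarySize),
                  row.names = colnames(counts))
  rd <- if (is.null(featureLength)) NULL else
    DataFrame(exonic_length = as.numeric(featureLength),
              row.names = rownames(counts))
  SummarizedExperiment(assays = list(counts = counts), colData = cd,
                       rowData = rd)
}

# map recorded fragment strand to inferred transcript strand
.correctStrand <- function(strand, mode) {
  switch(mode,
         forward = strand,
         reverse = chartr("+-", "-+", strand),
         unstranded = strand,
         stop("unknown strandedness mode: ", mode))
}

#' Strand-specific fragment counting
#'
#' Assigns each fragment to every feature whose exons it overlaps by at
#' least \code{minFragOverlap} nt on the same protocol-corrected strand.
#' Under the dUTP protocol (\code{mode = "reverse"}, the default) the
#' recorded fragment strand is the reverse of the transcript strand and is
#' flipped before matching; \code{"forward"} keeps it; \code{"unstranded"}
#' ignores strand.  Counting is exon-aware by default (NAT overlap regions
#' can be intronic in one member); \code{spanLevel = TRUE} counts against
#' whole spans instead.  \code{uniqueOnly = TRUE} drops fragments hitting
#' more than one feature.
#'
#' @param fragments \code{GRanges} of fragments with a \code{sample}
#'   metadata column (strand as recorded by the library protocol), or a
#'   data.frame with 1-based closed \code{chrom,start,end,sample,strand}.
#' @param ts A \code{\link{TranscriptSet}} of features.
#' @param mode One of \code{"reverse"}, \code{"forward"},
#'   \code{"unstranded"}.
#' @param minFragOverlap Minimum exonic overlap in nt (default 1).
#' @param uniqueOnly Drop multi-feature fragments (default FALSE).
#' @param spanLevel Count against transcript spans, introns included
#'   (default FALSE).
#' @param condition Optional sample -> condition map for the result.
#' @param librarySize Optional per-sample totals; defaults to fragments per
#'   sample.
#' @return A \code{SummarizedExperiment} (see \code{\link{countMatrix}})
#'   with one row per feature, exonic lengths in rowData.
#' @export
countFragments <- function(fragments, ts, mode = "reverse",
                           minFragOverlap = 1L, uniqueOnly = FALSE,
                           spanLevel = FALSE, condition = NULL,
                           librarySize = NULL) {
  stopifnot(is(ts, "TranscriptSet"))
  if (is.data.frame(fragments)) {
    fragments <- GRanges(fragments$chrom,
                         IRanges(fragments$start, fragments$end),
                         strand = fragments$strand,
                         sample = as.character(fragments$sample))
  }
  if (any(width(fragments) < 1L)) stop("empty fragment interval")
  mode <- match.arg(mode, c("reverse", "forward", "unstranded"))
  fstr <- .correctStrand(as.character(strand(fragments)), mode)
  samples <- sort(unique(mcols(fragments)$sample))
  ex <- if (spanLevel) {
    GRangesList(as.list(S4Vectors::split(txSpans(ts),
                                         seq_len(length(ts)))))
  } else txExons(ts)
  flat <- unlist(ex, use.names = FALSE)
  txOf <- rep(seq_len(length(ex)), S4Vectors::elementNROWS(ex))
  hits <- GenomicRanges::findOverlaps(fragments, flat, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  if (mode != "unstranded") {
    keep <- fstr[q] == as.character(strand(flat))[s]
    q <- q[keep]; s <- s[keep]
  }
  ovw <- pmin(end(fragments)[q], end(flat)[s]) -
         pmax(start(fragments)[q], start(flat)[s]) + 1L
  # total exonic overlap per (fragment, feature)
  pk <- paste(q, txOf[s])
  tot <- rowsum(ovw, pk)
  keys <- rownames(tot)
  ok <- tot[, 1L] >= minFragOverlap
  qs <- as.integer(sub(" .*", "", keys))[ok]
  txs <- as.integer(sub(".* ", "", keys))[ok]
  if (uniqueOnly) {
    nHit <- table(qs)
    keep <- qs %in% as.integer(names(nHit)[nHit == 1L])
    qs <- qs[keep]; txs <- txs[keep]
  }
  td <- txData(ts)
  cm <- matrix(0L, nrow = length(ts), ncol = length(samples),
               dimnames = list(td$transcript_id, samples))
  if (length(qs)) {
    tab <- table(factor(txs, levels = seq_len(length(ts))),
                 factor(mcols(fragments)$sample[qs], levels = samples))
    cm[] <- as.integer(tab)
  }
  if (is.null(librarySize)) {
    librarySize <- as.numeric(table(factor(mcols(fragments)$sample,
                                           levels = samples)))
    names(librarySize) <- samples
  }
  if (is.null(condition)) condition <- setNames(samples, samples)
  lens <- vapply(seq_len(length(ts)),
                 function(i) sum(width(txExons(ts)[[i]])), numeric(1))
  countMatrix(cm, condition = condition, librarySize = librarySize,
              featureLength = lens)
}

#' Read fragments from a BED6-like TSV
#'
#' Columns: chrom, start, end, name, sample, strand; BED coordinates
#' (0-based half-open), converted to 1-based closed on the returned
#' \code{GRanges}.
#'
#' @param path TSV path (no header).
#' @return \code{GRanges} with \code{sample} metadata column.
#' @export
readFragmentsTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "sample", "strand"),
                          stringsAsFactors = FALSE)
  GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand,
          sample = as.character(df$sample))
}

#' FPKM normalisation
#'
#' FPKM[f, s] = counts[f, s] * 1e9 / (librarySize[s] * length[f]), i.e.
#' fragments per kilobase of exonic transcript per million mapped
#' fragments.
#'
#' @param x A \code{SummarizedExperiment} from \code{\link{countMatrix}} /
#'   \code{\link{countFragments}}, or a plain counts matrix.
#' @param lengths Exonic feature lengths in nt; taken from
#'   \code{rowData(x)$exonic_length} when missing.
#' @param librarySize Per-sample totals; taken from
#'   \code{colData(x)$library_size} when missing.
#' @return Real matrix of FPKM values.
#' @export
fpkm <- function(x, lengths = NULL, librarySize = NULL) {
  if (is(x, "SummarizedExperiment")) {
    if (is.null(lengths)) lengths <- rowData(x)$exonic_length
    if (is.null(librarySize)) librarySize <- colData(x)$library_size
    x <- assay(x, "counts")
  }
  if (is.null(lengths) || any(lengths <= 0))
    stop("positive feature lengths required")
  if (is.null(librarySize) || any(librarySize <= 0))
    stop("positive library sizes required")
  sweep(sweep(x * 1e9, 2, as.numeric(librarySize), "/"),
        1, as.numeric(lengths), "/")
}
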