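#' Chlorophyll content (Arnon)
#'
#' Total chlorophyll per gram fresh weight from absorbances of the
#' ethanol/acetone extract at 645 and 663 nm:
#' \deqn{(20.2 A_{645} + 8.02 A_{663}) \times V / W}
#' with V the extract volume (ml) and W the fresh weight (g).  The printed
#' coefficients give total chlorophyll only; no a/b split is computed.
#' Vectorised.
#'
#' @param A645,A663 Absorbances (>= 0).
#' @param V Extract volume in ml (> 0).
#' @param W Fresh weight in g (> 0).
#' @return Chlorophyll content (mass per g fresh weight).
#' @export
chlorophyllContent <- function(A645, A663, V, W) {
  if (any(A645 < 0) || any(A663 < 0)) stop("absorbances must be >= 0")
  if (any(V <= 0)) stop("extract volume must be positive")
  if (any(W <= 0)) stop("fresh weight must be positive")
  (20.2 * A645 + 8.02 * A663) * (V / W)
}

#' Net photosynthetic rate from gas exchange
#'
#' Open-system infrared gas-analysis formula:
#' \deqn{(CO_2R - CO_2S \times (1000 - H_2OR) / (1000 - H_2OS))
#'   \times fda}
#' where CO2R/CO2S are the CO2 concentrations in the reference and sample
#' cell, H2OR/H2OS the water vapour concentrations (mmol/mol), and fda the
#' molar flow per leaf area.  Vectorised.
#'
#' @param CO2R,CO2S Reference / sample cell CO2 concentrations.
#' @param H2OR,H2OS Reference / sample cell H2O concentrations; H2OS must
#'   not equal 1000.
#' @param fda Flow per leaf area (> 0).
#' @return Net photosynthetic rate.
#' @export
netPhotosynthesis <- function(CO2R, CO2S, H2OR, H2OS, fda) {
  if (any(H2OS == 1000)) stop("H2OS = 1000 makes the correction undefined")
  if (any(fda < 0)) stop("fda must be non-negative")
  (CO2R - CO2S * (1000 - H2OR) / (1000 - H2OS)) * fda
}

#' Apply the physiology formulas to reading tables
#'
#' \code{chlorophyllTable} expects columns \code{A645, A663, V, W} (plus
#' any id/treatment columns) and appends \code{chlorophyll};
#' \code{gasExchangeTable} expects \code{CO2R, CO2S, H2OR, H2OS, fda} and
#' appends \code{photosynthesis}.  \code{treatmentSummary} reduces a value
#' column to per-treatment mean and standard error.
#'
#' @param df A data.frame of readings.
#' @return The augmented data.frame.
#' @export
chlorophyllTable <- function(df) {
  df$chlorophyll <- chlorophyllContent(df$A645, df$A663, df$V, df$W)
  df
}

#' @rdname chlorophyllTable
#' @export
gasExchangeTable <- function(df) {
  df$photosynthesis <- netPhotosynthesis(df$CO2R, df$CO2S, df$H2OR,
                                         df$H2OS, df$fda)
  df
}

#' @rdname chlorophyllTable
#' @param valueCol Name of the value column to summarise.
#' @param by Name of the grouping column (default "treatment").
#' @export
treatmentSummary <- function(df, valueCol, by = "treatment") {
  groups <- split(df[[valueCol]], df[[by]])
  out <- data.frame(
    treatment = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(v)
      stats::sd(v) / sqrt(length(v)), numeric(1)))
  rownames(out) <- NULL
  out
}
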