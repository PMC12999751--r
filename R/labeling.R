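#' Binary activity label from an EC50 value
#'
#' Applies the activity labeling rule: compounds with EC50 strictly below the
#' threshold (20 mg/L by default) are positive; values at or above the
#' threshold are negative. Right-censored values (recorded as \code{">20"},
#' i.e. only a lower bound is known) are negative when the censoring bound is
#' at or above the threshold, and unlabelable (an error) when the bound lies
#' below it, since the true value could fall on either side.
#'
#' @param ec50 numeric EC50 values in mg/L, or character values where a
#'   leading \code{">"} marks right-censoring (e.g. \code{">20"}).
#' @param threshold positive/negative cut in mg/L (default 20).
#' @return integer vector of 0/1 labels.
#' @examples
#' labelFromEc50(c("5", "20", ">20"))
#' @export
labelFromEc50 <- function(ec50, threshold = 20) {
  stopifnot(length(ec50) >= 1, threshold > 0)
  vapply(as.character(ec50), function(x) {
    if (is.na(x) || !nzchar(x)) stop("missing EC50 value cannot be labeled", call. = FALSE)
    censored <- startsWith(trimws(x), ">")
    val <- suppressWarnings(as.numeric(sub("^\\s*>", "", x)))
    if (is.na(val)) stop("unparseable EC50 value: ", sQuote(x), call. = FALSE)
    if (val <= 0) stop("EC50 must be positive: ", sQuote(x), call. = FALSE)
    if (censored) {
      if (val < threshold) {
        stop("right-censored EC50 ", sQuote(x), " is uninformative below the threshold ",
             threshold, " mg/L; record is unlabelable", call. = FALSE)
      }
      return(0L)
    }
    if (val < threshold) 1L else 0L
  }, integer(1), USE.NAMES = FALSE)
}
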