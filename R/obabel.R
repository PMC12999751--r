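# Bridge to OpenBabel (via ChemmineOB) for SMILES <-> molfile conversion.
# OpenBabel signals parse failure by returning an empty string, so every
# conversion is checked here and turned into a proper R error naming the input.

ob_convert <- function(from, to, text, add_h = FALSE) {
  if (add_h) {
    opts <- data.frame(names = "h", args = "", stringsAsFactors = FALSE)
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text, options = opts))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text))
  }
}

#' Canonicalize a SMILES string
#'
#' Converts any valid SMILES spelling to the unique canonical form produced by
#' the chemistry toolkit (OpenBabel). Canonicalization is idempotent and stable
#' across runs, so two spellings of the same molecule ("OCC", "CCO") map to one
#' string; stereo descriptors present in the input are preserved.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO"))
#' @export
canonicalizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  vapply(smiles, function(s) {
    out <- ob_convert("SMI", "CAN", paste0(s, "\n"))
    out <- sub("[\t\n ]+$", "", out)
    if (!nzchar(out)) {
      stop("SMILES parse failure: ", sQuote(s), call. = FALSE)
    }
    out
  }, character(1), USE.NAMES = FALSE)
}

# Canonical SMILES for a molfile text block; returns NA_character_ (not an
# error) when OpenBabel cannot sanitize the structure -- tautomer rule
# products that fail sanitization are dropped by the caller.
molfile_to_canonical <- function(molfile) {
  out <- tryCatch(ob_convert("SDF", "CAN", molfile), error = function(e) "")
  out <- sub("[\t\n ]+$", "", out)
  if (!nzchar(out)) NA_character_ else out
}
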