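# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage-stamped log message to standard error
#'
#' @param stage short stage label
#' @param ... message parts, pasted together
#' @keywords internal
hep_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Derive a stage-local seed from the master seed. Offsets are fixed per
# stage so one integer seed drives the whole pipeline reproducibly; result
# stays inside 32-bit integer range.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483629L)
}

row_medians <- function(x, na.rm = TRUE) {
  apply(x, 1L, stats::median, na.rm = na.rm)
}

col_medians <- function(x, na.rm = TRUE) {
  apply(x, 2L, stats::median, na.rm = na.rm)
}

#' Extract gene symbols from "UniProtID|GeneSymbol" protein ids
#'
#' Symbols are upper-cased; ids without a "|" separator are returned
#' upper-cased as-is (treated as bare symbols).
#'
#' @param ids character vector of protein ids
#' @return character vector of upper-case gene symbols
#' @export
gene_symbols <- function(ids) {
  toupper(sub("^[^|]*\\|", "", ids))
}

# Format numbers for on-disk tables so that write -> read round-trips are
# value-identical (17 significant digits reproduce a double exactly).
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
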