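#' Round half away from zero
#'
#' Decimal rounding with the half-up rule (0.05 -> 0.1), the convention used
#' for printed percentage tables, as opposed to [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a child seed from a master seed
#'
#' Deterministic mixing so independent stages consume independent but
#' reproducible RNG streams. Result stays inside 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param offset stage offset (integer).
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table with a provenance header
#'
#' Prepends a comment line naming the producing stage and a hash of the
#' parameters so every result file is self-describing.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param stage name of the producing stage.
#' @param params named list of parameters folded into the hash.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, stage, params = list()) {
  header <- sprintf("# stage=%s params_md5=%s", stage, params_hash(params))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_result_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# md5 of the deparsed parameter list; base tools only hashes files, so the
# parameters are serialized to a scratch file first.
params_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  if (length(params)) params <- params[order(names(params))]
  writeLines(paste(deparse(params), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}
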