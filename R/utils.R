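# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators behave as pure functions of
# (params, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Format numbers with enough digits to round-trip doubles through text.
format_num <- function(x) {
  formatC(x, digits = 17, format = "g", width = 1)
}

#' Write a data frame as a plain TSV
#'
#' Tab-separated, no quoting, no row names, numeric columns written with 17
#' significant digits so values round-trip exactly. Used for every tabular
#' artifact the package emits; given identical input the output is
#' byte-identical.
#'
#' @param x a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- format_num(y[[j]])
  }
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
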