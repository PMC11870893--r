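# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), unlike [round()] which
#' rounds half to even. Used everywhere a printed 2-decimal value or an
#' integer count is derived from a fraction, so that rendered metrics are
#' stable and match conventional table formatting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) == 2
#' round_half_up(17.945, 2)  # 17.95
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic TSV writer: fixed quoting, no row names, "." decimal.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# Collapse internal whitespace and trim; no case folding (botanical names
# are case-sensitive by convention).
normalize_label <- function(x) {
  gsub("\\s+", " ", trimws(x))
}

stop_tmnet <- function(msg, class) {
  stop(structure(class = c(class, "tmnet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
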