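#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
abort <- function(...) stop(sprintf(...), call. = FALSE)

#' Warn with a formatted message
#' @noRd
warn <- function(...) warning(sprintf(...), call. = FALSE)

#' Check that a scalar is a single finite number inside a range
#' @noRd
check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("'%s' must be a single finite number", name)
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    abort("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
          if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]")
  invisible(x)
}

#' Normalize line labels to HIGH/LOW
#' @noRd
normalize_line <- function(x) {
  out <- toupper(trimws(as.character(x)))
  bad <- !out %in% c("HIGH", "LOW")
  if (any(bad))
    abort("line labels must be HIGH or LOW (case-insensitive); got: %s",
          paste(unique(x[bad]), collapse = ", "))
  out
}

#' Derive reproducible stage seeds from one master seed
#'
#' One global seed is expanded into named per-stage seeds so that changing
#' the amount of randomness consumed by one stage does not perturb another.
#' @noRd
stage_seeds <- function(seed, stages) {
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

#' Vectorized strict upper triangle of a square matrix
#' @noRd
upper_vec <- function(m) m[upper.tri(m)]

#' Write a data frame as the package's TSV dialect
#'
#' Tab-delimited, UTF-8, no quoting, no row names; deterministic bytes for a
#' deterministic input.
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read the package's TSV dialect ('#' comments ignored)
#' @noRd
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE, ...)
}
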