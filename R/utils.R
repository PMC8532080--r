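`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop_config(field, sprintf("must be a single number in %s0,1%s",
                               if (open_left) "(" else "[",
                               if (open_right) ")" else "]"))
  }
  invisible(x)
}

check_count <- function(x, field, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < if (positive) 1 else 0) {
    stop_config(field, if (positive) "must be a positive integer"
                else "must be a non-negative integer")
  }
  invisible(as.integer(x))
}

variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Format a proportion as a percentage string
#'
#' Rounds to one decimal place of percent, the convention used in the
#' package's summary reports.
#'
#' @param count numerator.
#' @param total denominator.
#' @return Numeric percentage rounded to one decimal (e.g. 21/1202 -> 1.7).
#' @export
percent_of <- function(count, total) {
  if (total <= 0) return(NA_real_)
  round(100 * count / total, 1)
}
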