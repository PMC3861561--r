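#' @importFrom rlang abort warn %||%
NULL

# Classed conditions: "ki67_validation_error" for bad inputs/content,
# "ki67_io_error" for filesystem problems. The CLI maps these to exit
# codes 1 and 2 respectively.
abort_validation <- function(msg, ...) {
  abort(msg, class = "ki67_validation_error", ...)
}

abort_io <- function(msg, ...) {
  abort(msg, class = "ki67_io_error", ...)
}

#' Round half away from zero
#'
#' Percentage tables in pathology reports conventionally round halves up
#' (12.25 -> 12.3), unlike [round()]'s round-half-to-even. Counts stay
#' authoritative; this only affects displayed percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.5, 21.85), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Percentage of count/total, half-up rounded.
pct_of <- function(count, total, digits = 1) {
  round_half_up(100 * count / total, digits)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_probability <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    abort_validation(sprintf("`%s` must be a single number in [0, 1], not %s.",
                             name, deparse(substitute(x))))
  }
  invisible(x)
}

check_percentage <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 100)) {
    abort_validation(sprintf("`%s` must be within [0, 100].", name))
  }
  invisible(x)
}

# Derive a per-unit RNG seed from a root seed: deterministic, stays in
# [1, 2^31 - 2] so it is always a valid R integer seed.
derive_seed <- function(root, index) {
  as.integer((as.numeric(root) * 48271 + as.numeric(index) * 1000003) %%
               2147483646 + 1)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
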