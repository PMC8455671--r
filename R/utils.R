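#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; clinical papers round printed
#' percentages half away from zero (63.65 -> 63.7). Used for all reported
#' percentages so worked examples match printed values digit for digit.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.25, -0.25, 63.65), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with call. = FALSE everywhere; short wrapper keeps messages uniform
.fail <- function(...) stop(..., call. = FALSE)

.assert_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .fail(sprintf("'%s' must be a single numeric probability", name))
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok)
    .fail(sprintf("'%s' must lie in %s, got %g", name,
                  if (open) "(0, 1)" else "[0, 1]", x))
  invisible(x)
}
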