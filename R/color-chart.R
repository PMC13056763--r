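#' Urine color chart breakpoints
#'
#' Fixed mapping from urine specific gravity (USG) to the 7-level ordinal
#' urine color (Uc) scale. The breakpoints are chosen so that shades 1-2
#' cover USG at or below the low reference cut-off (1.012) and shade 3
#' starts strictly above it, which makes the color item of the four-item
#' score ("shade <= 2 suggests a low urine concentration") coherent with
#' the USG reference classification by construction.
#'
#' @return A tibble with columns `color` (1-7) and `usg_max`, the upper USG
#'   bound (inclusive) of each shade; shade 7 is open-ended.
#' @export
#' @examples
#' color_chart()
color_chart <- function() {
  tibble::tibble(
    color   = 1:7,
    usg_max = c(1.006, 1.012, 1.017, 1.022, 1.027, 1.032, Inf)
  )
}

#' Map urine specific gravity to an ordinal color score
#'
#' Monotone non-decreasing step mapping from USG to the 1-7 urine color
#' scale via [color_chart()], with optional ordinal misclassification:
#' with probability `noise` the score is perturbed by one level (direction
#' chosen at random), then clamped to 1..7.
#'
#' @param usg Numeric vector of specific gravities in \[1.000, 1.040\].
#' @param noise Probability in \[0, 1\] of a one-level scoring error.
#' @return Integer vector of color scores in 1..7.
#' @export
#' @examples
#' color_from_usg(c(1.005, 1.012, 1.020))
color_from_usg <- function(usg, noise = 0) {
  stopifnot(is.numeric(usg), length(noise) == 1, noise >= 0, noise <= 1)
  if (any(is.na(usg)) || any(usg < 1.000) || any(usg > 1.040)) {
    stop("`usg` must lie within the physiologic range [1.000, 1.040]",
         call. = FALSE)
  }
  chart <- color_chart()
  # left-open intervals (b[i], b[i+1]] so each shade's upper bound is inclusive
  col <- 1L + findInterval(usg, chart$usg_max[1:6], left.open = TRUE)
  if (noise > 0) {
    flip <- runif(length(col)) < noise
    step <- sample(c(-1L, 1L), length(col), replace = TRUE)
    col[flip] <- col[flip] + step[flip]
    col <- pmax.int(pmin.int(col, 7L), 1L)
  }
  as.integer(col)
}
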