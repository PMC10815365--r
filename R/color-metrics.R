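#' CIELAB colour coordinates
#'
#' Light container for a CIELAB triple (L*, a*, b*) as reported by a
#' colorimeter. Lightness L* must lie in \[0, 100\]; the chromatic axes a*
#' (red-green) and b* (yellow-blue) are unbounded but must be finite. No
#' gamut clipping is applied.
#'
#' @param L lightness, in \[0, 100\].
#' @param a red-green coordinate (positive = redder).
#' @param b yellow-blue coordinate (positive = yellower).
#' @return An object of class `color_cie` with fields `L`, `a`, `b`.
#' @examples
#' color_cie(61.4, 9.8, 40.2)
#' @export
color_cie <- function(L, a, b) {
  for (v in list(L = L, a = a, b = b)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("color_cie: L, a, b must each be a single finite number",
           call. = FALSE)
    }
  }
  if (L < 0 || L > 100) {
    stop("color_cie: L must lie in [0, 100], got ", L, call. = FALSE)
  }
  structure(list(L = as.numeric(L), a = as.numeric(a), b = as.numeric(b)),
            class = "color_cie")
}

as_color_cie <- function(x) {
  if (inherits(x, "color_cie")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(color_cie(x[[1]], x[[2]], x[[3]]))
  stop("expected a color_cie or a numeric triple (L, a, b)", call. = FALSE)
}

#' @export
print.color_cie <- function(x, ...) {
  cat(sprintf("CIELAB colour: L* = %.2f, a* = %.2f, b* = %.2f\n",
              x$L, x$a, x$b))
  invisible(x)
}

#' Total colour difference (Delta E*ab)
#'
#' Euclidean distance between two CIELAB colours,
#' \eqn{\Delta E = \sqrt{(L_0-L)^2 + (a_0-a)^2 + (b_0-b)^2}}. In storage
#' studies the reference is the fresh (day-0) colour, so a fruit measured
#' against its own baseline scores 0 and the value grows as the fruit
#' discolours.
#'
#' @param ref reference colour (`color_cie` or numeric triple), e.g. the
#'   day-0 batch mean.
#' @param cur current colour.
#' @return Non-negative scalar; symmetric in its arguments.
#' @examples
#' delta_e(color_cie(50, 0, 0), color_cie(47, 4, 0)) # 5
#' @export
delta_e <- function(ref, cur) {
  ref <- as_color_cie(ref)
  cur <- as_color_cie(cur)
  sqrt((ref$L - cur$L)^2 + (ref$a - cur$a)^2 + (ref$b - cur$b)^2)
}

#' Browning chromaticity coordinate
#'
#' The intermediate chromaticity value
#' \eqn{x = (a + 1.75 L) / (5.645 L + a - 3.012 b)} used by the browning
#' index. The denominator vanishes for degenerate colours (e.g. pure black
#' with a = b = 0), which is rejected.
#'
#' @param c a `color_cie` or numeric triple.
#' @return Scalar chromaticity value.
#' @seealso [browning_index()]
#' @export
browning_x <- function(c) {
  c <- as_color_cie(c)
  den <- 5.645 * c$L + c$a - 3.012 * c$b
  if (abs(den) < .Machine$double.eps * 100 * max(1, abs(c$L), abs(c$a), abs(c$b))) {
    stop("browning_x: degenerate colour, denominator 5.645*L + a - 3.012*b is zero",
         call. = FALSE)
  }
  (c$a + 1.75 * c$L) / den
}

#' Browning index (BI)
#'
#' Chromaticity-based scalar quantifying brown discolouration of plant
#' tissue: \eqn{BI = 100 (x - 0.31) / 0.170} with `x` from [browning_x()].
#' BI is zero exactly when the chromaticity equals the reference value 0.31,
#' and increases as the colour moves toward brown.
#'
#' @inheritParams browning_x
#' @return Scalar browning index (can be negative for colours less brown
#'   than the 0.31 reference chromaticity).
#' @examples
#' browning_index(color_cie(40, 10, 20))
#' @export
browning_index <- function(c) {
  100 * (browning_x(c) - 0.31) / 0.170
}
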