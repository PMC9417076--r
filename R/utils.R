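`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 2.2222 -> 2.2 and 15.5555 -> 15.6 at one decimal), unlike base
#' [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_named <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "imuagree_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_named("imuagree_nonfinite", "%s contains non-finite values", what)
  }
  invisible(x)
}

DEVICES    <- c("test", "criterion")
LOCATIONS  <- c("sacrum", "thigh", "shank")
ACTIVITIES <- c("squat", "jump", "walk", "stair_ascent", "stair_descent")
AXES       <- c("z", "x", "y")
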