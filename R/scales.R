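#' Define a depression rating scale
#'
#' A scale is identified by name and by the minimum and maximum total score it
#' can produce. The score range (`max_score - min_score`) is what the
#' severity-fraction transformation divides by, so that baseline severities
#' recorded on different instruments become comparable.
#'
#' @param name Scale name, e.g. `"CDRS-R"` or `"HAM-D"`.
#' @param min_score Lowest attainable total score.
#' @param max_score Highest attainable total score; must exceed `min_score`.
#' @return An object of class `"scale_spec"`: a list with elements `name`,
#'   `min_score`, `max_score` and `range`.
#' @examples
#' cdrs <- scale_spec("CDRS-R", 17, 113)
#' score_to_fraction(51.56, cdrs)
#' @export
scale_spec <- function(name, min_score, max_score) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  min_score <- as.numeric(min_score)
  max_score <- as.numeric(max_score)
  if (!is.finite(min_score) || !is.finite(max_score) || max_score <= min_score) {
    stop("scale '", name, "': max_score must be finite and exceed min_score",
         call. = FALSE)
  }
  structure(
    list(name = name, min_score = min_score, max_score = max_score,
         range = max_score - min_score),
    class = "scale_spec"
  )
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("<scale_spec> %s [%g, %g] (range %g)\n",
              x$name, x$min_score, x$max_score, x$range))
  invisible(x)
}

#' Built-in scale registry
#'
#' The two instruments used throughout: the Children's Depression Rating
#' Scale, Revised (total score 17-113, range 96) and the Hamilton Depression
#' Rating Scale (0-52 by convention here; HAM-D variants differ in item count,
#' so real data should supply their own bounds via the scales CSV).
#'
#' @return A data frame with columns `name`, `min_score`, `max_score`.
#' @export
default_scales <- function() {
  data.frame(
    name = c("CDRS-R", "HAM-D"),
    min_score = c(17, 0),
    max_score = c(113, 52),
    stringsAsFactors = FALSE
  )
}

resolve_scale <- function(scale) {
  if (inherits(scale, "scale_spec")) return(scale)
  if (is.list(scale) && all(c("name", "min_score", "max_score") %in% names(scale))) {
    return(scale_spec(scale$name[[1L]], scale$min_score[[1L]], scale$max_score[[1L]]))
  }
  stop("'scale' must be a scale_spec or a list/row with name, min_score, max_score",
       call. = FALSE)
}

#' Convert a raw scale score to a fraction of the scale range
#'
#' `fraction = (score - min) / (max - min)`, so 0 is the scale floor and 1 the
#' ceiling. On the CDRS-R (17-113) a mean of 51.56 corresponds to fraction
#' 0.36 and 57.32 to 0.42.
#'
#' @param score Numeric vector of scores in scale units.
#' @param scale A [scale_spec()] (or a list/row carrying `name`, `min_score`,
#'   `max_score`).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @seealso [fraction_to_score()] for the exact inverse.
#' @export
score_to_fraction <- function(score, scale) {
  scale <- resolve_scale(scale)
  score <- as.numeric(score)
  ok <- is.na(score) | (score >= scale$min_score & score <= scale$max_score)
  if (!all(ok)) {
    stop(sprintf("score %g outside bounds [%g, %g] of scale '%s'",
                 score[!ok][1L], scale$min_score, scale$max_score, scale$name),
         call. = FALSE)
  }
  (score - scale$min_score) / scale$range
}

#' Convert a fraction of a scale range back to scale units
#'
#' `score = min + fraction * (max - min)`; the exact inverse of
#' [score_to_fraction()].
#'
#' @param fraction Numeric vector in `[0, 1]`.
#' @inheritParams score_to_fraction
#' @return Numeric vector of scores in scale units.
#' @export
fraction_to_score <- function(fraction, scale) {
  scale <- resolve_scale(scale)
  fraction <- as.numeric(fraction)
  ok <- is.na(fraction) | (fraction >= 0 & fraction <= 1)
  if (!all(ok)) {
    stop(sprintf("fraction %g outside [0, 1]", fraction[!ok][1L]), call. = FALSE)
  }
  scale$min_score + fraction * scale$range
}
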