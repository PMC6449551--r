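#' Pain class codes
#'
#' The four thermal pain conditions, coded as in the stimulation paradigm:
#' 1 = LowCold, 2 = LowHeat, 3 = HighCold, 4 = HighHeat. Modality (cold/heat)
#' crosses intensity (low pain = threshold, high pain = tolerance).
#'
#' @format Named integer vector of length 4 (names are the class names).
#' @export
pain_classes <- c(LowCold = 1L, LowHeat = 2L, HighCold = 3L, HighHeat = 4L)

#' Convert between pain class codes and names
#'
#' @param x Integer codes in 1..4, or class names.
#' @return `pain_class_name()` returns the class names for integer codes;
#'   `pain_class_code()` returns integer codes for names. Both error on
#'   unknown values.
#' @examples
#' pain_class_name(c(1, 4))
#' pain_class_code("HighCold")
#' @export
pain_class_name <- function(x) {
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 1L | x > 4L)) {
    stop("pain class codes must be integers in 1..4", call. = FALSE)
  }
  names(pain_classes)[x]
}

#' @rdname pain_class_name
#' @export
pain_class_code <- function(x) {
  idx <- match(as.character(x), names(pain_classes))
  if (any(is.na(idx))) {
    stop("unknown pain class name(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  unname(pain_classes[idx])
}
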