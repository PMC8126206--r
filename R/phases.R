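#' Phase vocabulary
#'
#' The seven-class phase vocabulary used throughout the package. A fall
#' trial recorded under the laboratory protocol traverses, in order:
#' initial-static, pre-fall, free-fall, impact, resting, recovery and
#' ending-static. Integer codes 0--6 map onto the names in that canonical
#' order; the mapping is fixed and is relied upon by the classifiers, the
#' fragment-modification pass and the evaluation metrics.
#'
#' @return A character vector of the seven phase names, named by their
#'   integer codes `"0"` ... `"6"`.
#' @examples
#' phase_names()
#' phase_code("impact")
#' phase_name(2L)
#' @export
phase_names <- function() {
  c("0" = "initial-static",
    "1" = "pre-fall",
    "2" = "free-fall",
    "3" = "impact",
    "4" = "resting",
    "5" = "recovery",
    "6" = "ending-static")
}

#' @rdname phase_names
#' @param name Character vector of phase names.
#' @return `phase_code()`: the integer code(s) for `name`.
#' @export
phase_code <- function(name) {
  vocab <- phase_names()
  idx <- match(name, vocab)
  if (anyNA(idx)) {
    stop("unknown phase name(s): ",
         paste(unique(name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  as.integer(idx - 1L)
}

#' @rdname phase_names
#' @param code Integer vector of phase codes in 0--6.
#' @return `phase_name()`: the name(s) for `code`.
#' @export
phase_name <- function(code) {
  check_phase_codes(code)
  unname(phase_names()[as.integer(code) + 1L])
}

check_phase_codes <- function(code) {
  code <- as.integer(code)
  if (anyNA(code) || any(code < 0L | code > 6L)) {
    stop("phase codes must be integers in 0..6", call. = FALSE)
  }
  invisible(code)
}

PHASE_INITIAL_STATIC <- 0L
PHASE_PRE_FALL <- 1L
PHASE_FREE_FALL <- 2L
PHASE_IMPACT <- 3L
PHASE_RESTING <- 4L
PHASE_RECOVERY <- 5L
PHASE_ENDING_STATIC <- 6L
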