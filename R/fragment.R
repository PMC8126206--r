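#' Fragment modification
#'
#' Rule-based repair of short misclassification fragments in a
#' segment-label sequence. Because the protocol starts and ends with quiet
#' standing, the first segment is forced to initial-static and the last
#' three segments to ending-static. A single left-to-right pass over the
#' interior then repairs fragments of one, two or three segments whose
#' labels differ from identical flanking segments: writing in 1-based
#' pseudo-indices over `i = 2 .. N-3`, if `phase[i] != phase[i-1]` and
#' `phase[i-1]` reappears at `phase[i+1]`, `phase[i+2]` or `phase[i+3]`
#' (with the intervening segments also differing from `phase[i-1]`), then
#' `phase[i]` is overwritten with `phase[i-1]`. Repairs are applied in
#' place, so an overwritten segment feeds the comparisons of later
#' positions; a two- or three-segment fragment is therefore absorbed one
#' segment per iteration. The pass is deliberately single (not iterated to
#' convergence).
#'
#' Index mapping: pseudo-index `i` (1-based) corresponds to R index `i` on
#' the label vector; positions are reported 0-based elsewhere in the
#' package but this function operates on plain label vectors.
#'
#' @param labels Integer vector of segment phase codes (0--6), length >= 4.
#' @return Integer vector of modified codes, same length.
#' @examples
#' modify_fragments(c(1, 1, 2, 1, 1, 1, 1, 1))
#' @export
modify_fragments <- function(labels) {
  ph <- check_phase_codes(labels)
  N <- length(ph)
  if (N < 4L) {
    stop("sequence-too-short: fragment modification needs >= 4 segments",
         call. = FALSE)
  }
  ph[1L] <- PHASE_INITIAL_STATIC
  ph[N] <- PHASE_ENDING_STATIC
  ph[N - 1L] <- PHASE_ENDING_STATIC
  ph[N - 2L] <- PHASE_ENDING_STATIC
  if (N >= 5L) {
    for (i in 2:(N - 3L)) {
      prev <- ph[i - 1L]
      if (ph[i] != prev) {
        if (ph[i + 1L] == prev) {
          ph[i] <- prev
        } else if (ph[i + 2L] == prev) {
          ph[i] <- prev
        } else if (i + 3L <= N && ph[i + 3L] == prev) {
          ph[i] <- prev
        }
      }
    }
  }
  ph
}

#' @rdname modify_fragments
#' @details `modify_fragments_oracle()` is a literal line-by-line
#'   transcription of the rule pass, kept free of any simplification so it
#'   can serve as an independent reference in tests.
#' @export
modify_fragments_oracle <- function(labels) {
  phase <- check_phase_codes(labels)
  N <- length(phase)
  if (N < 4L) {
    stop("sequence-too-short: fragment modification needs >= 4 segments",
         call. = FALSE)
  }
  sphase1 <- PHASE_INITIAL_STATIC
  sphase7 <- PHASE_ENDING_STATIC
  mphase <- phase
  phase[1] <- sphase1
  phase[N] <- sphase7
  phase[N - 1] <- sphase7
  phase[N - 2] <- sphase7
  if (2 <= N - 3) {
    for (i in 2:(N - 3)) {
      if (phase[i] != phase[i - 1] && phase[i - 1] == phase[i + 1]) {
        phase[i] <- phase[i - 1]
      } else if (phase[i] != phase[i - 1] && phase[i + 1] != phase[i - 1] &&
                 phase[i - 1] == phase[i + 2]) {
        phase[i] <- phase[i - 1]
      } else if (phase[i] != phase[i - 1] && phase[i + 1] != phase[i - 1] &&
                 phase[i + 2] != phase[i - 1] && phase[i - 1] == phase[i + 3]) {
        phase[i] <- phase[i - 1]
      }
      mphase[i] <- phase[i]
    }
  }
  mphase[1] <- sphase1
  mphase[N] <- sphase7
  mphase[N - 1] <- sphase7
  mphase[N - 2] <- sphase7
  mphase
}
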