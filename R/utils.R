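#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

# Internal RNG helpers: every generator is a pure function of (parameters,
# seed). Randomness is drawn inside a local RNG scope so the caller's
# .Random.seed is never touched, and a master seed spawns per-subject
# substreams by fixed integer arithmetic.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a reproducible substream seed
#'
#' Fixed integer arithmetic mapping a master seed plus a (subject, stage)
#' index pair to a new seed below 2^31, so every stage and subject can be
#' re-run in isolation.
#'
#' @param seed Master seed.
#' @param index Substream index (e.g. subject number).
#' @param stream Stream id (e.g. stage number).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, index, stream = 0L) {
  s <- (as.double(seed) * 48271 + as.double(index) * 9349 +
          as.double(stream) * 6581 + 1) %% 2147483647
  as.integer(s)
}

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style canonical HRF: a peak gamma density minus a scaled undershoot
#' gamma density, normalised to unit peak. `hrf_canonical(0)` is 0 by
#' construction, so event-locked averages start at baseline.
#'
#' @param t Time in seconds (vector).
#' @param peak_delay,under_delay Shape parameters (seconds) of the response
#'   peak and undershoot; defaults 6 and 16.
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return Numeric vector of HRF values, max 1.
#' @export
hrf_canonical <- function(t, peak_delay = 6, under_delay = 16, ratio = 6) {
  h <- dgamma(t, shape = peak_delay, rate = 1) -
    dgamma(t, shape = under_delay, rate = 1) / ratio
  hmax <- max(dgamma(seq(0, 30, by = 0.01), shape = peak_delay, rate = 1))
  h / hmax
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
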