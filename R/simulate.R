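#' Simulate a shape-factor time series
#'
#' Generates one nucleus's SF trajectory as a two-state Markov chain
#' (round/squeeze) with the regime's per-frame transition probabilities.
#' The emitted SF is the state's baseline value plus truncated Gaussian
#' jitter, clipped so that the emitted value always lies on the state's
#' side of the 0.4 squeezing threshold (the ground-truth squeeze flag is
#' therefore exactly `sf >= 0.4`). The initial state is drawn from the
#' chain's stationary distribution.
#'
#' @param regime a [synth_regime()].
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed for this series.
#' @return tibble with columns `frame` (0-based), `sf`, `squeezing`.
#' @examples
#' simulate_sf_series(synth_regime("vessel"), n_frames = 40, seed = 7)
#' @export
simulate_sf_series <- function(regime, n_frames, seed = 1) {
  if (!inherits(regime, "synth_regime")) abort("regime must be a synth_regime")
  validate_regime(regime)
  if (n_frames < 1) abort("n_frames must be >= 1")

  pe <- regime$p_enter_squeeze
  px <- regime$p_exit_squeeze

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  state <- logical(n_frames) # TRUE = squeezing
  occ <- if (pe + px > 0) pe / (pe + px) else 0
  state[1] <- runif(1) < occ
  if (n_frames > 1) {
    u <- runif(n_frames - 1)
    for (i in 2:n_frames) {
      state[i] <- if (state[i - 1]) u[i - 1] >= px else u[i - 1] < pe
    }
  }

  jit_sd <- regime$sf_jitter_sd
  jitter <- rnorm(n_frames, 0, jit_sd)
  mu <- ifelse(state, regime$sf_squeeze, regime$sf_baseline)
  sf <- mu + jitter
  thr <- 0.4
  eps <- 1e-4
  # truncate the jitter (4 sd) and keep the emitted value inside its
  # state's band and inside [0, 1), so squeeze flag <=> sf >= 0.4 and
  # rendered geometry stays bounded
  lo <- pmax(ifelse(state, thr, 0), mu - 4 * jit_sd)
  hi <- pmin(ifelse(state, 1 - eps, thr - eps), mu + 4 * jit_sd)
  sf <- pmin(pmax(sf, lo), hi)

  tibble(frame = seq_len(n_frames) - 1L, sf = sf, squeezing = state)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
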