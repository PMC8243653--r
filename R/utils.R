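# Small shared numeric helpers.

#' Round half away from zero
#'
#' Annotation sample remapping and millisecond-to-sample conversion use
#' round-half-away-from-zero (not banker's rounding) so that 0.5 sample
#' ties always move outward, symmetrically for negative offsets.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Full linear convolution via FFT, numerically exact to ~1e-12 for the
# signal lengths used here.
conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  X <- fft(c(x, rep(0, nf - length(x))))
  H <- fft(c(h, rep(0, nf - length(h))))
  Re(fft(X * H, inverse = TRUE))[seq_len(n)] / nf
}

# Mirror (symmetric) extension of a vector by `p` samples on each side.
mirror_pad <- function(x, p) {
  n <- length(x)
  if (p <= 0) return(x)
  if (p > n - 1) stop("mirror_pad: pad longer than signal")
  c(x[(p + 1):2], x, x[(n - 1):(n - p)])
}

#' Derive a child seed from a master seed
#'
#' Every stochastic stage (fold tie-breaks, per-class capping, tree
#' training, per-patient synthesis) draws from its own seed derived from
#' the single master seed and a stage tag, so no stage consumes global
#' RNG state meant for another. The derivation is a small deterministic
#' string hash folded into \[0, 2^31).
#'
#' @param master integer master seed.
#' @param tag character stage tag (e.g. `"fold"`, `"cap2"`, `"tree17"`).
#' @return integer seed in \[0, 2^31).
#' @export
derive_seed <- function(master, tag) {
  h <- as.double(master %% 2147483647)
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
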