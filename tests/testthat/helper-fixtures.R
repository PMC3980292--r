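# Small fixtures shared across test files, built in code.

small_protocol <- function(n_labels = 6, isi = 20, seed = 2, ...) {
  generate_protocol(sprintf("s%02d", seq_len(n_labels)),
                    interstimulus_frames = isi, frame_rate = 5, seed = seed,
                    ...)
}

# A compact movie with full ground truth; noiseless/clean by default so
# exact algebraic properties can be asserted.
small_truth <- function(shape = c(30, 30), n_units = 3, noise_sigma = 0,
                        seed = 5, n_artifacts = 0, ...) {
  generate_ground_truth(shape, n_units, small_protocol(), radius_range = c(3, 5),
                        noise_sigma = noise_sigma, seed = seed,
                        n_artifacts = n_artifacts, ...)
}

# Noiseless conical mixture with pure columns: c_true sources, each with a
# pure pixel, plus mixed columns; returns list(A, pure, traces, mixing).
conical_mixture <- function(c_true = 5, n_mixed = 40, m = 80, seed = 11) {
  with_seed(seed, {
    traces <- matrix(abs(rnorm(m * c_true)), m, c_true)
    mixing <- matrix(0, c_true, c_true + n_mixed)
    mixing[cbind(seq_len(c_true), seq_len(c_true))] <- runif(c_true, 0.8, 1.2)
    for (j in seq_len(n_mixed))   # scatter fringes: total mixed weight < pure
      mixing[, c_true + j] <- runif(c_true, 0, 0.5 / c_true)
    list(A = traces %*% mixing, pure = seq_len(c_true),
         traces = traces, mixing = mixing)
  })
}
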