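# small deterministic fixtures used across tests

clean_population <- function(n = 5, seed = 3) {
  sample_population(n, seed = seed, noise_sd = 0, wander_amp = 0)
}

clean_record <- function(seed = 3, duration_s = 20, fs = 500, subject = 1) {
  pop <- clean_population(max(2, subject), seed = seed)
  synthesize_record(pop[subject, ], duration_s = duration_s, fs = fs,
                    seed = seed)
}

# deterministic pseudo-image batch for classifier contract tests; classes
# differ by the position of a bright block (batch norm cancels plain
# brightness offsets, so the class signal must be spatial)
toy_images <- function(n_per_class = 6, classes = 2, size = 32, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = rep(sprintf("C%d", seq_len(classes)), each = n_per_class),
    image = lapply(seq_len(classes * n_per_class), function(i) {
      cls <- (i - 1) %/% n_per_class
      im <- array(sample(0:60, size^2 * 3, TRUE), c(size, size, 3))
      rows <- (cls * 8 + 1):(cls * 8 + 8)
      im[rows, , ] <- im[rows, , ] + 180
      im
    })
  )
}
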