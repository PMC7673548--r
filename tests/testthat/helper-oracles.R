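# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive O(N^2) DFT, grid-search cosine fits, and
# textbook formulas, kept dumb and readable.

# naive O(N^2) discrete Fourier transform, component k (0-based)
naive_dft <- function(x, k) {
  n <- length(x)
  sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n))
}

# best cosine at 1/period by exhaustive search over phases
grid_search_cosine <- function(x, period, n_phase = 720) {
  t <- seq_along(x) - 1
  phases <- seq(0, 2 * pi, length.out = n_phase + 1)[seq_len(n_phase)]
  rs <- vapply(phases, function(p) {
    stats::cor(x, cos(2 * pi * t / period - p))
  }, numeric(1))
  list(r = max(rs), ph = phases[which.max(rs)])
}

# textbook circular standard deviation (second, independent implementation)
textbook_circ_sd <- function(a) {
  C <- mean(cos(a)); S <- mean(sin(a))
  sqrt(-2 * log(sqrt(C^2 + S^2)))
}

# population sd by direct enumeration
enum_pop_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))

# small fast protocol shared by several tests (4 trials of 10 volumes)
tiny_protocol <- function() {
  protocol_config(trials_per_run = 4, runs_per_condition = 2,
                  n_participants = 2)
}
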