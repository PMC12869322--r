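# Independent oracles, kept deliberately naive: direct textbook formulas
# and brute-force enumeration, never calling the package functions they
# are used to check.

# two-group Hedge's g by the textbook formula, one feature at a time
g_oracle <- function(patient_values, control_values) {
  n1 <- length(patient_values)
  n0 <- length(control_values)
  sp <- sqrt(((n1 - 1) * stats::var(patient_values) +
                (n0 - 1) * stats::var(control_values)) / (n1 + n0 - 2))
  d <- (mean(patient_values) - mean(control_values)) / sp
  d * (1 - 3 / (4 * (n1 + n0) - 9))
}

# per-feature g over a matrix, patients = TRUE rows
g_oracle_matrix <- function(x, patient) {
  apply(x, 2, function(col) g_oracle(col[patient], col[!patient]))
}

# BH step-up by literal enumeration of the rule
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# AUC as the brute-force pairwise-comparison probability
auc_oracle <- function(scores, positive) {
  s1 <- scores[positive]
  s0 <- scores[!positive]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# rank-sum U statistic by exhaustive pair counting (x vs y)
u_oracle <- function(x, y) {
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot
}

# dominant FFT amplitude of a sinusoidal component at frequency f_hz
fft_amplitude <- function(x, tr, f_hz) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / (n * tr)
  amp <- Mod(stats::fft(x)) / n * 2
  amp[which.min(abs(freqs - f_hz))]
}
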