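# Shared fixtures and independent oracles, built in code at test time.

# Tiny beta matrix with named dims.
tiny_beta <- function(values, samples, probes) {
  matrix(values, nrow = length(samples), ncol = length(probes),
         dimnames = list(samples, probes))
}

# Independent sort-based median oracle (no stats::median).
median_oracle <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) return(NA_real_)
  s <- sort(unname(v))
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Independent loop-based biweight midcorrelation oracle, written directly
# from the defining formula with scalar arithmetic only.
bicor_oracle <- function(x, y) {
  n <- length(x)
  mx <- median_oracle(x); my <- median_oracle(y)
  dx <- median_oracle(abs(x - mx)); dy <- median_oracle(abs(y - my))
  if (dx == 0 || dy == 0) return(stats::cor(x, y))
  xt <- numeric(n); yt <- numeric(n)
  for (i in seq_len(n)) {
    u <- (x[i] - mx) / (9 * dx)
    a <- if (abs(u) < 1) (1 - u^2)^2 else 0
    xt[i] <- (x[i] - mx) * a
    v <- (y[i] - my) / (9 * dy)
    b <- if (abs(v) < 1) (1 - v^2)^2 else 0
    yt[i] <- (y[i] - my) * b
  }
  num <- 0; sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    num <- num + xt[i] * yt[i]
    sx <- sx + xt[i]^2
    sy <- sy + yt[i]^2
  }
  num / (sqrt(sx) * sqrt(sy))
}

# Small GA-signal simulation for fast clock tests.
small_clock_sim <- function(n = 120, p = 300, k = 15, seed = 42L, ...) {
  simulate_dataset(sim_config(n_samples = n, n_probes = p, n_clock_probes = k,
                              seed = seed, ...))
}

# Minimal sample sheet for a beta matrix.
sheet_for <- function(beta, ga, sex = "unknown", condition = "control") {
  data.frame(sample_id = rownames(beta), ga_weeks = ga, sex = sex,
             condition = condition, stratum = condition, platform = "450K",
             stringsAsFactors = FALSE)
}
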