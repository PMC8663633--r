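# Shared fixtures, built once per test run.

# Small healthy cohort and its normative profiles (right side only, short
# walks keep the suite fast).
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sims <- simulate_healthy_cohort(5, seed = 77, sides = "R",
                                      n_steps = 14)
      norm <- build_normative_set(lapply(sims, `[[`, "recording"))
      cache <<- list(sims = sims, normatives = norm)
    }
    cache
  }
})

# A tiny valid recording for IO tests.
make_toy_recording <- function(n = 250, footswitch = TRUE, seed = 5) {
  set.seed(seed)
  chans <- list(channel_label("L", "TA"), channel_label("R", "SOL"))
  emg_recording(matrix(rnorm(2 * n), ncol = 2), chans,
                sampling_rate = 1000,
                footswitch = if (footswitch) rep_len(c(1L, 0L), n),
                subject_id = "T01", timepoint = "T1", group = "CG")
}

# Direct-counting BDSI oracle, independent of the implementation.
bdsi_oracle <- function(a, b) {
  hits <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) hits <- hits + 1
    if (a[i] == 0 && b[i] == 0) hits <- hits + 1
  }
  hits / length(a) * 100
}

# All masks of length n as rows of a matrix.
all_masks <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

# Exact two-sided signed-rank p-value by enumerating sign assignments.
signflip_p_oracle <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- all_masks(n)
  vs <- as.numeric(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(vs <= v_obs + eps), mean(vs >= v_obs - eps)))
}
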