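# Shared fixtures. Everything is generated in code; the heavier Monte-Carlo
# run used by several acceptance checks is computed once per test session.

std_chirp_spec <- function(window = "rectangular", down = FALSE) {
  if (down) chirp_spec(41e3, 39e3, 7e-3, 125e3, window = window)
  else chirp_spec(39e3, 41e3, 7e-3, 125e3, window = window)
}

std_chirp <- function(...) make_chirp(std_chirp_spec(...))

# Two-path received waveform built from individually propagated copies
# (amplitudes set directly, so relative path strength is exact).
two_path_trace <- function(a_los, a_nlos, extra, los = 1,
                           template = std_chirp()) {
  rx1 <- propagate(template, channel_spec(los, attenuation_const = 0,
                                          snr_db = Inf))
  rx2 <- propagate(template, channel_spec(los + extra, attenuation_const = 0,
                                          snr_db = Inf))
  n <- max(length(rx1$samples), length(rx2$samples))
  pad <- function(x) c(x, numeric(n - length(x)))
  matched_filter(waveform(a_los * pad(rx1$samples) +
                          a_nlos * pad(rx2$samples), 125e3),
                 template)
}

.fixture_env <- new.env(parent = emptyenv())

# Medium-sized Monte-Carlo run shared by the acceptance checks
# (2,000 iterations; the full study uses 10,000 — see scripts/acceptance.R).
acceptance_mc_run <- function() {
  if (is.null(.fixture_env$mc)) {
    .fixture_env$mc <- run_mc(mc_config(n_iter = 2000,
                                        m_values = c(1.1, 2, 3, 4),
                                        seed = 20260922))
  }
  .fixture_env$mc
}

# Bootstrap standard error of a paired-metric statistic over iterations.
boot_se <- function(errors, stat, n_boot = 200, seed = 1) {
  n <- nrow(errors)
  vals <- with_seed_local(seed, {
    replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      stat(errors[idx, , drop = FALSE])
    })
  })
  stats::sd(vals)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
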