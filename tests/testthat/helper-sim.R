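# Shared simulation fixtures, built lazily and cached for the test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# noise-free profile with stride jitter off unless asked for
nf_profile <- function(belt_speed = 1.0, stride_time = 1.2, stride_cv = 0,
                       ...) {
  noise_free(gait_profile(belt_speed = belt_speed,
                          stride_time = stride_time,
                          stride_cv = stride_cv, ...))
}

nf_trial <- function(belt_speed = 1.0, stride_time = 1.2, duration = 126,
                     seed = 1, ...) {
  key <- paste("nf", belt_speed, stride_time, duration, seed,
               paste(deparse(list(...)), collapse = ""))
  cached(key, simulate_trial(
    nf_profile(belt_speed = belt_speed, stride_time = stride_time, ...),
    duration_walk = duration, seed = seed))
}

# short trial + analysis pair used by several files
nf_analysis <- function(belt_speed = 1.0, stride_time = 1.2,
                        duration = 126, seed = 1, ...) {
  key <- paste("an", belt_speed, stride_time, duration, seed,
               paste(deparse(list(...)), collapse = ""))
  tr <- nf_trial(belt_speed, stride_time, duration, seed, ...)
  list(trial = tr,
       analysis = cached(key, analyze_trial(tr$skeleton, tr$imus, tr$belt)))
}

# quadrature amplitude of a sinusoid at frequency f over a time window
sine_amplitude <- function(t, y, f, sel = rep(TRUE, length(t))) {
  a <- 2 * mean(y[sel] * sin(2 * pi * f * t[sel]))
  b <- 2 * mean(y[sel] * cos(2 * pi * f * t[sel]))
  sqrt(a^2 + b^2)
}

# window of an analysis restricted for event matching (boundary events are
# unresolvable): reference ICs at least one stride inside the window
interior_truth_ic <- function(trial, analysis, side) {
  interior_events(trial$truth$ic_times[[side]], analysis$window,
                  margin = trial$profile$stride_time)
}
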