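# Shared fixtures: small synthetic objects built in code at test time.

# a deterministic template + neutral frame pair, small enough for fast tests
fixture_template <- function(seed = 11L) make_template(seed)

fixture_neutral <- function(seed = 11L) {
  apply_expression(fixture_template(seed), "neutral", intensity = 0,
                   noise_sd = 0, noise_seed = 0L)
}

# stub classifiers for the session engine: functions (frames, expression)
oracle_classifier <- function(frames, expression) {
  rep(map_to_binary(expression), length(frames))
}

always_wrong_on <- function(bad_class) {
  function(frames, expression) {
    target <- map_to_binary(expression)
    if (expression == bad_class) {
      rep(setdiff(c("positive", "negative"), target), length(frames))
    } else {
      rep(target, length(frames))
    }
  }
}

always_wrong_classifier <- function(frames, expression) {
  target <- map_to_binary(expression)
  rep(setdiff(c("positive", "negative"), target), length(frames))
}

# classifier correct on exactly k of n frames
partial_classifier <- function(k) {
  function(frames, expression) {
    target <- map_to_binary(expression)
    other <- setdiff(c("positive", "negative"), target)
    n <- length(frames)
    c(rep(target, k), rep(other, n - k))
  }
}

# independent Hazen quartile oracle: position formula h = n*p + 0.5 with
# linear interpolation over the sorted sample
hazen_quantile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- n * pp + 0.5
    lo <- floor(h); hi <- ceiling(h)
    lo <- min(max(lo, 1), n); hi <- min(max(hi, 1), n)
    xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
  }, numeric(1))
}

# a small labeled cohort reused across classifier tests
small_cohort_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(
        cohort_spec(n_subjects = 3L, frames_per_expression = 6L,
                    seed = 7L))$features
    }
    cache
  }
})

# a trained model good enough to act as a near-oracle frame classifier
oracle_near_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_model(small_cohort_features(),
                            train_config(epochs = 60L, seed = 99L))
    }
    cache
  }
})

table1_counts <- c(anger = 9L, disgust = 9L, fear = 6L, happiness = 7L,
                   neutral = 12L, sadness = 0L, surprise = 16L)
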