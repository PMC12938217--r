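# Shared fixtures. Heavy objects are built once per test session and
# memoised here; every builder is fully seeded.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# a small, untrained network used by structural and single-step tests
fixture_net <- function() memo("net", function() init_network(model_params(), seed = 42))

# independent brute-force ABS oracle: a literal transcription of the
# four-case rule, scalar, no shared code with plasticity_case()
abs_oracle <- function(omega_E_pre, V_post, theta_pre, theta_minus, theta_plus) {
  if (omega_E_pre >= theta_pre && V_post >= theta_plus) return("LTP")
  if (omega_E_pre >= theta_pre && theta_minus <= V_post && V_post < theta_plus) return("LTD")
  if (omega_E_pre < theta_pre && V_post >= theta_plus) return("LTD")
  "none"
}

# brute-force interval-union oracle for episode segmentation: marks a
# per-step boolean timeline instead of merging intervals
episode_oracle <- function(events, horizon) {
  above <- matrix(FALSE, nrow = horizon, ncol = max(events$ca_id, 1))
  for (i in seq_len(nrow(events))) {
    if (events$end[i] > events$start[i])
      above[(events$start[i] + 1):events$end[i], events$ca_id[i]] <- TRUE
  }
  any_above <- rowSums(above) > 0
  r <- rle(any_above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  on <- which(r$values)
  data.frame(start = starts[on] - 1L, end = ends[on],
             coactive = vapply(on, function(j) {
               any(rowSums(above[starts[j]:ends[j], , drop = FALSE]) >= 2)
             }, logical(1)))
}

# random activity series whose events are easy to enumerate
random_activity_series <- function(n) round(runif(n), 2)
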