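# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small dataset: 2 subjects x 1 trial per activity, short trials
tiny_recordings <- function() {
  fixture("tiny_recordings", function() {
    generate_dataset(2, stats::setNames(rep(1L, 9), activity_codes()),
                     seed = 101, duration = 6)
  })
}

tiny_features <- function() {
  fixture("tiny_features", function() {
    pipeline_features(tiny_recordings())
  })
}

# random unit quaternion
random_quat <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}
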