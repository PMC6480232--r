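# Shared fixtures: scenarios and transfer matrices are expensive to build,
# so they are constructed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# the full-size default valley scenario used by the acceptance checks
acc_scenario <- function() {
  if (is.null(.fixture_cache$sc)) .fixture_cache$sc <- valley_scenario(seed = 1)
  .fixture_cache$sc
}

acc_transfer <- function() {
  if (is.null(.fixture_cache$tm)) {
    sc <- acc_scenario()
    .fixture_cache$tm <- suppressMessages(
      build_transfer_matrix(sc$sources, sc$receptors, sc$met))
  }
  .fixture_cache$tm
}

# a small scenario for unit tests (8 receptors, 48 hours)
tiny_scenario <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- valley_scenario(seed = 5, n_receptors = 8,
                                           n_hours = 48, calm_frac = 0.25)
  }
  .fixture_cache$tiny
}

tiny_transfer <- function() {
  if (is.null(.fixture_cache$tiny_tm)) {
    sc <- tiny_scenario()
    .fixture_cache$tiny_tm <- suppressMessages(
      build_transfer_matrix(sc$sources, sc$receptors, sc$met))
  }
  .fixture_cache$tiny_tm
}
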