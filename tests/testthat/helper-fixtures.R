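# Shared, lazily built fixtures. Generation is seeded and deterministic, so
# caching within a test run never changes results — it only avoids paying the
# descriptor computation more than once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# the assay-scale reactivation fixture (596 pairs, exact class quota)
s1_scale_fixture <- function() {
  cached("s1_scale", function() generate_sppo_fixture(seed = 101L))
}

# a small reactivation fixture for fast model checks
small_sppo_fixture <- function() {
  cached("small_sppo", function() {
    generate_sppo_fixture(n_sppos = 30L, noise_rate = 0, seed = 7L)
  })
}

# the regression-scale logBB fixture
logbb_scale_fixture <- function() {
  cached("logbb_scale", function() generate_logbb_fixture(seed = 101L))
}

# deterministic numeric toy features for classifier tests (no chemistry)
toy_features <- function(n, p = 5L, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("f", seq_len(p))))
  x
}
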