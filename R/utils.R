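# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed and a stream name, so that
# schedule construction, probe-delay draws, behaviour, etc. each consume an
# independent RNG stream. Kept below 2^31 - 1 so it is always a valid R seed.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Canonical order of the two levels within each cue dimension; used for
# deterministic tie-breaking in subjective relabelling.
dimension_levels <- function(dimension) {
  switch(dimension,
    color = c("blue", "red"),
    shape = c("animal", "object"),
    abort(paste0("unknown cue dimension: ", dimension))
  )
}

other_dimension <- function(dimension) {
  if (dimension == "color") "shape" else "color"
}

feature_dimension <- function(feature) {
  if (feature %in% c("blue", "red")) "color" else "shape"
}
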