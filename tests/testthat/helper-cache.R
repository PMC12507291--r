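# Heavy shared fixtures, computed once per test run.

.sv_cache <- new.env(parent = emptyenv())

# full 31-SF temporal-response-function fits against the sensitivity surface
cached_trf_fits <- function() {
  if (is.null(.sv_cache$fits)) .sv_cache$fits <- fit_trf_set()
  .sv_cache$fits
}

cached_surface <- function() {
  if (is.null(.sv_cache$surface))
    .sv_cache$surface <- fit_trf_surface(cached_trf_fits())
  .sv_cache$surface
}

# per-SF fits at the seven filter-bank channel frequencies
cached_bank_fits <- function() {
  if (is.null(.sv_cache$bank_fits)) {
    prev <- NULL
    .sv_cache$bank_fits <- lapply(bank_spec()$sf_set, function(th) {
      f <- fit_trf_for_sf(th, prev = prev)
      prev <<- f
      f
    })
  }
  .sv_cache$bank_fits
}

# the 40-trial synthetic battery (5 directions x present/absent x 4 draws)
cached_battery <- function() {
  if (is.null(.sv_cache$battery))
    .sv_cache$battery <- run_battery(seed = 1, surface = cached_surface())
  .sv_cache$battery
}

# small movie helper for filter tests
tiny_movie <- function(frames, pitch = 3.36 / 51, rate = 480) {
  structure(list(frames = frames, pitch = pitch, rate = rate),
            class = "retinal_movie")
}
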