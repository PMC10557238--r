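# Lazily computed 20-repetition ensemble of the canonical scenario, shared
# by the acceptance checks that look at the same study.

fig2d_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- fig2d_objects()
      trajs <- lapply(1:20, function(i)
        simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 730,
                     dt = 0.25, record_dt = 1, seed = 2000 + i,
                     releases = sc$releases, sprays = sc$sprays))
      series <- lapply(trajs, function(tr)
        allele_series(tr, sc$cube_off, features = c("W", "G", "H", "V"),
                      proportions = TRUE))
      cache <<- list(sc = sc, trajs = trajs, series = series)
    }
    cache
  }
})

# repetition x time matrix for one feature from a list of series tibbles
feature_matrix <- function(series, feat) {
  do.call(rbind, lapply(series, function(s)
    s$value[s$feature == feat]))
}
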