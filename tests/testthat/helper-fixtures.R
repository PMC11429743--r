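# Small in-code fixtures shared across test files.

# Marker matrix whose 2p-centered rows have known geometry (freq fixed at 0.5
# so centered dosages are exactly -1/0/+1): H1 == H2, H3 = -H1 (antipodal),
# H4 orthogonal to H1.
geometry_markers <- function() {
  new_marker_matrix(
    rbind(H1 = c(0L, 2L, 0L, 2L),
          H2 = c(0L, 2L, 0L, 2L),
          H3 = c(2L, 0L, 2L, 0L),
          H4 = c(0L, 2L, 2L, 0L)),
    freq = rep(0.5, 4)
  )
}

# A small simulated bundle reused by several files (fixed seed).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_hybrids = 60, n_markers = 300, n_locations = 4,
                        n_years = 3, n_states = 2, seed = 42)
      cache <<- simulate_g2f_bundle(cfg)
    }
    cache
  }
})

# Plot records for a single environment with a known block shift.
two_block_env <- function(shift = 2) {
  g <- rnorm(10)
  tibble::tibble(
    env_id = "E1",
    hybrid = rep(sprintf("H%02d", 1:10), each = 2),
    replicate = rep(1:2, 10),
    block = rep(c("B1", "B2"), 10),
    yield_mg_ha = 10 + rep(g, each = 2) + ifelse(rep(1:2, 10) == 2, shift, 0) +
      rnorm(20, 0, 0.2)
  )
}
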