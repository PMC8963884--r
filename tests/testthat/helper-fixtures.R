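# Shared fixtures, built in code.

circle_polygon <- function(r = 50, n = 200, center = c(0, 0),
                           phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# an irregular but smooth star-shaped polygon
blob_polygon <- function(r = 50, n = 180, wobble = 0.15, seed = 42) {
  set.seed(seed)
  k <- 2:4
  amp <- runif(3, 0, wobble)
  ph <- runif(3, 0, 2 * pi)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  rad <- r * (1 + Reduce(`+`, Map(function(kk, aa, pp)
    aa * cos(kk * ang + pp), k, amp, ph)))
  cbind(rad * cos(ang), rad * sin(ang))
}

# straight track along +x
straight_track <- function(n = 20, dt = 5, speed = 1) {
  data.frame(frame = 0:(n - 1), time = (0:(n - 1)) * dt,
             x = (0:(n - 1)) * speed * dt, y = 0)
}

# small phase diagram cached across acceptance tests (built on first use)
.cc_cache <- new.env(parent = emptyenv())

acceptance_diagram <- function() {
  if (is.null(.cc_cache$pd)) {
    .cc_cache$pd <- phase_diagram(replicates = 20L,
                                  base_params = compass_params(),
                                  seed = 20260925L)
  }
  .cc_cache$pd
}
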