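# Shared helpers: in-domain point sampling and tiny run configurations.

# sample n points inside the U-shaped domain (tubes + half torus), away from
# the wall by `margin`
sample_domain_points <- function(n, geom, xa = 0, margin = 0, seed = 1) {
  set.seed(seed)
  r <- geom$r0 - margin
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (runif(1) < 0.7) { # tubes
      side <- sample(c("left", "right"), 1)
      x <- runif(1, xa, geom$Xc)
      rho <- r * sqrt(runif(1))
      q <- runif(1, 0, 2 * pi)
      out[i, ] <- tube_position(x, rho, q, geom, side)
    } else {             # half torus, rejection on the volume element
      repeat {
        p <- runif(1, 0, pi)
        rho <- r * sqrt(runif(1))
        q <- runif(1, 0, 2 * pi)
        if (runif(1) < (geom$R + rho * cos(q)) / (geom$R + r)) break
      }
      out[i, ] <- torus_position(p, rho, q, geom)
    }
  }
  out
}

# a small, fast tissue configuration for engine behavior tests
tiny_config <- function(..., r0 = 12, R = 25, L = 130, duration = 20,
                        init_phase = "synchronized", seed = 1) {
  run_config(geometry = geometry_params(r0 = r0, R = R, L = L),
             duration = duration, init_phase = init_phase, seed = seed, ...)
}
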