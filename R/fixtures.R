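# Synthetic phase fields and toy segment records: oracles for the
# observables and fast test tissues.

#' Generate a planted synthetic phase field
#'
#' Places cells uniformly at random in a box and assigns phases by rule:
#' * `"uniform"`: all phases equal `phase0`;
#' * `"gradient"`: axial phase gradient `theta = phase0 + 2 pi x / wavelength`;
#' * `"random"`: i.i.d. uniform on \[0, 2 pi);
#' * `"vortex"`: `theta = s * atan2(w2 - c2, w1 - c1)` about the chosen axis
#'   (`s = +1` for `"ccw"`, `-1` for `"cw"`), a winding-number +/-1 vortex.
#'
#' @param rule phase assignment rule.
#' @param box box extents `c(Lx, Ly, Lz)`, um (the 110 x 110 x 55 default box
#'   holds ~998 cells at the default density).
#' @param density cell density, cells/um^3 (ignored if `n` is given).
#' @param n number of cells (default `round(density * volume)`).
#' @param phase0 base phase, rad.
#' @param wavelength gradient wavelength, um.
#' @param vortex_center in-plane center of the planted vortex, um
#'   (default: box center).
#' @param vortex_axis rotation axis of the planted vortex: `"z"` (phase
#'   depends on x, y) or `"y"` (on x, z).
#' @param handedness sense of spatial phase increase around the axis.
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y`, `z`, `theta` (and `arrested = 0`
#'   so the table feeds the observables directly).
#' @examples
#' f <- make_planted_field("vortex", seed = 1)
#' nrow(f) # ~998 cells
#' @export
make_planted_field <- function(rule = c("uniform", "gradient", "random", "vortex"),
                               box = c(110, 110, 55), density = 0.0015,
                               n = NULL, phase0 = 3 * pi / 2, wavelength = 55,
                               vortex_center = NULL,
                               vortex_axis = c("z", "y"),
                               handedness = c("ccw", "cw"), seed = 1L) {
  rule <- match.arg(rule)
  vortex_axis <- match.arg(vortex_axis)
  handedness <- match.arg(handedness)
  stopifnot(length(box) == 3, all(box > 0), density > 0)
  if (is.null(n)) n <- round(density * prod(box))
  draws <- .with_seed(seed, stats::runif(4 * n))
  x <- draws[seq_len(n)] * box[1]
  y <- draws[n + seq_len(n)] * box[2]
  z <- draws[2 * n + seq_len(n)] * box[3]
  theta <- switch(rule,
    uniform = rep(phase0, n),
    gradient = (phase0 + 2 * pi * x / wavelength) %% (2 * pi),
    random = draws[3 * n + seq_len(n)] * 2 * pi,
    vortex = {
      s <- if (handedness == "ccw") 1 else -1
      if (vortex_axis == "z") {
        ctr <- if (is.null(vortex_center)) box[1:2] / 2 else vortex_center
        (s * atan2(y - ctr[2], x - ctr[1])) %% (2 * pi)
      } else {
        ctr <- if (is.null(vortex_center)) box[c(1, 3)] / 2 else vortex_center
        (s * atan2(z - ctr[2], x - ctr[1])) %% (2 * pi)
      }
    })
  data.frame(x = x, y = y, z = z, theta = theta, arrested = 0L)
}

# evaluate expr under a temporary seed without disturbing the session RNG
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Generate paired toy segment records
#'
#' Independent Bernoulli defect labels per side per boundary locus: the
#' closed-form oracle for the left-right independence statistics.
#'
#' @param n_segments number of boundary loci.
#' @param p_defect_left,p_defect_right per-side defect probabilities.
#' @param seed integer seed.
#' @return list with elements `left` and `right`, each a `segment_record`.
#' @export
make_toy_record <- function(n_segments, p_defect_left, p_defect_right,
                            seed = 1L) {
  stopifnot(p_defect_left >= 0, p_defect_left <= 1,
            p_defect_right >= 0, p_defect_right <= 1, n_segments >= 1)
  u <- .with_seed(seed, stats::runif(2 * n_segments))
  lab <- function(u, p) ifelse(u < p, "defective", "normal")
  list(left = score_record(lab(u[seq_len(n_segments)], p_defect_left),
                           side = "left"),
       right = score_record(lab(u[n_segments + seq_len(n_segments)],
                                p_defect_right), side = "right"))
}
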