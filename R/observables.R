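# Observables: local phase order, boundary detection and scoring
# (ALD/FRS/PLD), defect statistics, phase vorticity, kymographs.

.unwrap <- function(a) {
  if (length(a) < 2) return(a)
  d <- diff(a)
  d <- (d + pi) %% (2 * pi) - pi
  c(a[1], a[1] + cumsum(d))
}

.circ_stats <- function(theta) {
  n <- length(theta)
  if (n == 0) return(list(R = NA_real_, psi = NA_real_, n = 0L))
  c1 <- sum(cos(theta)) / n
  s1 <- sum(sin(theta)) / n
  list(R = sqrt(c1^2 + s1^2), psi = atan2(s1, c1) %% (2 * pi), n = n)
}

.side_filter <- function(cells, side, geom) {
  act <- if ("arrested" %in% names(cells)) cells$arrested == 0 else TRUE
  sel <- if (side == "left") cells$y < geom$Yc else cells$y >= geom$Yc
  cells[act & sel, , drop = FALSE]
}

#' Phase order of one thin axial slice
#'
#' Modulus `Zm` and argument `Psim` of the mean unit phasor over cells of one
#' side lying in the slab `[x, x + dx_slice)`. An empty slice yields `NA`
#' (flagged missing, excluded from downstream averages).
#'
#' @param cells data.frame with columns `x`, `y`, `theta` (and optionally
#'   `arrested`; arrested cells are excluded).
#' @param x slice start, um.
#' @param side `"left"` or `"right"`.
#' @param geom a [geometry_params()] object (separates the sides at `Yc`).
#' @param dx_slice slice width, um.
#' @return list with `Z`, `psi` and the cell count `n`.
#' @export
slice_order <- function(cells, x, side = c("left", "right"), geom,
                        dx_slice = 11) {
  side <- match.arg(side)
  cc <- .side_filter(cells, side, geom)
  inx <- cc$x >= x & cc$x < x + dx_slice
  st <- .circ_stats(cc$theta[inx])
  list(Z = st$R, psi = st$psi, n = st$n)
}

#' Local phase order parameter
#'
#' Arithmetic mean of the slice moduli of `M` consecutive slices starting at
#' `x`. Slice-first averaging keeps the local order high in the presence of a
#' smooth phase gradient, unlike a single thick slab. Missing (empty) slices
#' are excluded; if all are missing the result is `NA`.
#'
#' @inheritParams slice_order
#' @param M number of consecutive slices.
#' @return local order `Z` in \[0, 1\] (or `NA`).
#' @export
local_order <- function(cells, x, side = c("left", "right"), geom,
                        M = 5, dx_slice = 11) {
  side <- match.arg(side)
  zs <- vapply(seq_len(M) - 1L, function(m)
    slice_order(cells, x + m * dx_slice, side, geom, dx_slice)$Z, numeric(1))
  if (all(is.na(zs))) NA_real_ else mean(zs, na.rm = TRUE)
}

#' Detect boundary-setting times from the anterior mean phase
#'
#' Times at which the temporally unwrapped first-slice mean phase crosses the
#' boundary-setting phase `theta` (mod 2 pi) in the upward direction, linearly
#' interpolated between samples. Crossings closer than `Ta/2` to the previous
#' kept one are merged (the first is kept), suppressing double events from
#' fluctuations.
#'
#' @param times sample times, min.
#' @param psi mean-phase samples, rad (`NA`s are dropped).
#' @param theta boundary-setting phase, rad.
#' @param Ta anterior period, min.
#' @return numeric vector of event times `tau_i`, min.
#' @export
detect_boundary_times <- function(times, psi, theta = 3 * pi / 2, Ta = 30) {
  ok <- !is.na(psi) & !is.na(times)
  times <- times[ok]; psi <- psi[ok]
  if (length(times) < 2) return(numeric(0))
  u <- .unwrap(psi)
  v <- (u - theta) / (2 * pi)
  taus <- numeric(0)
  fl <- floor(v)
  for (i in 2:length(v)) {
    if (v[i] > v[i - 1] && fl[i] > fl[i - 1]) {
      for (m in seq.int(fl[i - 1] + 1L, fl[i])) {
        f <- (m - v[i - 1]) / (v[i] - v[i - 1])
        taus <- c(taus, times[i - 1] + f * (times[i] - times[i - 1]))
      }
    }
  }
  if (length(taus) == 0) return(taus)
  taus <- sort(taus)
  kept <- taus[1]
  for (t in taus[-1]) if (t - kept[length(kept)] >= Ta / 2) kept <- c(kept, t)
  kept
}

#' Classify a detected boundary as normal or defective
#'
#' A boundary set at time `tau` is normal iff the local order at the anterior
#' end satisfies `Z(t, xa) >= Zc` at every sample in the window
#' `[tau - Ta/2, tau - Ta/2 + eta]`; the half-period offset evaluates the
#' integrity of the whole forming segment, and the `eta` window suppresses
#' false detections from momentary fluctuations of `Z`.
#'
#' @param times,Z the `Z(t, xa)` series (min, dimensionless).
#' @param tau boundary-setting time(s), min.
#' @param Ta anterior period, min.
#' @param Zc order threshold.
#' @param eta confirmation window, min.
#' @return character vector: `"normal"`, `"defective"`, or `NA` when the
#'   window is not covered by the series (boundary excluded).
#' @export
classify_boundary <- function(times, Z, tau, Ta = 30, Zc = 0.85, eta = 4) {
  vapply(tau, function(tt) {
    lo <- tt - Ta / 2
    hi <- lo + eta
    if (lo < min(times) || hi > max(times)) return(NA_character_)
    w <- Z[times >= lo & times <= hi]
    w <- w[!is.na(w)]
    if (length(w) == 0) return(NA_character_)
    if (all(w >= Zc)) "normal" else "defective"
  }, character(1))
}

#' Number detected normal boundaries
#'
#' If the immediately preceding detected event was normal and numbered `j`,
#' the current normal boundary is `j + 1`; otherwise its number is inferred
#' from the event time: `round(tau/Ta)` if `round(tau/Ta) - tau/Ta < Delta`,
#' else `round(tau/Ta) - 1`. Defective events are not numbered (`NA`). If an
#' inferred number collides with one already assigned, the earlier event
#' keeps it and a warning is emitted.
#'
#' @param tau event times, min (ascending).
#' @param label classification of each event (`"normal"`/`"defective"`; `NA`
#'   allowed, treated as defective for chaining purposes).
#' @param Ta anterior period, min.
#' @param Delta numbering tolerance.
#' @return integer vector of boundary numbers (`NA` for non-normal events).
#' @export
number_boundary <- function(tau, label, Ta = 30, Delta = 0.3) {
  n <- length(tau)
  idx <- rep(NA_integer_, n)
  used <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(label[i]) || label[i] != "normal") next
    if (i > 1 && !is.na(idx[i - 1])) {
      j <- idx[i - 1] + 1L
    } else {
      rd <- round(tau[i] / Ta)
      j <- if (rd - tau[i] / Ta < Delta) as.integer(rd) else as.integer(rd) - 1L
    }
    if (j %in% used) {
      warning(sprintf("boundary number %d already assigned; keeping the earlier event", j))
      next
    }
    idx[i] <- j
    used <- c(used, j)
  }
  idx
}

#' Score a labeled boundary sequence
#'
#' Builds a per-side segment record and derives the anterior limit of defects
#' (ALD, smallest defective boundary index), the first recovered segment
#' (FRS) and the posterior limit of defects (PLD, largest defective index =
#' `jp - 1` where all boundaries `>= jp` are normal). In the simulation
#' convention FRS is `jf - 1` with `jf` the smallest normal index; in the
#' experimental convention it is the first normal boundary after segment 9,
#' minus 1.
#'
#' @param label character vector of `"normal"`/`"defective"` for boundaries
#'   `1..length(label)`.
#' @param convention `"simulation"` or `"experiment"`.
#' @param tau optional vector of boundary-setting times aligned with `label`.
#' @param side optional side tag stored in the record.
#' @return A `segment_record`: data.frame with columns `index`, `label`
#'   (and `tau` if given) and attributes `ALD`, `FRS`, `PLD`, `convention`,
#'   `side` (missing quantities are `NA`).
#' @examples
#' lab <- rep("normal", 20)
#' lab[c(1:9, 11, 14)] <- "defective"
#' r <- score_record(lab)
#' attr(r, "FRS"); attr(r, "PLD") # 9 and 14
#' @export
score_record <- function(label, convention = c("simulation", "experiment"),
                         tau = NULL, side = NA_character_) {
  convention <- match.arg(convention)
  stopifnot(all(label %in% c("normal", "defective")))
  idx <- seq_along(label)
  def <- idx[label == "defective"]
  nor <- idx[label == "normal"]
  ALD <- if (length(def)) min(def) else NA_integer_
  PLD <- if (length(def)) max(def) else NA_integer_
  FRS <- if (convention == "simulation") {
    if (length(nor)) min(nor) - 1L else NA_integer_
  } else {
    nf <- nor[nor > 9]
    if (length(nf)) min(nf) - 1L else NA_integer_
  }
  rec <- data.frame(index = idx, label = label, stringsAsFactors = FALSE)
  if (!is.null(tau)) rec$tau <- tau
  attr(rec, "ALD") <- ALD
  attr(rec, "FRS") <- FRS
  attr(rec, "PLD") <- PLD
  attr(rec, "convention") <- convention
  attr(rec, "side") <- side
  class(rec) <- c("segment_record", "data.frame")
  rec
}

#' Extract the segment record of one side of a run
#'
#' Full pipeline from the recorded anterior series: detect boundary-setting
#' times from the first-slice mean phase, classify each with the
#' `Z(t, xa) >= Zc` window rule, number the normal boundaries, and label all
#' remaining boundary indices in `1..n_boundaries` defective.
#'
#' @param run a `psm_run`.
#' @param side `"left"` or `"right"`.
#' @param convention FRS convention, see [score_record()].
#' @param n_boundaries number of scoreable boundaries; defaults to
#'   `floor(duration/Ta) - 1` so the classification window of the last one is
#'   covered.
#' @return A `segment_record`.
#' @export
segment_record <- function(run, side = c("left", "right"),
                           convention = c("simulation", "experiment"),
                           n_boundaries = NULL) {
  side <- match.arg(side)
  convention <- match.arg(convention)
  cfg <- run$config
  det <- cfg$detection
  Ta <- cfg$phase$Ta
  s <- run$series
  psi <- if (side == "left") s$psi1_left else s$psi1_right
  Z <- if (side == "left") s$Z_left else s$Z_right
  if (is.null(n_boundaries))
    n_boundaries <- max(1L, as.integer(floor(cfg$duration / Ta)) - 1L)
  tau <- detect_boundary_times(s$time, psi, theta = cfg$phase$theta_set, Ta = Ta)
  lab <- classify_boundary(s$time, Z, tau, Ta = Ta, Zc = det$Zc, eta = det$eta)
  keep <- !is.na(lab)
  num <- number_boundary(tau[keep], lab[keep], Ta = Ta, Delta = det$Delta)
  label <- rep("defective", n_boundaries)
  tau_full <- rep(NA_real_, n_boundaries)
  ok <- !is.na(num) & num >= 1L & num <= n_boundaries
  label[num[ok]] <- "normal"
  tau_full[num[ok]] <- tau[keep][ok]
  score_record(label, convention = convention, tau = tau_full, side = side)
}

#' Lengths of consecutive defect runs between FRS and PLD
#'
#' @param record a `segment_record` (or a label vector accepted by
#'   [score_record()]).
#' @return integer vector of maximal consecutive-defective run lengths with
#'   indices strictly inside `(FRS, PLD]`; empty if FRS or PLD is undefined
#'   or there are no defects in between.
#' @export
defect_runs <- function(record) {
  if (!inherits(record, "segment_record")) record <- score_record(record)
  FRS <- attr(record, "FRS"); PLD <- attr(record, "PLD")
  if (is.na(FRS) || is.na(PLD) || PLD <= FRS) return(integer(0))
  lab <- record$label[record$index > FRS & record$index <= PLD]
  r <- rle(lab == "defective")
  as.integer(r$lengths[r$values])
}

#' Left-right single and double defect statistics
#'
#' Over boundary loci shared by both sides and posterior to `start_after`,
#' counts loci with at least one defective side (`Nt`), with exactly one
#' (`Ns`), and the single fraction `Fs = Ns/Nt`.
#'
#' @param left,right `segment_record`s (or label vectors).
#' @param start_after only loci with index strictly greater than this value
#'   are counted (9 marks the onset of resynchronization).
#' @return list with `Ns`, `Nt`, `Fs` (`Fs` is `NA` when `Nt = 0`).
#' @export
single_double_stats <- function(left, right, start_after = 9) {
  if (!inherits(left, "segment_record")) left <- score_record(left)
  if (!inherits(right, "segment_record")) right <- score_record(right)
  J <- min(nrow(left), nrow(right))
  idx <- seq_len(J)
  idx <- idx[idx > start_after]
  dl <- left$label[idx] == "defective"
  dr <- right$label[idx] == "defective"
  Nt <- sum(dl | dr)
  Ns <- sum(xor(dl, dr))
  list(Ns = Ns, Nt = Nt, Fs = if (Nt > 0) Ns / Nt else NA_real_)
}

#' Expected single-defect fraction under left-right independence
#'
#' If each side is defective independently with probability `p` at a locus,
#' the fraction of defective loci that are single-sided is
#' `Fs = 2 p (1 - p) / (2 p (1 - p) + p^2) = 2 (1 - p) / (2 - p)`, defined by
#' its limit 1 as `p -> 0`.
#'
#' @param p per-side defect probability in \[0, 1\].
#' @return expected `Fs`.
#' @export
expected_single_fraction <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p == 0, 1, 2 * (1 - p) / (2 - p))
}

# ---------------------------------------------------------------------------
# Phase vorticity
# ---------------------------------------------------------------------------

.sector_means <- function(px, pw, theta, x0, w0, params) {
  dx <- px - x0
  dw <- pw - w0
  d2 <- dx * dx + dw * dw
  lo <- params$delta_l
  hi <- params$delta_l + params$l
  ring <- d2 >= lo * lo & d2 < hi * hi
  if (!any(ring)) return(NULL)
  ang <- atan2(dw[ring], dx[ring]) %% (2 * pi)
  sec <- pmin(5L, as.integer(floor(ang / (pi / 3))))
  th <- theta[ring]
  means <- rep(NA_real_, 6)
  for (i in 0:5) {
    sel <- sec == i
    if (!any(sel)) return(NULL) # an empty sector vetoes the grid point
    means[i + 1] <- atan2(sum(sin(th[sel])), sum(cos(th[sel]))) %% (2 * pi)
  }
  means
}

.sector_index_corr <- function(th_hat) {
  i <- 0:5
  mi <- 5 / 2
  vi <- 35 / 12 # sum((i - 5/2)^2)/6, the printed normalization
  mth <- mean(th_hat)
  sth <- sqrt(sum((th_hat - mth)^2) / 6)
  if (sth == 0) return(0)
  sum((i - mi) * (th_hat - mth)) / 6 / (sqrt(vi) * sth)
}

#' Phase vorticity at one grid point
#'
#' Builds a six-sector ring around the grid point, takes the circular mean
#' phase per sector, cyclically permutes the means so the smallest comes
#' first (ascending sector order for one handedness, descending for the
#' other), and accepts a vortex when the permuted means increase linearly
#' with sector index: Pearson correlation above `alpha` *and* total winding
#' `(theta_hat_5 - theta_hat_0)/2 pi` at least `psi_min`. Any empty sector
#' vetoes the point. The returned vorticity is the winding fraction, in
#' \[0, 1).
#'
#' @param px,pw projected cell coordinates in the plane, um.
#' @param theta cell phases, rad.
#' @param x0,w0 grid-point coordinates, um.
#' @param params a [vorticity_params()] object.
#' @param handedness `"ccw"` (sector means ascend counterclockwise) or
#'   `"cw"`.
#' @return vorticity `psi` in \[0, 1).
#' @export
vorticity_at_grid <- function(px, pw, theta, x0, w0, params = vorticity_params(),
                              handedness = c("ccw", "cw")) {
  handedness <- match.arg(handedness)
  means <- .sector_means(px, pw, theta, x0, w0, params)
  if (is.null(means)) return(0)
  k <- which.min(means) - 1L
  ord <- if (handedness == "ccw") (k + 0:5) %% 6 else (k - 0:5) %% 6
  th_hat <- means[ord + 1L]
  rc <- .sector_index_corr(th_hat)
  winding <- (th_hat[6] - th_hat[1]) / (2 * pi)
  if (rc > params$alpha && winding >= params$psi_min) winding else 0
}

.vorticity_plane <- function(px, pw, theta, x_grid, w_grid, params) {
  ncw <- length(x_grid)
  out_cw <- numeric(ncw)
  out_ccw <- numeric(ncw)
  reach <- params$delta_l + params$l
  for (si in seq_along(x_grid)) {
    xs <- x_grid[si]
    near <- abs(px - xs) < reach
    if (!any(near)) next
    pxn <- px[near]; pwn <- pw[near]; thn <- theta[near]
    best_cw <- 0; best_ccw <- 0
    for (wu in w_grid) {
      means <- .sector_means(pxn, pwn, thn, xs, wu, params)
      if (is.null(means)) next
      k <- which.min(means) - 1L
      for (hand in c("ccw", "cw")) {
        ord <- if (hand == "ccw") (k + 0:5) %% 6 else (k - 0:5) %% 6
        th_hat <- means[ord + 1L]
        rc <- .sector_index_corr(th_hat)
        winding <- (th_hat[6] - th_hat[1]) / (2 * pi)
        if (rc > params$alpha && winding >= params$psi_min) {
          if (hand == "ccw") best_ccw <- max(best_ccw, winding)
          else best_cw <- max(best_cw, winding)
        }
      }
    }
    out_cw[si] <- best_cw
    out_ccw[si] <- best_ccw
  }
  list(cw = out_cw, ccw = out_ccw)
}

#' Axial vorticity profile of one PSM side
#'
#' Projects the cells of one side onto four thin slices (two z-slices for
#' vortices rotating about the z-axis, two y-slices for vortices about the
#' y-axis), computes the vorticity on a regular grid in each projection
#' plane, takes the maximum over the transverse grid per axial position and
#' then the maximum across the four planes, separately for each handedness.
#'
#' @param cells cell table with `x`, `y`, `z`, `theta` (arrested cells are
#'   excluded if an `arrested` column is present).
#' @param geom a [geometry_params()] object.
#' @param side `"left"` or `"right"`.
#' @param params a [vorticity_params()] object.
#' @param xa anterior-end position, um.
#' @param r current tube radius, um.
#' @return data.frame with columns `x` (grid positions) and `psi_cw`,
#'   `psi_ccw`.
#' @export
vorticity_profile <- function(cells, geom, side = c("left", "right"),
                              params = vorticity_params(), xa = 0,
                              r = geom$r0) {
  side <- match.arg(side)
  cc <- .side_filter(cells, side, geom)
  y0 <- if (side == "left") 0 else 2 * geom$R
  th <- params$slab_thickness
  x_grid <- seq(xa, geom$Lx, by = params$dx)
  w_grid_y <- seq(y0, y0 + 2 * r, by = params$dw)
  w_grid_z <- seq(0, 2 * r, by = params$dw)
  planes <- list(
    list(sel = cc$z <= th,            pw = "y", wg = w_grid_y),
    list(sel = cc$z >= 2 * r - th,    pw = "y", wg = w_grid_y),
    list(sel = cc$y - y0 <= th,       pw = "z", wg = w_grid_z),
    list(sel = cc$y - y0 >= 2 * r - th, pw = "z", wg = w_grid_z))
  cw <- ccw <- numeric(length(x_grid))
  for (pl in planes) {
    sub <- cc[pl$sel, , drop = FALSE]
    if (nrow(sub) == 0) next
    res <- .vorticity_plane(sub$x, sub[[pl$pw]], sub$theta, x_grid, pl$wg, params)
    cw <- pmax(cw, res$cw)
    ccw <- pmax(ccw, res$ccw)
  }
  data.frame(x = x_grid, psi_cw = cw, psi_ccw = ccw)
}

#' Vorticity profile of a cuboid test field
#'
#' Same detector as [vorticity_profile()] applied to a rectangular box (used
#' with the planted fields of [make_planted_field()]): two z-slices and two
#' y-slices of the configured thickness at the box faces.
#'
#' @param cells cell table with `x`, `y`, `z`, `theta`.
#' @param box box extents `c(Lx, Ly, Lz)`, um.
#' @param params a [vorticity_params()] object.
#' @return data.frame with columns `x`, `psi_cw`, `psi_ccw`.
#' @export
vorticity_profile_box <- function(cells, box, params = vorticity_params()) {
  th <- params$slab_thickness
  x_grid <- seq(0, box[1], by = params$dx)
  w_grid_y <- seq(0, box[2], by = params$dw)
  w_grid_z <- seq(0, box[3], by = params$dw)
  planes <- list(
    list(sel = cells$z <= th,          pw = "y", wg = w_grid_y),
    list(sel = cells$z >= box[3] - th, pw = "y", wg = w_grid_y),
    list(sel = cells$y <= th,          pw = "z", wg = w_grid_z),
    list(sel = cells$y >= box[2] - th, pw = "z", wg = w_grid_z))
  cw <- ccw <- numeric(length(x_grid))
  for (pl in planes) {
    sub <- cells[pl$sel, , drop = FALSE]
    if (nrow(sub) == 0) next
    res <- .vorticity_plane(sub$x, sub[[pl$pw]], sub$theta, x_grid, pl$wg, params)
    cw <- pmax(cw, res$cw)
    ccw <- pmax(ccw, res$ccw)
  }
  data.frame(x = x_grid, psi_cw = cw, psi_ccw = ccw)
}

# ---------------------------------------------------------------------------
# Kymographs and derived run measurements
# ---------------------------------------------------------------------------

#' Kymograph of local order or vorticity
#'
#' For `what = "Z"`, uses the axial slice-order profiles recorded during the
#' run; for `what = "psi"`, computes the vorticity profile on every stored
#' snapshot (requires `keep_snapshots = TRUE`). Axial positions are reported
#' tissue-relative (`x - xa`); the anterior-end trajectory is included so
#' absolute positions can be reconstructed.
#'
#' @param run a `psm_run`.
#' @param what `"Z"` or `"psi"`.
#' @param side `"left"` or `"right"`.
#' @param handedness for `what = "psi"`: `"cw"` or `"ccw"`.
#' @return A `psm_kymograph`: list with `time`, `x_offset`, `values`
#'   (time x position matrix), `xa`, `side`, `what`.
#' @export
kymograph <- function(run, what = c("Z", "psi"), side = c("left", "right"),
                      handedness = c("ccw", "cw")) {
  what <- match.arg(what)
  side <- match.arg(side)
  handedness <- match.arg(handedness)
  cfg <- run$config
  if (what == "Z") {
    v <- if (side == "left") run$profile$Z_left else run$profile$Z_right
    tt <- run$profile$times
    xo <- run$profile$x_offset
  } else {
    if (length(run$snapshots) == 0)
      stop("vorticity kymographs need a run with keep_snapshots = TRUE", call. = FALSE)
    tt <- run$snapshot_times
    xas <- approx(run$series$time, run$series$xa, xout = tt, rule = 2)$y
    profs <- lapply(seq_along(tt), function(i)
      vorticity_profile(run$snapshots[[i]], cfg$geometry, side,
                        cfg$vorticity, xa = xas[i], r = run$r_final))
    xo <- profs[[1]]$x - xas[1]
    v <- t(vapply(profs, function(p)
      if (handedness == "cw") p$psi_cw else p$psi_ccw,
      numeric(length(xo))))
  }
  xa <- approx(run$series$time, run$series$xa, xout = tt, rule = 2)$y
  out <- list(time = tt, x_offset = xo, values = v, xa = xa,
              side = side, what = what)
  class(out) <- "psm_kymograph"
  out
}

#' @export
plot.psm_kymograph <- function(x, ...) {
  graphics::image(x$time, x$x_offset, x$values,
                  xlab = "time (min)", ylab = "x - xa (um)",
                  main = sprintf("%s kymograph (%s)", x$what, x$side), ...)
  invisible(x)
}

#' Oscillation period at the posterior tip
#'
#' Mean interval between successive upward crossings of the recorded
#' posterior circular mean phase through `theta`.
#'
#' @param run a `psm_run`.
#' @param theta reference phase, rad.
#' @param discard_minutes initial transient to discard, min.
#' @return mean period, min (`NA` if fewer than two crossings remain).
#' @export
posterior_period <- function(run, theta = 3 * pi / 2, discard_minutes = 10) {
  s <- run$series
  Ta <- run$config$phase$Ta
  tau <- detect_boundary_times(s$time, s$posterior_phase, theta = theta, Ta = Ta)
  tau <- tau[tau > discard_minutes]
  if (length(tau) < 2) return(NA_real_)
  mean(diff(tau))
}

#' Score arrested stripes by local phase coherence
#'
#' Desynchronization experiments are scored on the formed pattern: a segment
#' boundary is counted as normal while its stripe is still recognizable in
#' the arrested phase field. This scorer finds stripe positions as upward
#' crossings of the stripe phase in the binned, unwrapped arrested pattern
#' and attaches to each a coherence value: the circular resultant length of
#' the detrended phases `theta_i - 2 pi (x_i - x_c)/S` over arrested cells
#' within half a segment length `S/2` of the crossing. A perfect stripe
#' pattern gives coherence 1, a fully randomized one ~0; a stripe is deemed
#' recognizable when its coherence is at least `R_min` (default 0.5, the
#' half-coherent midpoint). The anterior limit of defects of the pattern is
#' one past the leading run of recognizable stripes.
#'
#' @param run a `psm_run` whose `final` state retains the arrested cells
#'   (use `arrested_window >= duration` to keep them all).
#' @param side `"left"`, `"right"`, or `"both"`; left and right patterns
#'   drift apart under phase noise, so desynchronization runs are scored per
#'   side, like embryos.
#' @param R_min coherence threshold for a recognizable stripe.
#' @param theta stripe phase, rad.
#' @param S segment length, um; defaults to advection speed x anterior
#'   period.
#' @param bin axial bin width for the crossing search, um (choose so a bin
#'   holds a handful of cells at the run density).
#' @param min_per_bin bins with fewer cells are skipped in the search.
#' @return data.frame with one row per stripe (anterior to posterior):
#'   `stripe`, `x`, `coherence`, `recognizable`; attributes `n_leading`
#'   (length of the leading recognizable run) and `ALD` (`n_leading + 1`).
#' @export
stripe_coherence_record <- function(run, side = c("both", "left", "right"),
                                    R_min = 0.5, theta = 3 * pi / 2,
                                    S = NULL, bin = 5, min_per_bin = 2) {
  side <- match.arg(side)
  cfg <- run$config
  if (is.null(S)) S <- cfg$mechanics$va * cfg$phase$Ta
  arr <- run$final[run$final$arrested == 1, , drop = FALSE]
  if (side != "both") {
    sel <- if (side == "left") arr$y < cfg$geometry$Yc else arr$y >= cfg$geometry$Yc
    arr <- arr[sel, , drop = FALSE]
  }
  if (nrow(arr) < 20)
    stop("too few arrested cells to score stripes", call. = FALSE)
  # stripe positions: crossings of the binned, unwrapped mean phase
  br <- seq(floor(min(arr$x)), ceiling(max(arr$x)) + bin, by = bin)
  gi <- findInterval(arr$x, br)
  xs <- c(); ph <- c()
  for (g in sort(unique(gi))) {
    sel <- gi == g
    if (sum(sel) < min_per_bin) next
    xs <- c(xs, mean(arr$x[sel]))
    ph <- c(ph, atan2(sum(sin(arr$theta[sel])), sum(cos(arr$theta[sel]))) %% (2 * pi))
  }
  o <- order(xs)
  xs <- xs[o]; u <- .unwrap(ph[o])
  v <- (u - theta) / (2 * pi)
  fl <- floor(v)
  cross <- numeric(0)
  for (i in 2:length(v)) {
    if (v[i] > v[i - 1] && fl[i] > fl[i - 1]) {
      for (m in seq.int(fl[i - 1] + 1L, fl[i])) {
        f <- (m - v[i - 1]) / (v[i] - v[i - 1])
        cross <- c(cross, xs[i - 1] + f * (xs[i] - xs[i - 1]))
      }
    }
  }
  cross <- sort(cross)
  # keep crossings with a full coherence window inside the pattern
  cross <- cross[cross - S / 2 >= min(arr$x) & cross + S / 2 <= max(arr$x)]
  if (length(cross) == 0)
    stop("no stripe crossings found in the arrested pattern", call. = FALSE)
  # local wavelength from neighbouring crossings (the early pattern forms
  # while the wave transient still runs, with a longer wavelength; stripe
  # sharpness is scored against the local spacing, not the asymptotic S)
  nS <- length(cross)
  S_loc <- vapply(seq_len(nS), function(k) {
    lo <- if (k > 1) cross[k] - cross[k - 1] else NA_real_
    hi <- if (k < nS) cross[k + 1] - cross[k] else NA_real_
    s <- mean(c(lo, hi), na.rm = TRUE)
    if (is.finite(s) && s > S / 2 && s < 2 * S) s else S
  }, numeric(1))
  coh <- vapply(seq_len(nS), function(k) {
    xc <- cross[k]
    sel <- abs(arr$x - xc) <= S_loc[k] / 2
    res <- arr$theta[sel] - 2 * pi * (arr$x[sel] - xc) / S_loc[k]
    sqrt(sum(cos(res))^2 + sum(sin(res))^2) / sum(sel)
  }, numeric(1))
  rec <- data.frame(stripe = seq_len(nS), x = cross, coherence = coh,
                    recognizable = coh >= R_min)
  # a leading stripe run also ends where a stripe failed to appear at all
  # (spacing far beyond the local wavelength)
  gap_ok <- c(TRUE, diff(cross) <= 1.6 * pmax(S_loc[-nS], S))
  good <- rec$recognizable & cumprod(gap_ok) == 1
  n_lead <- if (all(good)) nS else which(!good)[1] - 1L
  attr(rec, "n_leading") <- as.integer(n_lead)
  attr(rec, "ALD") <- as.integer(n_lead) + 1L
  rec
}

#' Wavelength of the arrested stripe pattern
#'
#' Bins the arrested (segmented) cells axially, takes the circular mean
#' phase per bin, unwraps it along x and measures the mean spacing between
#' successive upward crossings of `theta`. Under synchronized dynamics this
#' spacing is the segment length (advection speed x anterior period).
#'
#' @param run a `psm_run` (its `final` state must retain arrested cells).
#' @param theta stripe phase, rad.
#' @param bin axial bin width, um.
#' @param min_cells_per_bin bins with fewer cells are dropped.
#' @return list with `wavelength` (mean spacing, um), `crossings` (stripe
#'   positions, um) and `n_stripes`.
#' @export
stripe_wavelength <- function(run, theta = 3 * pi / 2, bin = 2,
                              min_cells_per_bin = 3) {
  arr <- run$final[run$final$arrested == 1, , drop = FALSE]
  if (nrow(arr) < 20)
    stop("too few arrested cells to measure a stripe pattern", call. = FALSE)
  br <- seq(floor(min(arr$x)), ceiling(max(arr$x)) + bin, by = bin)
  gi <- findInterval(arr$x, br)
  xs <- c(); ph <- c()
  for (g in sort(unique(gi))) {
    sel <- gi == g
    if (sum(sel) < min_cells_per_bin) next
    st <- .circ_stats(arr$theta[sel])
    xs <- c(xs, mean(arr$x[sel]))
    ph <- c(ph, st$psi)
  }
  if (length(xs) < 4) stop("too few populated bins", call. = FALSE)
  o <- order(xs)
  xs <- xs[o]; ph <- .unwrap(ph[o])
  v <- (ph - theta) / (2 * pi)
  cross <- numeric(0)
  fl <- floor(v)
  for (i in 2:length(v)) {
    if (v[i] > v[i - 1] && fl[i] > fl[i - 1]) {
      for (m in seq.int(fl[i - 1] + 1L, fl[i])) {
        f <- (m - v[i - 1]) / (v[i] - v[i - 1])
        cross <- c(cross, xs[i - 1] + f * (xs[i] - xs[i - 1]))
      }
    }
  }
  if (length(cross) < 2)
    stop("fewer than two stripe crossings found", call. = FALSE)
  list(wavelength = mean(diff(sort(cross))), crossings = sort(cross),
       n_stripes = length(cross))
}
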