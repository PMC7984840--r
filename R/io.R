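# Configuration files, result serialization, run manifests and the
# command-line entry points. Configs are YAML with one block per parameter
# group; tabular outputs are CSV with units embedded in the column names
# (lengths um, times min, angles rad).

.block_builders <- function() {
  list(geometry = geometry_params, mechanics = mechanics_params,
       phase = phase_params, program = program_params,
       detection = detection_params, vorticity = vorticity_params)
}

.top_level_keys <- c("preset", "dt", "duration", "seed", "init_phase",
                     "relax_minutes", "obs_dt", "profile_dt", "snapshot_dt",
                     "keep_snapshots", "arrested_window", "posterior_window")

#' Load a run configuration from a YAML file
#'
#' The file may name a `preset` and override any parameter inside the blocks
#' `geometry`, `mechanics`, `phase`, `program`, `detection`, `vorticity`, or
#' the top-level run controls (`dt`, `duration`, `seed`, `init_phase`, ...).
#' Unknown keys are rejected with an error naming the key; values are
#' validated by the corresponding `*_params()` constructor. An empty file
#' yields the full-default `fig3_constant` preset.
#'
#' @param path path to the YAML file.
#' @return A `psm_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping", call. = FALSE)
  builders <- .block_builders()
  known <- c(names(builders), .top_level_keys)
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  preset <- if (!is.null(raw$preset)) raw$preset else "fig3_constant"
  args <- list()
  for (blk in names(builders)) {
    if (is.null(raw[[blk]])) next
    builder <- builders[[blk]]
    ok <- names(formals(builder))
    bad <- setdiff(names(raw[[blk]]), ok)
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s' block: %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
    args[[blk]] <- do.call(builder, raw[[blk]])
  }
  for (key in setdiff(.top_level_keys, "preset"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  do.call(preset_config, c(list(name = preset), args))
}

#' Reproducible hash of a configuration
#'
#' FNV-1a over the canonical deparsed parameter list; used in manifests to
#' verify config round trips.
#'
#' @param config a `psm_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      x[order(names(x))]
    } else x
  }
  s <- paste(deparse(canon(unclass(config)), control = "all"), collapse = "")
  bytes <- utf8ToInt(s)
  # FNV-1a in exact 32-bit arithmetic (doubles, 16-bit split multiplication)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- bitwXor(lo, b) + hi * 65536
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Write run outputs to a directory
#'
#' Emits `series.csv` (boundary and tissue time series), `events.csv`,
#' `final_state.csv`, per-side `record_<side>.csv` segment records, optional
#' snapshot CSVs, and `manifest.json` listing every file together with the
#' seed and config hash and echoing the configuration.
#'
#' @param run a `psm_run`.
#' @param dir output directory (created if needed).
#' @param snapshots also write one CSV per stored snapshot?
#' @return invisibly, the manifest as a list.
#' @export
write_run <- function(run, dir, snapshots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  wr(run$series, "series.csv")
  wr(run$events, "events.csv")
  wr(run$final, "final_state.csv")
  for (side in c("left", "right")) {
    rec <- segment_record(run, side)
    df <- as.data.frame(rec)
    df$side <- side
    wr(df, sprintf("record_%s.csv", side))
  }
  if (snapshots && length(run$snapshots)) {
    for (i in seq_along(run$snapshots)) {
      df <- run$snapshots[[i]]
      df$time_min <- run$snapshot_times[i]
      wr(df, sprintf("snapshot_%04d.csv", i))
    }
  }
  manifest <- list(
    package = "psmclock",
    version = as.character(utils::packageVersion("psmclock")),
    seed = run$seed,
    status = run$status,
    config_hash = config_hash(run$config),
    config = .config_to_plain(run$config),
    files = files,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.config_to_plain <- function(config) {
  out <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  out
}

# ---------------------------------------------------------------------------
# Command-line interface: psmclock run|observe|score
# ---------------------------------------------------------------------------

#' Command-line entry point
#'
#' Dispatches the subcommands used by the `exec/psmclock` script:
#' * `run --config <yaml> [--preset name] [--seed s] [--out dir]` - run a
#'   simulation and write its outputs;
#' * `observe --state <csv> [--xa x] [--out dir]` - compute order and
#'   vorticity profiles from a cell-state CSV;
#' * `score --left <csv> --right <csv> [--out dir]` - score a pair of segment
#'   records (ALD/FRS/PLD, defect runs, single-defect fraction);
#' * `sweep --configs <dir> [--seeds s1,s2,...] [--out dir]` - run every YAML
#'   config in a directory for each seed (e.g. a washout-time sweep), one
#'   run per config x seed, each written to its own subdirectory.
#'
#' @param args character vector of command-line arguments.
#' @return exit code, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: psmclock <run|observe|score|sweep> [options]"
  if (length(args) == 0) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  code <- tryCatch({
    switch(cmd,
           run = .cli_run(rest),
           observe = .cli_observe(rest),
           score = .cli_score(rest),
           sweep = .cli_sweep(rest),
           { message(usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

.parse_opts <- function(args, spec) {
  # spec: named list default values; NA means required
  vals <- spec
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(spec)) stop("unknown option --", key)
    if (i + 1 > length(args)) stop("missing value for --", key)
    vals[[key]] <- args[i + 1]
    i <- i + 2
  }
  req <- names(vals)[vapply(vals, function(v) length(v) == 1 && is.na(v), logical(1))]
  if (length(req)) stop("missing required option(s): ",
                        paste0("--", req, collapse = ", "))
  vals
}

.cli_run <- function(args) {
  o <- .parse_opts(args, list(config = "", preset = "", seed = "", out = "psmclock_run"))
  cfg <- if (nzchar(o$config)) load_config(o$config)
         else if (nzchar(o$preset)) preset_config(o$preset)
         else preset_config("fig3_constant")
  seed <- if (nzchar(o$seed)) as.integer(o$seed) else cfg$seed
  run <- run_simulation(cfg, seed = seed)
  write_run(run, o$out)
  message("run complete (", run$status, "); outputs in ", o$out)
  0L
}

.cli_observe <- function(args) {
  o <- .parse_opts(args, list(state = NA, xa = "0", out = "psmclock_obs",
                              r0 = "25", R = "50", L = "325"))
  cells <- read.csv(o$state)
  geom <- geometry_params(r0 = as.numeric(o$r0), R = as.numeric(o$R),
                          L = as.numeric(o$L))
  xa <- as.numeric(o$xa)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  for (side in c("left", "right")) {
    xs <- seq(xa, geom$Lx - 5 * 11, by = 11)
    zp <- vapply(xs, function(x0) local_order(cells, x0, side, geom), numeric(1))
    write.csv(data.frame(x_um = xs, Z = zp),
              file.path(o$out, sprintf("order_%s.csv", side)), row.names = FALSE)
    vp <- vorticity_profile(cells, geom, side, xa = xa)
    names(vp) <- c("x_um", "psi_cw", "psi_ccw")
    write.csv(vp, file.path(o$out, sprintf("vorticity_%s.csv", side)),
              row.names = FALSE)
  }
  message("observables written to ", o$out)
  0L
}

.cli_sweep <- function(args) {
  o <- .parse_opts(args, list(configs = NA, seeds = "1", out = "psmclock_sweep"))
  files <- list.files(o$configs, pattern = "\\.ya?ml$", full.names = TRUE)
  if (length(files) == 0) stop("no YAML configs found in ", o$configs)
  seeds <- as.integer(strsplit(o$seeds, ",")[[1]])
  for (f in files) {
    cfg <- load_config(f)
    for (s in seeds) {
      tag <- sprintf("%s_seed%d", tools::file_path_sans_ext(basename(f)), s)
      run <- run_simulation(cfg, seed = s)
      write_run(run, file.path(o$out, tag))
      message("completed ", tag)
    }
  }
  0L
}

.cli_score <- function(args) {
  o <- .parse_opts(args, list(left = NA, right = NA, out = "psmclock_score"))
  rd <- function(p) {
    df <- read.csv(p)
    score_record(df$label, tau = if ("tau" %in% names(df)) df$tau else NULL)
  }
  left <- rd(o$left)
  right <- rd(o$right)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  stats <- single_double_stats(left, right)
  summ <- data.frame(
    side = c("left", "right"),
    ALD = c(attr(left, "ALD"), attr(right, "ALD")),
    FRS = c(attr(left, "FRS"), attr(right, "FRS")),
    PLD = c(attr(left, "PLD"), attr(right, "PLD")))
  write.csv(summ, file.path(o$out, "summary.csv"), row.names = FALSE)
  runs <- data.frame(
    side = c(rep("left", length(defect_runs(left))),
             rep("right", length(defect_runs(right)))),
    run_length = c(defect_runs(left), defect_runs(right)))
  write.csv(runs, file.path(o$out, "defect_runs.csv"), row.names = FALSE)
  jsonlite::write_json(stats, file.path(o$out, "lr_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  message("scores written to ", o$out)
  0L
}
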