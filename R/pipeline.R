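# End-to-end orchestration: configuration, resumable surface runs, and
# report generation.  Everything is driven by a plain-list (JSON-
# serialisable) run configuration that is echoed into every output for
# provenance.

#' Run configuration for the pipeline
#'
#' @param input path to a trajectory CSV (`frame,id,x_mm,y_mm`), or
#'   `NULL` to use `generator`.
#' @param generator list describing a synthetic input:
#'   `list(type = "boids_school" | "leader_follower_chain" |
#'   "independent_walkers", ...)` with [generator_config()] arguments.
#' @param setting `"local"` or `"global"`.
#' @param grid named list of threshold vectors (default
#'   [default_grid()]).
#' @param timescales integer vector of frame strides.
#' @param scope `"main_complex"` or `"full_system"`.
#' @param cut_scheme `"cut_one"` or `"exhaustive"`.
#' @param flags encoder convention flags (`vf_half_angle`,
#'   `view_toward_neighbour`, `smooth_first`).
#' @param seed integer seed for generators.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, generator = NULL, setting = "local",
                       grid = NULL, timescales = 20, scope = "main_complex",
                       cut_scheme = "cut_one", flags = list(), seed = 1,
                       out_dir = ".") {
  if (is.null(input) && is.null(generator)) {
    stop("run_config needs either an input CSV or a generator spec")
  }
  structure(list(input = input, generator = generator, setting = setting,
                 grid = grid, timescales = as.integer(timescales),
                 scope = scope, cut_scheme = cut_scheme, flags = flags,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file written by [write_run_config()].
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$grid <- as.list(obj$grid)
  do.call(run_config, obj[intersect(names(obj), names(formals(run_config)))])
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(config),
                                           auto_unbox = TRUE, digits = NA)),
             tmp)
  unname(tools::md5sum(tmp))
}

load_input <- function(config) {
  if (!is.null(config$input)) {
    return(read_trajectory_csv(config$input))
  }
  gen <- config$generator
  type <- gen$type %||% "boids_school"
  args <- gen[setdiff(names(gen), "type")]
  if (!("seed" %in% names(args))) args$seed <- config$seed
  cfg <- do.call(generator_config, args)
  switch(type,
         boids_school = boids_school(cfg),
         leader_follower_chain = leader_follower_chain(cfg),
         independent_walkers = independent_walkers(cfg),
         stop("unknown generator type: ", type))
}

#' Run a Phi surface over a threshold grid, resumably
#'
#' Executes encode -> TPM -> per-state Phi for every grid cell and
#' timescale of the configuration, appending one CSV row per cell to
#' `surface_<setting>_dt<k>.csv` in the output directory.  Cells already
#' present in the output are skipped, so an interrupted run can be
#' resumed by re-invoking with the same configuration.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-cell progress on stderr.
#' @return (invisibly) a list of `phi_surface` data.frames, one per
#'   timescale, as read back from the output files.
#' @export
run_surface <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- load_input(config)
  grid <- config$grid %||% default_grid(config$setting)
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  axes <- names(grid)
  hash <- config_hash(config)
  write_run_config(config, file.path(config$out_dir, "run_config.json"))
  out <- list()
  for (dt in config$timescales) {
    path <- file.path(config$out_dir,
                      sprintf("surface_%s_dt%d.csv", config$setting, dt))
    done <- if (file.exists(path)) read.csv(path) else NULL
    cell_key <- function(row) paste(signif(unlist(row[axes]), 12),
                                    collapse = "|")
    done_keys <- if (is.null(done)) character(0) else {
      vapply(seq_len(nrow(done)), function(i) cell_key(done[i, ]),
             character(1))
    }
    for (i in seq_len(nrow(cells))) {
      key <- cell_key(cells[i, , drop = FALSE])
      if (key %in% done_keys) next
      t0 <- Sys.time()
      thr <- if (config$setting == "local") {
        local_thresholds(cells$xi_D[i], cells$xi_VF[i], cells$xi_TR[i])
      } else {
        global_thresholds(Xi_AD = cells$Xi_AD[i], Xi_CM = cells$Xi_CM[i])
      }
      enc_args <- c(list(traj, thr, dt), config$flags)
      seq_i <- if (config$setting == "local") {
        do.call(local_collective_state, enc_args)
      } else {
        do.call(global_collective_state, enc_args)
      }
      tab <- phi_per_state(estimate_tpm(seq_i), scope = config$scope,
                           cut_scheme = config$cut_scheme)
      row <- cbind(cells[i, , drop = FALSE],
                   mean_phi = mean_phi(tab), var_phi = variance_phi(tab),
                   dt_frames = dt, n = n_individuals(traj),
                   setting = config$setting, scope = config$scope,
                   config = hash)
      write.table(row, path, sep = ",", row.names = FALSE,
                  col.names = !file.exists(path), append = file.exists(path))
      if (!quiet) {
        message(sprintf("cell %d/%d (dt=%d) in %.2fs", i, nrow(cells), dt,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      }
    }
    out[[as.character(dt)]] <- read.csv(path)
  }
  invisible(out)
}

#' Run a leadership / classification report
#'
#' Produces the descriptive quantities that support behavioural
#' classification: match rates, cohesion, per-ON-count mean Phi, and
#' state occupancy, serialised as JSON.  No behavioural labels are
#' attached unless `classify = TRUE`, in which case a simple documented
#' heuristic over the computed quantities is reported alongside them.
#'
#' @param config a [run_config()]; the first timescale and (for grids)
#'   the first grid cell are used unless scalar thresholds are given in
#'   `config$grid`.
#' @param classify attach heuristic behaviour labels (off by default;
#'   the labels are interpretive, the quantities are the result).
#' @return a `match_report` (written to `report.json` in `out_dir`).
#' @export
run_report <- function(config, classify = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- load_input(config)
  grid <- config$grid %||% default_grid(config$setting)
  thr <- if (config$setting == "local") {
    local_thresholds(grid$xi_D[1], grid$xi_VF[1], grid$xi_TR[1])
  } else {
    global_thresholds(Xi_AD = grid$Xi_AD[1], Xi_CM = grid$Xi_CM[1])
  }
  rep_ <- do.call(match_report,
                  c(list(traj, thr, config$timescales[1],
                         scope = config$scope), config$flags))
  if (classify) {
    rep_$label <- classify_heuristic(rep_)
  }
  match_report_json(rep_, file.path(config$out_dir, "report.json"))
  rep_
}

# Heuristic, opt-in behavioural labels built from the computed
# quantities; interpretive only.
classify_heuristic <- function(rep_) {
  if (rep_$n == 2) return("chasing")
  if (!is.na(rep_$mip_cut_match_rate) && rep_$mip_cut_match_rate < 30) {
    return("fission-fusion")
  }
  if (rep_$n >= 5) "interactive" else "leadership"
}

#' Read a collective-state sequence written by [write_state_seq()]
#'
#' @param path CSV path (`t,bit_1,...`); the JSON sidecar, when present,
#'   restores thresholds and convention flags.
#' @return a `state_seq`.
#' @export
read_state_seq <- function(path) {
  d <- read.csv(path)
  bits <- as.matrix(d[grepl("^bit_", names(d))])
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  new_state_seq(bits, meta$thresholds, meta$dt_frames %||% 1L,
                meta$fps %||% 120, meta$setting %||% "unknown",
                d$t, meta$n_zero_velocity %||% 0L,
                as.list(meta$flags %||% list()))
}
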