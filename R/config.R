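# Run configuration and experiment orchestration. A RunConfig is a flat
# YAML-style key/value file; run_experiment() executes train -> mode run(s)
# -> assessment and writes an artifact bundle whose files all embed the
# config hash, so mismatched artifacts can be detected on reload.

.tg_config_defaults <- list(
  fixture = "orthogonal",     # "orthogonal", "nonorthogonal", or a file path
  mode = "retrieval",
  duration = 1.0,             # s, scored window per run
  dt = 1e-4,                  # s
  theta_hz = NA,              # NA = basal preset frequency
  gamma_hz = NA,              # NA = basal (~35 Hz)
  n_runs = 10,
  seed = 1,
  out_dir = NULL)

#' Load and validate a run configuration
#'
#' Reads a YAML key/value file, fills defaults (`dt = 1e-4`,
#' `duration = 1.0`, `n_runs = 10`), and rejects unknown keys and invalid
#' values.
#'
#' @param path Path to a YAML config file, or a named list.
#' @return A validated `tg_config` (named list).
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), names(.tg_config_defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(.tg_config_defaults, raw)
  if (!is.numeric(cfg$dt) || cfg$dt <= 0)
    stop("config key 'dt' must be a positive number")
  if (!is.numeric(cfg$duration) || cfg$duration <= 0)
    stop("config key 'duration' must be a positive number")
  if (cfg$n_runs < 1) stop("config key 'n_runs' must be >= 1")
  modes <- c("retrieval", "imagination", "dreaming", "dreaming_fast_gamma",
             "dreaming_no_theta", "schizophrenia")
  if (!cfg$mode %in% modes)
    stop("config key 'mode' must be one of: ", paste(modes, collapse = ", "))
  structure(cfg, class = "tg_config")
}

#' Save a configuration to YAML
#'
#' @param cfg A `tg_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

.config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  # small stable polynomial hash over the serialized config
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.fixture_set <- function(fixture) {
  if (identical(fixture, "orthogonal")) return(make_orthogonal_set())
  if (identical(fixture, "nonorthogonal")) return(make_nonorthogonal_set())
  read_sequence_set(fixture)
}

#' Run a full experiment from a configuration
#'
#' Orchestrates training on the configured fixture, the frequency transforms,
#' the configured mode run(s), and the assessment. For `mode = "retrieval"`
#' the result is a success table; for isolation modes it is the simulation
#' trace bundle. If `out_dir` is set, a config echo, the table (text + JSON)
#' and a structured log are written there, all stamped with the config hash.
#'
#' @param config A `tg_config` from [load_config()] (or a named list).
#' @return A list with `config`, `hash`, `network`, and `table` (retrieval)
#'   or `sim` (isolation modes).
#' @export
run_experiment <- function(config) {
  cfg <- if (inherits(config, "tg_config")) config else load_config(config)
  hash <- .config_hash(cfg)
  t0 <- Sys.time()
  seqset <- .fixture_set(cfg$fixture)
  net <- build_network(seqset, dt = cfg$dt)
  net <- train_sequences(net, seqset, seed = cfg$seed)
  if (!is.na(cfg$theta_hz))
    net <- scale_time_constants(net, "theta_glutamatergic_and_slowGABA",
                                theta_factor(cfg$theta_hz))
  if (!is.na(cfg$gamma_hz) && cfg$gamma_hz != 35)
    net <- scale_time_constants(net, "L1L2_fastGABA",
                                fast_gamma_factor(cfg$gamma_hz))
  out <- list(config = cfg, hash = hash, network = net)
  if (cfg$mode == "retrieval") {
    out$table <- success_table(net, seqset, n_runs = cfg$n_runs,
                               duration = cfg$duration, seed = cfg$seed)
  } else {
    out$sim <- run_isolation(net, cfg$mode, duration = cfg$duration,
                             seed = cfg$seed)
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_config(structure(c(unclass(cfg), list(hash = hash)),
                          class = "tg_config"),
                file.path(cfg$out_dir, "config.yaml"))
    if (!is.null(out$table))
      write_success_table(out$table,
                          file.path(cfg$out_dir,
                                    paste0("success_table_", hash)))
    if (!is.null(out$sim))
      saveRDS(out$sim, file.path(cfg$out_dir,
                                 paste0("traces_", hash, ".rds")))
    log <- c(sprintf("config_hash: %s", hash),
             sprintf("seed: %s", cfg$seed),
             sprintf("mode: %s", cfg$mode),
             sprintf("elapsed_s: %.1f",
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    writeLines(log, file.path(cfg$out_dir, "run.log"))
  }
  out
}
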