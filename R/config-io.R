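# Configuration and record I/O: YAML config with schema validation and
# paper-default filling, deterministic per-module child seeds, record
# serialization with integrity checking, and CSV probe export.

CONFIG_BLOCKS <- c("bioicd", "cell", "substrate", "solver", "protocol",
                   "metrics", "output", "seed")

default_run_config <- function() {
  list(
    bioicd = unclass(bioicd_params())[1:14],
    cell = list(subtype = "epi", variant = "default"),
    substrate = list(kind = "homogeneous", nx = 256L, ny = 256L, dx = 0.025,
                     diffusion = 1.54, fraction = 0.20, scar_length_cm = 3.4,
                     gz_width_cm = 0.5),
    solver = list(dt = 0.02, duration = 1000, probe_every = 1,
                  frame_every = 5, snapshot_every = 100, use_tables = TRUE,
                  erev_every = 25L),
    protocol = list(pacing_freq = 1.2, s2_coupling = 340, pulse_amp = -52,
                    pulse_dur = 2),
    metrics = list(sync_v = -20, reset_v = -75, sync_level = 0.95,
                   reset_level = 0.99, current_threshold = 1, act_v = -20,
                   act_lockout = 50),
    output = list(record = "record.rds", probes_csv = NA),
    seed = 1L)
}

#' Load, validate and save run configurations
#'
#' Configurations are nested YAML with blocks `bioicd`, `cell`, `substrate`,
#' `solver`, `protocol`, `metrics`, `output` and a global `seed`. Unknown
#' keys are rejected with the path to the offending field; omitted keys take
#' the package defaults, which equal the published model values (conductance
#' 150 nS/pF, n = 8, tau 1400 ms, dt = 0.02 ms, dx = 0.025 cm, D = 1.54
#' cm^2/s, ...). A configuration round-trips losslessly through
#' [save_config()] / [load_config()].
#'
#' @param path YAML file path.
#' @return `load_config`: the resolved configuration (class `run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  resolve_config(raw)
}

#' @rdname load_config
#' @param config a configuration list (possibly partial).
#' @export
resolve_config <- function(config = list()) {
  def <- default_run_config()
  bad <- setdiff(names(config), CONFIG_BLOCKS)
  if (length(bad))
    stop("config schema violation at: ", paste(bad, collapse = ", "))
  for (blk in setdiff(names(config), "seed")) {
    unknown <- setdiff(names(config[[blk]]), names(def[[blk]]))
    if (length(unknown))
      stop("config schema violation at: ",
           paste(paste0(blk, "$", unknown), collapse = ", "))
    def[[blk]] <- utils::modifyList(def[[blk]], config[[blk]])
  }
  if (!is.null(config$seed)) def$seed <- as.integer(config$seed)
  validate_config(def)
  structure(def, class = "run_config")
}

validate_config <- function(cfg) {
  b <- cfg$bioicd
  if (b$g_max < 0) stop("config schema violation at: bioicd$g_max (negative)")
  if (b$tau_o <= 0 || b$tau_a <= 0)
    stop("config schema violation at: bioicd$tau_o/tau_a (non-positive)")
  if (b$v_cat_low >= b$v_cat_high)
    stop("config schema violation at: bioicd$v_cat_low/v_cat_high")
  if (cfg$solver$dt <= 0) stop("config schema violation at: solver$dt")
  if (cfg$substrate$dx <= 0) stop("config schema violation at: substrate$dx")
  dmax <- cfg$substrate$diffusion / 1000
  if (cfg$solver$dt >= cfg$substrate$dx^2 / (4 * dmax))
    stop("config schema violation at: solver$dt (diffusion stability bound)")
  invisible(cfg)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$output$probes_csv <- if (is.na(cfg$output$probes_csv)) NULL
                           else cfg$output$probes_csv
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Deterministic per-module child seed
#'
#' One global seed expands into independent child seeds keyed by module
#' name, so adding a module never perturbs another module's random stream.
#'
#' @param seed global integer seed.
#' @param module module name (e.g. `"substrate"`).
#' @return A positive integer seed below 2^31.
#' @export
child_seed <- function(seed, module) {
  h <- sum(utf8ToInt(module) * seq_along(utf8ToInt(module)) * 2654435.0)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629) + 1L
}

# --------------------------------------------------------------- record IO

#' Save / load a simulation record
#'
#' Records are written as RDS with an MD5 checksum sidecar (`<path>.md5`);
#' reading verifies the checksum when the sidecar is present and always
#' fails with an integrity error on truncated or corrupt files.
#'
#' @param record a `bioicd_record` (or any serializable run record).
#' @param path file path (`.rds`).
#' @return `write_record` returns `path` invisibly; `read_record` the
#'   record.
#' @export
write_record <- function(record, path) {
  saveRDS(record, path)
  md5 <- unname(tools::md5sum(path))
  writeLines(md5, paste0(path, ".md5"))
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path)
  side <- paste0(path, ".md5")
  if (file.exists(side)) {
    want <- readLines(side, n = 1)
    have <- unname(tools::md5sum(path))
    if (!identical(want, have))
      stop("integrity error: record checksum mismatch for ", path)
  }
  rec <- tryCatch(readRDS(path), error = function(e)
    stop("integrity error: cannot read record ", path, " (", conditionMessage(e), ")"))
  rec
}

#' Export probe traces as CSV
#'
#' Writes one row per sample with columns `time_ms` and, per probe,
#' `v_mV`, `i_bioicd_pApF`, `o`, `a1` (suffixed with the probe name).
#'
#' @param record a `bioicd_record`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
export_probes_csv <- function(record, path) {
  p <- record$probes
  df <- data.frame(time_ms = p$time)
  nm <- p$names %||% paste0("p", seq_len(ncol(p$v)))
  for (j in seq_len(ncol(p$v))) {
    df[[paste0("v_mV_", nm[j])]] <- p$v[, j]
    df[[paste0("i_bioicd_pApF_", nm[j])]] <- p$i_bioicd[, j]
    df[[paste0("o_", nm[j])]] <- p$o[, j]
    df[[paste0("a1_", nm[j])]] <- p$a1[, j]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
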