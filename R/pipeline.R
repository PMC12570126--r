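#' Default run configuration
#'
#' A nested list holding every tunable of the two workflows (model
#' exploration and genotype comparison), resolvable entirely offline:
#' membrane and synapse parameters, the two stimulus protocols, the occupancy
#' sweep list, repetition count, master seed and output directory. Serialized
#' to/from YAML by [write_config()] / [read_config()].
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_reps = 10L,
    outdir = ".",
    verbose = TRUE,
    membrane = list(c_m = 1, g_na = 120, g_k = 36, g_leak = 1,
                    e_na = 65, e_k = -74, e_leak = -85),
    circuit = list(g_axial = 2, occupancy = 9.04, rectified = FALSE,
                   spike_threshold = 0, refractory = 2),
    chem = list(g_syn = 0.1, v_syn = 0, tau_rise = 0.1, tau_decay = 3),
    gap_map = list(l_min = 0.01, l_max = 0.6, k_sig = 0.9, x0 = 5, p_sat = 10),
    single = list(pulse_rate = 10, n_pulses = 1L, pulse_amplitude = 80,
                  pulse_width = 0.5, noise_sd = 1, duration = 10, dt = 0.01,
                  onset = 1),
    train = list(pulse_rate = 100, n_pulses = 10L, pulse_amplitude = 80,
                 pulse_width = 0.5, noise_sd = 1, duration = 100, dt = 0.01,
                 onset = 1),
    sweep = list(occupancies = c(9.04, 8.26, 7.65, 5.37, 5.31, 4.18, 1)),
    compare = list(reference = "fra_LOF", alpha = 0.05, method = "analytic",
                   n_perm = 999L))
}

#' Read / write a run configuration
#'
#' YAML round-trip of the [default_config()] structure; unknown keys are
#' preserved, missing keys fall back to the defaults.
#'
#' @param path file path.
#' @param config configuration list.
#' @return `read_config()` returns the merged configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# rolling polynomial hash over the YAML serialization: a stable config
# fingerprint (base 31 mod 2^31 - 1, kept in double-precision-safe range)
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(config))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_circuit <- function(config) {
  gf_circuit(membrane = do.call(membrane_params, config$membrane),
             g_axial = config$circuit$g_axial,
             chem = do.call(chem_synapse_params, config$chem),
             gap_map = do.call(gap_map_params, config$gap_map),
             occupancy = config$circuit$occupancy,
             rectified = config$circuit$rectified,
             spike_threshold = config$circuit$spike_threshold,
             refractory = config$circuit$refractory)
}

config_spec <- function(config, which = c("single", "train"), seed = NULL) {
  which <- match.arg(which)
  do.call(stimulus_spec, c(config[[which]], list(seed = seed)))
}

write_run_log <- function(config, stage, outdir, extra = list()) {
  log <- c(list(stage = stage, config_hash = config_hash(config),
                seed = config$seed, timestamp = format(Sys.time(), tz = "UTC"),
                package_version = as.character(utils::packageVersion("gfsynapse"))),
           extra)
  jsonlite::write_json(log, file.path(outdir, paste0(stage, "_log.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the single-pulse and train protocols and write metric files
#'
#' Executes both protocols at the configured occupancy with seeded noise,
#' writes per-run metrics (`simulate_metrics.csv`), optional voltage traces
#' (`traces_single.csv`, `traces_train.csv`) and a JSON run log with the
#' config hash and master seed.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir output directory (created if missing); defaults to
#'   `config$outdir`.
#' @param traces logical; also dump voltage traces as CSV.
#' @return Invisibly, the metrics `data.frame`.
#' @export
cmd_simulate <- function(config = default_config(), outdir = config$outdir,
                         traces = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  circ <- config_circuit(config)
  rows <- lapply(seq_len(config$n_reps), function(r) {
    s1 <- config_spec(config, "single", seed = child_seed(config$seed, 1L, r))
    s2 <- config_spec(config, "train", seed = child_seed(config$seed, 2L, r))
    sim1 <- run_circuit(circ, s1)
    sim2 <- run_circuit(circ, s2)
    if (traces && r == 1L) {
      for (nm in c("single", "train")) {
        sim <- if (nm == "single") sim1 else sim2
        df <- data.frame(time_ms = sim$time, v0 = sim$v[, 1], v1 = sim$v[, 2],
                         v2 = sim$v[, 3], v3 = sim$v[, 4])
        utils::write.csv(df, file.path(outdir, paste0("traces_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
    data.frame(rep = r, occupancy = config$circuit$occupancy,
               latency_ms = sim1$latency, responded = !is.na(sim1$latency),
               response_pct = sim2$response_pct)
  })
  metrics <- do.call(rbind, rows)
  path <- file.path(outdir, "simulate_metrics.csv")
  # encode failed latencies as empty fields alongside the responded flag
  out <- metrics
  out$latency_ms <- ifelse(out$responded, format(out$latency_ms), "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  write_run_log(config, "simulate", outdir,
                list(metrics_file = "simulate_metrics.csv"))
  if (isTRUE(config$verbose))
    message("simulate: mean latency ",
            round(mean(metrics$latency_ms, na.rm = TRUE), 3), " ms, mean response ",
            round(mean(metrics$response_pct), 1), "% -> ", path)
  invisible(metrics)
}

#' Sweep occupancies and write the decrement-curve table
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the sweep `data.frame` (also written to `sweep.csv`).
#' @export
cmd_sweep <- function(config = default_config(), outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- genotype_sweep(config$sweep$occupancies,
                        circuit = config_circuit(config),
                        n_reps = config$n_reps, seed = config$seed,
                        single = config_spec(config, "single"),
                        train = config_spec(config, "train"))
  utils::write.csv(tab, file.path(outdir, "sweep.csv"), row.names = FALSE)
  write_run_log(config, "sweep", outdir, list(metrics_file = "sweep.csv"))
  invisible(tab)
}

#' Generate the synthetic per-terminal dataset
#'
#' @inheritParams cmd_simulate
#' @param table genotype table; defaults to [default_genotype_table()].
#' @return Invisibly, the terminal `data.frame` (written to `terminals.csv`).
#' @export
cmd_generate <- function(config = default_config(), outdir = config$outdir,
                         table = default_genotype_table()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  records <- generate_all_terminals(table, seed = config$seed)
  utils::write.csv(records, file.path(outdir, "terminals.csv"), row.names = FALSE)
  write_run_log(config, "generate", outdir,
                list(metrics_file = "terminals.csv", n_records = nrow(records)))
  invisible(records)
}

#' Run the genotype comparison table
#'
#' @inheritParams cmd_simulate
#' @param terminals terminal records `data.frame`, or a path to a CSV written
#'   by [cmd_generate()].
#' @return Invisibly, the comparison `data.frame` (written to
#'   `comparisons.csv`).
#' @export
cmd_compare <- function(config = default_config(), terminals,
                        outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(terminals))
    terminals <- utils::read.csv(terminals, stringsAsFactors = FALSE)
  tab <- table1_comparisons(terminals, reference = config$compare$reference,
                            alpha = config$compare$alpha,
                            method = config$compare$method,
                            n_perm = config$compare$n_perm,
                            seed = config$seed)
  utils::write.csv(tab, file.path(outdir, "comparisons.csv"), row.names = FALSE)
  write_run_log(config, "compare", outdir, list(metrics_file = "comparisons.csv"))
  invisible(tab)
}

#' Calibrate and report
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the `"gf_calibration"` object (summary written to
#'   `calibration.json`).
#' @export
cmd_calibrate <- function(config = default_config(), outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cal <- gf_calibrate(circuit = config_circuit(config))
  jsonlite::write_json(list(feasible = cal$feasible, params = cal$params,
                            metrics = cal$metrics),
                       file.path(outdir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_log(config, "calibrate", outdir,
                list(metrics_file = "calibration.json"))
  invisible(cal)
}
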