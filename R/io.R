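## Plain-text readers/writers: dataset CSVs with a ground-truth sidecar,
## JSON metadata and replication records, scenario configs as YAML or JSON,
## estimate and training-log CSVs.

#' Write / read a simulated dataset
#'
#' `write_sim_dataset` writes three files under `path` (a stem without
#' extension): `<stem>.csv` with columns `W_1..W_p, A, Y`;
#' `<stem>_truth.csv` with the ground-truth columns `Y0, Y1, g_true, eta`;
#' and `<stem>_meta.json` carrying the roles, seed, scenario configuration,
#' drawn coefficients and transformation records. `read_sim_dataset`
#' reassembles the `sim_dataset` from the three files.
#'
#' @param sim a `sim_dataset` from [simulate_scenario()].
#' @param path file stem (no extension).
#' @return `write_sim_dataset` returns `path` invisibly; `read_sim_dataset`
#'   returns a `sim_dataset`.
#' @export
write_sim_dataset <- function(sim, path) {
  stopifnot(inherits(sim, "sim_dataset"))
  main <- data.frame(sim$w, A = sim$a, Y = sim$y, check.names = FALSE)
  utils::write.csv(main, paste0(path, ".csv"), row.names = FALSE)
  truth <- data.frame(Y0 = sim$y0, Y1 = sim$y1, mu0 = sim$mu0,
                      g_true = sim$g_true, eta = sim$eta)
  utils::write.csv(truth, paste0(path, "_truth.csv"), row.names = FALSE)
  meta <- list(roles = sim$roles,
               config = unclass(sim$config),
               coefficients = sim$coefficients,
               transformations = sim$transformations)
  jsonlite::write_json(meta, paste0(path, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_sim_dataset
#' @export
read_sim_dataset <- function(path) {
  main <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  truth <- utils::read.csv(paste0(path, "_truth.csv"))
  meta <- jsonlite::read_json(paste0(path, "_meta.json"), simplifyVector = TRUE)
  p <- length(meta$roles)
  w <- as.matrix(main[, seq_len(p), drop = FALSE])
  cfg <- meta$config
  config <- scenario_config(n = cfg$n, p = cfg$p, block_sizes = cfg$block_sizes,
                            rho = cfg$rho, beta = cfg$beta,
                            intercept = cfg$intercept,
                            conf_range = cfg$conf_range, iv_range = cfg$iv_range,
                            nonlinear_fraction = cfg$nonlinear_fraction,
                            noise_sd = cfg$noise_sd, seed = cfg$seed)
  structure(list(w = w, roles = meta$roles, a = main$A, y = main$Y,
                 y0 = truth$Y0, y1 = truth$Y1, mu0 = truth$mu0,
                 g_true = truth$g_true, eta = truth$eta,
                 coefficients = meta$coefficients,
                 transformations = meta$transformations,
                 config = config),
            class = "sim_dataset")
}

#' Read a scenario configuration from a YAML or JSON file
#'
#' The file mirrors the [scenario_config()] fields verbatim.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_invalid("the yaml package is required for YAML configs", "invalid_input")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(scenario_config, cfg)
}

#' Write ATE estimates to CSV
#'
#' One row per estimate: method, point, stderr, ci bounds, n, plus optional
#' scenario/setting/seed identifiers.
#'
#' @param estimates list of `ate_estimate` objects.
#' @param path output CSV path.
#' @param scenario_id,setting_id,seed optional identifiers repeated per row.
#' @return the data.frame written, invisibly.
#' @export
write_estimates <- function(estimates, path, scenario_id = NA, setting_id = NA,
                            seed = NA) {
  df <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(method = e$method, point = e$point, stderr = e$stderr,
               ci_lower = e$ci_lower, ci_upper = e$ci_upper, n = e$n,
               scenario_id = scenario_id, setting_id = setting_id, seed = seed)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a per-epoch training log to CSV
#'
#' @param fit an `nn_fit` from [fit_network()].
#' @param path output CSV path.
#' @export
write_training_log <- function(fit, path) {
  stopifnot(inherits(fit, "nn_fit"))
  utils::write.csv(fit$log, path, row.names = FALSE)
  invisible(fit$log)
}

## Replication-record JSON round trip used by run_grid's resume mechanism.
write_record <- function(rec, path) {
  out <- list(
    scenario = unclass(rec$scenario), setting = unclass(rec$setting),
    seed = rec$seed, diverged = rec$diverged,
    scenario_id = rec$scenario_id, setting_id = rec$setting_id,
    replication = rec$replication
  )
  if (rec$diverged) {
    out$message <- rec$message
  } else {
    out$estimates <- as.list(rec$estimates)
    out$metrics <- unclass(rec$metrics)
    out$capture_counts <- as.data.frame(rec$capture$counts)
    out$capture_k <- rec$capture$k
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- list(
    scenario = do.call(scenario_config, x$scenario),
    setting = do.call(hyper_setting, x$setting),
    seed = x$seed, diverged = isTRUE(x$diverged),
    scenario_id = x$scenario_id, setting_id = x$setting_id,
    replication = x$replication
  )
  if (rec$diverged) {
    rec$message <- x$message
  } else {
    rec$estimates <- unlist(x$estimates)
    rec$metrics <- structure(x$metrics, class = "prediction_metrics")
    counts <- as.matrix(x$capture_counts)
    rownames(counts) <- c("outcome", "treatment")
    rec$capture <- structure(list(counts = counts, k = x$capture_k,
                                  assoc = NULL),
                             class = "capture_counts")
  }
  structure(rec, class = "replication_record")
}

#' Serialize network parameters to a JSON archive
#'
#' Writes every parameter tensor flat with a manifest (family, widths, input
#' size, standardization) so a fit can be stored as text and restored
#' exactly.
#'
#' @param net an `nn_model`.
#' @param path output JSON path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "nn_model"))
  cores <- model_cores(net)
  tensors <- lapply(cores, function(core) {
    flat <- core_to_flat(core)
    lapply(flat, function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
      else list(dim = length(x), data = as.numeric(x))
    })
  })
  jsonlite::write_json(list(family = net$family, p = net$p,
                            widths = net$widths,
                            standardize = net$standardize,
                            tensors = tensors),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- if (x$family == "joint") {
    joint_network(x$p, x$widths, seed = 0L)
  } else {
    double_network(x$p, x$widths, seed = 0L)
  }
  restore <- function(core, tens) {
    flat <- lapply(tens, function(t) {
      if (length(t$dim) == 2) matrix(t$data, t$dim[1], t$dim[2])
      else if (t$dim == 1) t$data[1] else t$data
    })
    flat_to_core(core, flat)
  }
  if (x$family == "joint") {
    net$core <- restore(net$core, x$tensors$joint)
  } else {
    net$outcome <- restore(net$outcome, x$tensors$outcome)
    net$treatment <- restore(net$treatment, x$tensors$treatment)
  }
  if (!is.null(x$standardize)) {
    net$standardize <- list(center = x$standardize$center,
                            scale = x$standardize$scale)
  }
  net
}
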