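## Monte Carlo harness: scenario x hyperparameter grid x replications, then
## bias / MC SD / RMSE summaries with percentile bootstrap intervals.

#' Hyperparameter setting for one grid cell
#'
#' @param family `"jNN"` (joint) or `"dNN"` (double).
#' @param widths hidden-layer sizes.
#' @param cl1 global L1 constant.
#' @param cl1tg targeted L1 constant.
#' @return an object of class `hyper_setting`.
#' @export
hyper_setting <- function(family = c("jNN", "dNN"), widths, cl1 = 0, cl1tg = 0) {
  family <- match.arg(family)
  if (cl1 < 0 || cl1tg < 0) {
    stop_invalid("penalty constants must be nonnegative", "invalid_parameter")
  }
  structure(list(family = family, widths = as.integer(widths),
                 cl1 = cl1, cl1tg = cl1tg),
            class = "hyper_setting")
}

setting_id <- function(s) {
  sprintf("%s.H%s.CL1_%g.CL1TG_%g", s$family,
          paste(s$widths, collapse = "_"), s$cl1, s$cl1tg)
}

#' Default 16-setting hyperparameter grid
#'
#' Crosses the two families with two trunk shapes (wide `[p, p, p]` and
#' bottlenecked `[ceiling(p/10), p, ceiling(p/10)]`), two global L1 constants
#' (0.01, 0.1) and two targeted constants (0, 0.7). Contains both
#' best-reported settings for each family.
#'
#' @param p number of covariates the networks will see.
#' @return a named list of 16 [hyper_setting()] objects.
#' @export
default_grid <- function(p) {
  narrow <- max(1L, ceiling(p / 10))
  out <- list()
  for (fam in c("jNN", "dNN")) {
    for (wid in list(rep(p, 3), c(narrow, p, narrow))) {
      for (cl1 in c(0.01, 0.1)) {
        for (cl1tg in c(0, 0.7)) {
          s <- hyper_setting(fam, wid, cl1, cl1tg)
          out[[setting_id(s)]] <- s
        }
      }
    }
  }
  out
}

#' Run one simulation replication end to end
#'
#' Simulates a dataset from the scenario, fits the setting's network family,
#' forms the nuisance predictions, computes all five ATE estimators, the
#' prediction metrics and the top-k capture counts. All randomness derives
#' from the single replication seed through [derive_seed()]: the dataset seed
#' depends only on the replication seed (so different settings on the same
#' seed share an identical dataset) and the fit seed is a separate child.
#'
#' Training divergence — and a degenerate replication whose dataset leaves an
#' estimator undefined (an empty treatment arm under extreme propensities) —
#' is caught and returned as a flagged record rather than an error.
#'
#' @param scenario a [scenario_config()].
#' @param setting a [hyper_setting()].
#' @param seed replication seed.
#' @param optimizer optional [optimizer_config()]; its seed is overridden by
#'   the derived fit seed.
#' @param capture_k top-k for the capture counts.
#' @return an object of class `replication_record`.
#' @export
run_replication <- function(scenario, setting, seed,
                            optimizer = optimizer_config(), capture_k = 15) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(setting, "hyper_setting"))
  sim_cfg <- scenario
  sim_cfg$seed <- derive_seed(seed, "sim")
  sim <- simulate_scenario(sim_cfg)
  optimizer$seed <- derive_seed(seed, "fit")
  loss <- loss_config(cl1 = setting$cl1, cl1tg = setting$cl1tg)
  net <- if (setting$family == "jNN") {
    joint_network(ncol(sim$w), setting$widths)
  } else {
    double_network(ncol(sim$w), setting$widths)
  }
  rec <- list(scenario = sim_cfg, setting = setting, seed = as.integer(seed),
              diverged = FALSE)
  flagged <- function(e) {
    rec$diverged <- TRUE
    rec$message <- conditionMessage(e)
    structure(rec, class = "replication_record")
  }
  tryCatch({
    fit <- fit_network(net, sim$w, sim$a, sim$y, loss, optimizer)
    preds <- fit$predictions
    fw <- forward_model(fit$net, sim$w, sim$a)
    rec$estimates <- estimate_all(sim$y, sim$a, preds)
    rec$metrics <- prediction_metrics(fw$yhat, sim$y, preds$ghat, sim$a)
    rec$capture <- capture_counts(sim$w, sim$roles, fw$yhat, preds$ghat,
                                  k = capture_k)
    structure(rec, class = "replication_record")
  },
  nnaipw_divergence = flagged,
  undefined_estimator = flagged,
  undefined_auc = flagged)
}

#' @export
print.replication_record <- function(x, ...) {
  cat("Replication (seed", x$seed, ") of", setting_id(x$setting), "\n")
  if (x$diverged) {
    cat("  training diverged:", x$message, "\n")
  } else {
    cat("  estimates:", paste(sprintf("%s=%.3f", names(x$estimates),
                                      x$estimates), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Run the full scenario x setting x replication grid
#'
#' Per-cell seeds derive from the master seed and the cell labels, so any
#' cell can be recomputed in isolation. When `out_dir` is given each record
#' is saved as a JSON file named after its cell and existing files are
#' skipped, making interrupted runs resumable.
#'
#' @param scenarios named list of [scenario_config()] objects.
#' @param settings named list of [hyper_setting()] objects.
#' @param replications replications per cell.
#' @param master_seed master integer seed.
#' @param out_dir optional directory for per-cell JSON records.
#' @param ... passed on to [run_replication()].
#' @return list of `replication_record` objects with scenario/setting ids
#'   attached.
#' @export
run_grid <- function(scenarios, settings, replications, master_seed = 1L,
                     out_dir = NULL, ...) {
  if (is.null(names(scenarios))) names(scenarios) <- paste0("scenario", seq_along(scenarios))
  if (is.null(names(settings))) names(settings) <- vapply(settings, setting_id, "")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  records <- list()
  for (sc in names(scenarios)) for (st in names(settings)) {
    for (r in seq_len(replications)) {
      cell <- paste(sc, st, r, sep = "::")
      seed <- derive_seed(master_seed, cell)
      path <- if (!is.null(out_dir)) {
        file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", cell), ".json"))
      } else NULL
      if (!is.null(path) && file.exists(path)) {
        rec <- read_record(path)
      } else {
        rec <- run_replication(scenarios[[sc]], settings[[st]], seed, ...)
        rec$scenario_id <- sc
        rec$setting_id <- st
        rec$replication <- r
        if (!is.null(path)) write_record(rec, path)
      }
      records[[cell]] <- rec
    }
  }
  records
}

#' Flatten replication records to a data frame
#'
#' One row per (scenario, setting, replication, estimator) with the point
#' estimate, prediction metrics and capture counts.
#'
#' @param records list of `replication_record` objects from [run_grid()].
#' @return a data.frame.
#' @export
records_to_df <- function(records) {
  rows <- lapply(records, function(r) {
    if (isTRUE(r$diverged)) return(NULL)
    data.frame(
      scenario_id = r$scenario_id %||% NA_character_,
      setting_id = r$setting_id %||% setting_id(r$setting),
      seed = r$seed,
      estimator = names(r$estimates),
      estimate = unname(r$estimates),
      r2 = r$metrics$r2, auc = r$metrics$auc, geo = r$metrics$geo,
      capture_iv_treatment = r$capture$counts["treatment", "iv"],
      capture_conf_treatment = r$capture$counts["treatment", "confounder"],
      capture_conf_outcome = r$capture$counts["outcome", "confounder"],
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Summarize replication records
#'
#' For every (scenario, setting, estimator) cell: `bias = mean(estimate) -
#' true_beta`, `mc_sd = sd(estimate)` across replications, `rmse =
#' sqrt(mean((estimate - true_beta)^2))`, each with a seeded percentile
#' bootstrap 95% interval over the replications, plus mean prediction metrics
#' and mean capture counts.
#'
#' @param records list from [run_grid()] or a data.frame from
#'   [records_to_df()].
#' @param true_beta the true treatment effect.
#' @param bootstrap_b number of bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return a data.frame of class `summary_table`, one row per cell.
#' @export
summarize_records <- function(records, true_beta, bootstrap_b = 1000, seed = 1L) {
  df <- if (is.data.frame(records)) records else records_to_df(records)
  if (is.null(df) || nrow(df) == 0) {
    stop_invalid("no non-diverged records to summarize", "degenerate_summary")
  }
  cells <- split(df, list(df$scenario_id, df$setting_id, df$estimator),
                 drop = TRUE)
  rows <- lapply(cells, function(d) {
    est <- d$estimate
    if (length(est) < 2) {
      stop_invalid("need at least 2 replications per cell", "degenerate_summary")
    }
    stat <- function(x) c(bias = mean(x) - true_beta,
                          mc_sd = stats::sd(x),
                          rmse = sqrt(mean((x - true_beta)^2)))
    pt <- stat(est)
    boot <- with_seed(derive_seed(seed, paste(d$scenario_id[1],
                                              d$setting_id[1],
                                              d$estimator[1])), {
      t(replicate(bootstrap_b, stat(sample(est, replace = TRUE))))
    })
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(
      scenario_id = d$scenario_id[1], setting_id = d$setting_id[1],
      estimator = d$estimator[1], replications = length(est),
      bias = pt["bias"], bias_lo = ci[1, "bias"], bias_hi = ci[2, "bias"],
      mc_sd = pt["mc_sd"], mc_sd_lo = ci[1, "mc_sd"], mc_sd_hi = ci[2, "mc_sd"],
      rmse = pt["rmse"], rmse_lo = ci[1, "rmse"], rmse_hi = ci[2, "rmse"],
      mean_r2 = mean(d$r2), mean_auc = mean(d$auc), mean_geo = mean(d$geo),
      mean_capture_iv_trt = mean(d$capture_iv_treatment),
      mean_capture_conf_trt = mean(d$capture_conf_treatment),
      row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary_table", class(out))
  out
}
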