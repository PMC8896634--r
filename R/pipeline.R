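## Study orchestration: equilibrate and simulate replicates, pool residency
## windows, run the null models, and emit Table-style summary TSVs plus run
## metadata. Replicates use independent seeds derived from the base seed, so
## results are invariant to execution order.

#' Default study configuration
#'
#' The defaults are the study conditions: a synthetic structure of L = 60 at
#' about 7 contacts per site, the packaged potential table, the 1qhw reported
#' mutation parameters, Ne = 100, kT = 0.6, 500 substitutions per replicate,
#' 25 replicates, windows of at least 10 substitutions, and 10,000
#' null-model windows at target autocorrelation 0.95.
#'
#' @param base_seed Integer base seed.
#' @return Nested configuration list.
#' @export
default_config <- function(base_seed = 1L) {
  list(
    structure = list(type = "synthetic", L = 60L, target_density = 7,
                     cutoff = 7.0, min_sep = 2L, n_decoys = 55L),
    potentials = list(source = "packaged"),
    mutation = list(protein = "1qhw"),
    evolution = list(Ne = 100L, kT = 0.6, nu = 3.4,
                     n_substitutions = 500L, n_replicates = 25L,
                     burn_in = 200L, exponent = "reported"),
    analysis = list(min_residency = 10L, complete_only = TRUE,
                    null_n_windows = 10000L, null_target_R = 0.95),
    seeds = list(base_seed = as.integer(base_seed)))
}

#' @noRd
.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Build the evolution context described by a configuration
#'
#' @param config Configuration list (see [default_config()]), or a path to
#'   a YAML file with the same blocks.
#' @return An [evol_context()]; the synthetic structure is attached as
#'   attribute `"structure"`.
#' @export
context_from_config <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .merge_config(default_config(), config)
  sc <- config$structure
  if (!identical(sc$type, "synthetic")) {
    st <- parse_structure(sc$pdb, chain = sc$chain %||% "A")
    map <- build_contact_map(st, cutoff = sc$cutoff, min_sep = sc$min_sep)
    syn <- list(structure = st, map = map, density = contact_density(map))
  } else {
    syn <- synthetic_structure(L = sc$L, target_density = sc$target_density,
                               rng_seed = config$seeds$base_seed,
                               cutoff = sc$cutoff, min_sep = sc$min_sep)
  }
  decoys <- generate_decoys(syn$map, n_decoys = sc$n_decoys,
                            rng_seed = config$seeds$base_seed + 1L)
  pot <- switch(config$potentials$source,
                packaged = default_potentials(),
                random = random_potentials(config$seeds$base_seed + 2L),
                read_potentials(config$potentials$source))
  mut <- if (!is.null(config$mutation$protein)) {
    study_fixtures()[[config$mutation$protein]]$mutation
  } else {
    mutation_params(config$mutation$kappa, config$mutation$pi_nuc,
                    normalize = TRUE)
  }
  ev <- config$evolution
  ctx <- evol_context(syn$map, decoys, pot, mut, Ne = ev$Ne,
                      params = energetics_params(kT = ev$kT, nu = ev$nu),
                      exponent = ev$exponent)
  attr(ctx, "structure") <- syn
  attr(ctx, "config") <- config
  ctx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full study
#'
#' Equilibrates and simulates `n_replicates` independent trajectories,
#' extracts and pools residency windows, summarizes the shift metrics, runs
#' the randomized and autocorrelated null models against the pooled
#' empirical distributions, and computes the stability/uniformity profile
#' of the first replicate. If `out_dir` is given, all tables are written as
#' TSV along with YAML run metadata.
#'
#' @param config Configuration list or YAML path (see [default_config()]).
#' @param out_dir Optional output directory.
#' @param progress Print one line per replicate.
#' @return An object of class `study_result`.
#' @export
run_study <- function(config = default_config(), out_dir = NULL,
                      progress = interactive()) {
  ctx <- context_from_config(config)
  config <- attr(ctx, "config")
  ev <- config$evolution
  an <- config$analysis
  base_seed <- config$seeds$base_seed
  trajectories <- vector("list", ev$n_replicates)
  windows <- list()
  for (rep in seq_len(ev$n_replicates)) {
    seed_r <- (base_seed + 7919L * rep) %% .Machine$integer.max
    traj <- withr::with_seed(seed_r, {
      st <- tryCatch(
        equilibrate(ctx, burn_in = ev$burn_in),
        error = function(e) stop("replicate ", rep, ", equilibration: ",
                                 conditionMessage(e)))
      tryCatch(
        simulate_trajectory(ctx, st, n_substitutions = ev$n_substitutions),
        error = function(e) stop("replicate ", rep, ", simulation: ",
                                 conditionMessage(e)))
    })
    attr(traj, "seed") <- seed_r
    trajectories[[rep]] <- traj
    windows <- c(windows,
                 extract_windows(traj, min_residency = an$min_residency,
                                 complete_only = an$complete_only))
    if (progress) {
      message(sprintf("replicate %d/%d: dG %.2f, %d pooled windows",
                      rep, ev$n_replicates, traj$dG[traj$n + 1],
                      length(windows)))
    }
  }
  if (length(windows) == 0) stop("study produced no residency windows")
  stability_summary <- summarize_shifts(windows)
  dists <- empirical_distributions(windows)
  target_R <- an$null_target_R %||% dists$lag1_target
  rand <- randomized_null(dists, n_windows = an$null_n_windows,
                          rng_seed = base_seed + 101L)
  auto <- autocorrelated_null(dists, n_windows = an$null_n_windows,
                              target_R = target_R,
                              rng_seed = base_seed + 103L)
  summary_tab <- rbind(
    cbind(model = "stability", stability_summary),
    cbind(model = "randomized", rand$summary),
    cbind(model = "autocorrelated", auto$summary))
  acs_sub <- lapply(trajectories, trajectory_autocorrelations,
                    clock = "substitution")
  acs_ns <- lapply(trajectories, trajectory_autocorrelations,
                   clock = "nonsynonymous")
  autocorr <- list(
    window_R1 = pooled_window_autocorrelation(windows),
    change_R1 = mean(vapply(acs_ns, `[[`, numeric(1), "change_R1")),
    site_R1_substitution_clock =
      mean(vapply(acs_sub, `[[`, numeric(1), "propensity_R1")),
    change_R1_substitution_clock =
      mean(vapply(acs_sub, `[[`, numeric(1), "change_R1")))
  profile <- stability_uniformity_profile(trajectories[[1]])
  res <- structure(list(config = config, ctx = ctx,
                        trajectories = trajectories, windows = windows,
                        dists = dists, summary = summary_tab,
                        randomized = rand, autocorrelated = auto,
                        autocorr = autocorr, profile = profile),
                   class = "study_result")
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", length(x$trajectories), "replicates,",
      length(x$windows), "pooled windows\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write study outputs to a directory
#'
#' @param res A [run_study()] result.
#' @param out_dir Output directory (created if needed).
#' @export
write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trajectories"), showWarnings = FALSE)
  for (rep in seq_along(res$trajectories)) {
    write_trajectory(res$trajectories[[rep]], res$ctx,
                     file.path(out_dir, "trajectories",
                               sprintf("rep_%03d", rep)))
  }
  write_window_metrics(res$windows, file.path(out_dir, "windows.tsv"))
  series <- data.frame(
    window = rep(seq_along(res$windows),
                 vapply(res$windows, `[[`, numeric(1), "T_res")),
    t = unlist(lapply(res$windows, function(w) seq_len(w$T_res))),
    propensity = unlist(lapply(res$windows, `[[`, "series")))
  utils::write.table(series, file.path(out_dir, "window_series.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$profile$states,
                     file.path(out_dir, "profile_states.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$profile$substitutions,
                     file.path(out_dir, "profile_substitutions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(config = res$config,
               replicate_seeds = vapply(res$trajectories, attr, numeric(1),
                                        "seed"),
               autocorr = res$autocorr,
               null_lag1_realized = res$autocorrelated$lag1_realized,
               spearman_dG_avgU = res$profile$spearman_dG_avgU,
               spearman_ddG_avg_dU = res$profile$spearman_ddG_avg_dU,
               package_version = as.character(utils::packageVersion("stabevol")))
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
  invisible(out_dir)
}

#' Human-readable study report
#'
#' @param res A [run_study()] result (or a directory written by
#'   [write_study()], from which the summary table is re-read).
#' @return Character vector of Markdown lines (also reported).
#' @export
report_study <- function(res) {
  if (is.character(res)) {
    path <- file.path(res, "summary.tsv")
    if (!file.exists(path)) stop("no summary.tsv under ", res)
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    lines <- c("# Propensity-shift study report", "",
               paste(utils::capture.output(print(tab, row.names = FALSE)),
                     collapse = "\n"))
    return(lines)
  }
  stopifnot(inherits(res, "study_result"))
  if (length(res$windows) == 0) {
    return("# Propensity-shift study report\n\nNo residency windows.")
  }
  fmt <- function(x) formatC(x, digits = 3, format = "fg")
  lines <- c(
    "# Propensity-shift study report", "",
    sprintf("Replicates: %d; pooled residency windows: %d (T_res >= %d).",
            length(res$trajectories), length(res$windows),
            res$config$analysis$min_residency),
    "",
    "## Percent negative shifts (Table-1-style)", "",
    utils::capture.output(print(res$summary[, c("model", "n_windows",
                                                "pct_neg_slr",
                                                "pct_neg_ami")],
                                row.names = FALSE)),
    "",
    sprintf("Pooled lag-1 autocorrelation: propensities %s; changes %s.",
            fmt(res$autocorr$window_R1), fmt(res$autocorr$change_R1)),
    sprintf("Autocorrelated null realized lag-1 R: %s (target %s).",
            fmt(res$autocorrelated$lag1_realized),
            fmt(res$config$analysis$null_target_R %||%
                  res$dists$lag1_target)),
    "",
    "## Stability / uniformity (replicate 1)", "",
    sprintf("Spearman(dG, avg U) = %s; Spearman(ddG, avg dU) = %s.",
            fmt(res$profile$spearman_dG_avgU),
            fmt(res$profile$spearman_ddG_avg_dU)))
  lines
}
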