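# Scenario orchestration: configuration-driven end-to-end runs of the four
# analysis flows on synthetic data, with planted truth reported next to the
# recovered estimates, plus deterministic report figures.

#' Run an end-to-end scenario
#'
#' Scenarios: `bap_profile` (distance-dependent bAP Ca2+ attenuation with
#' depolarization boost), `linearity` (EPSPs/APs/Both supralinearity),
#' `contact_geometry` (connected-pair generation and contact recovery),
#' `plasticity_map` (cohort plasticity pipeline). The summary pairs every
#' planted generator parameter with its recovered estimate.
#'
#' @param config A list (or path to a JSON file) with `scenario`, `seed`, and
#'   optional scenario parameters (`generator`, `analysis` sublists) and
#'   `out_dir`.
#' @return Invisibly, the summary list (also written as `summary.json` plus
#'   CSV tables and a log when `out_dir` is set).
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$scenario))
    stopf("config must name a scenario")
  scenario <- match.arg(config$scenario,
                        c("bap_profile", "linearity", "contact_geometry",
                          "plasticity_map"))
  seed <- config$seed %||% 1
  gen <- config$generator %||% list()
  ana <- config$analysis %||% list()
  summary <- switch(scenario,
    bap_profile = scenario_bap_profile(gen, ana, seed),
    linearity = scenario_linearity(gen, ana, seed),
    contact_geometry = scenario_contact_geometry(gen, ana, seed),
    plasticity_map = scenario_plasticity_map(gen, ana, seed))
  summary$scenario <- scenario
  summary$seed <- seed
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary[setdiff(names(summary), "tables")],
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    for (nm in names(summary$tables %||% list()))
      utils::write.csv(summary$tables[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    writeLines(c(sprintf("scenario: %s", scenario),
                 sprintf("seed: %s", seed),
                 sprintf("package: synplastkit %s",
                         as.character(utils::packageVersion("synplastkit"))),
                 sprintf("R: %s", R.version.string),
                 sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
               file.path(config$out_dir, "run.log"))
  }
  invisible(summary)
}

scenario_bap_profile <- function(gen, ana, seed) {
  ca <- do.call(synth_ca_params, gen[intersect(names(gen),
    names(formals(synth_ca_params)))])
  movies <- gen_linescan_dataset(ca, seed = seed,
    n_repeats = gen$n_repeats %||% 10)
  window <- ana$window %||% c(0, 275)
  meas <- do.call(rbind, lapply(movies, function(mv) {
    tr <- compute_dgr(mv)
    truth <- attr(mv, "truth")
    data.frame(location = truth$location, distance = mv$distance_to_soma,
               state = mv$state,
               integral = integrate_transient(tr, window),
               diameter = estimate_dendrite_diameter(mv))
  }))
  prof <- bap_distance_profile(meas)
  list(truth = list(lambda = ca$decay_length_lambda,
                    beta = ca$boost_slope_beta),
       recovered = list(lambda_rest = prof$lambda_rest,
                        lambda_depolarized = prof$lambda_depolarized,
                        boost_distance_r = prof$boost_distance_r,
                        boost_distance_p = prof$boost_distance_p),
       tables = list(measurements = meas, profile = prof$table))
}

scenario_linearity <- function(gen, ana, seed) {
  ca <- do.call(synth_ca_params, gen[intersect(names(gen),
    names(formals(synth_ca_params)))])
  out <- lapply(c(synchronous = "synchronous", asynchronous = "asynchronous"),
                function(tm) {
    movies <- gen_framescan_segments(ca, timing = tm,
      n_segments = gen$n_segments %||% 8,
      n_repeats = gen$n_repeats %||% 16,
      seed = child_seed(seed, if (tm == "synchronous") 1 else 2))
    linearity_analysis(movies, window = ana$window %||% c(0, 1000))
  })
  list(truth = list(supralinearity_synchronous = 100 * (1 + ca$interaction_gamma),
                    supralinearity_asynchronous = 100 * (1 + ca$interaction_gamma_async)),
       recovered = list(
         supralinearity_synchronous = out$synchronous$supralinearity,
         supralinearity_synchronous_sem = out$synchronous$supralinearity_sem,
         supralinearity_asynchronous = out$asynchronous$supralinearity,
         supralinearity_asynchronous_sem = out$asynchronous$supralinearity_sem),
       tables = list(synchronous = out$synchronous$per_segment,
                     asynchronous = out$asynchronous$per_segment))
}

scenario_contact_geometry <- function(gen, ana, seed) {
  n_pairs <- gen$n_pairs %||% 12
  params <- do.call(morpho_gen_params, gen[intersect(names(gen),
    names(formals(morpho_gen_params)))])
  n_contacts <- gen$n_contacts %||% 3
  rows <- lapply(seq_len(n_pairs), function(i) {
    pair <- gen_connected_pair(params, n_contacts = n_contacts,
                               seed = child_seed(seed, i))
    ct <- detect_contacts(pair, threshold = ana$threshold %||% 2.0)
    sh <- sholl(pair$post, step = ana$sholl_step %||% 6.5)
    data.frame(pair = i, planted = n_contacts, recovered = nrow(ct),
               mean_distance = if (nrow(ct)) mean(ct$distance_to_soma) else NA,
               mean_y_offset = if (nrow(ct)) mean(ct$y_offset) else NA,
               r75 = sh$r75)
  })
  tab <- do.call(rbind, rows)
  all_ct <- do.call(rbind, lapply(seq_len(n_pairs), function(i)
    detect_contacts(gen_connected_pair(params, n_contacts = n_contacts,
                                       seed = child_seed(seed, i)))))
  cs <- contact_stats(all_ct)
  list(truth = list(n_contacts = n_contacts,
                    descent_bias = params$axon_descent_bias),
       recovered = list(recovery_exact = all(tab$recovered == tab$planted),
                        mean_contact_distance = cs$mean_distance,
                        fraction_within_100um = cs$fraction_within_radius,
                        n_below_soma = cs$n_below_soma, n_total = cs$n,
                        p_below = cs$p_below, mean_r75 = mean(tab$r75)),
       tables = list(pairs = tab, contacts = all_ct))
}

scenario_plasticity_map <- function(gen, ana, seed) {
  n_conn <- gen$n_connections %||% 12
  conditions <- rep_len(c("synchronous", "asynchronous", "control"), n_conn)
  effects <- gen$effects %||%
    list(synchronous = 0.83, asynchronous = 1.0, control = 1.0)
  locus <- gen$locus %||% "presynaptic_dp"
  experiments <- lapply(seq_len(n_conn), function(i) {
    cond <- conditions[i]
    eff <- effects[[cond]] %||% 1.0
    tr <- plasticity_ground_truth(
      expression_locus = if (eff == 1) "none" else locus,
      effect_size = eff, condition = cond)
    gen_plasticity_experiment(release_model(), tr,
                              n_baseline = gen$n_baseline %||% 35,
                              n_post = gen$n_post %||% 60,
                              seed = child_seed(seed, i))
  })
  res <- run_plasticity_pipeline(experiments)
  list(truth = list(effects = effects, locus = locus),
       recovered = list(pooled = res$pooled),
       tables = list(per_connection = res$per_connection,
                     pooled = res$pooled))
}

#' Render report figures from a scenario summary
#'
#' Deterministic plots mirroring the study's figure layouts (distance
#' profiles, supralinearity boxplots, contact geometry, pooled plasticity);
#' one file per panel.
#'
#' @param summary A summary from [run_scenario()].
#' @param out_dir Output directory.
#' @param device `"pdf"` (default, robust headless) or `"png"`.
#' @return Character vector of files written.
#' @export
make_report <- function(summary, out_dir, device = c("pdf", "png")) {
  device <- match.arg(device)
  if (is.null(summary$scenario) || is.null(summary$tables) ||
      !length(summary$tables))
    stopf("empty or incomplete summary")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  open_dev <- function(name) {
    f <- file.path(out_dir, paste0(name, ".", device))
    if (device == "pdf") grDevices::pdf(f, width = 5, height = 4)
    else grDevices::png(f, width = 500, height = 400)
    files <<- c(files, f)
  }
  if (summary$scenario == "bap_profile") {
    tab <- summary$tables$profile
    open_dev("distance_profile")
    plot(tab$distance, tab$corrected_rest, pch = 1, col = "steelblue",
         xlab = "distance from soma (um)",
         ylab = "diameter-corrected dG/R integral (%.um)",
         main = "bAP Ca2+ transients vs distance")
    graphics::points(tab$distance, tab$corrected_depol, pch = 16, col = "navy")
    graphics::legend("topright", c("rest", "depolarized"),
                     pch = c(1, 16), col = c("steelblue", "navy"))
    grDevices::dev.off()
    open_dev("boost_vs_distance")
    plot(tab$distance, tab$corrected_depol - tab$corrected_rest, pch = 16,
         xlab = "distance from soma (um)", ylab = "boost (%.um)",
         main = sprintf("boost vs distance (r = %.2f)",
                        summary$recovered$boost_distance_r))
    grDevices::dev.off()
  } else if (summary$scenario == "linearity") {
    open_dev("supralinearity")
    vals <- list(synchronous = summary$tables$synchronous$supralinearity,
                 asynchronous = summary$tables$asynchronous$supralinearity)
    graphics::boxplot(vals, ylab = "supralinearity (%)",
                      main = "Ca2+ supralinearity by timing")
    graphics::abline(h = 100, lty = 2)
    grDevices::dev.off()
  } else if (summary$scenario == "contact_geometry") {
    ct <- summary$tables$contacts
    open_dev("contact_positions")
    plot(ct$x, ct$y_offset, pch = 16, col = "purple",
         xlab = "x (um)", ylab = "y offset from soma (um)",
         main = "putative contact positions")
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
  } else if (summary$scenario == "plasticity_map") {
    per <- summary$tables$per_connection
    open_dev("plasticity_ratio")
    graphics::boxplot(ratio ~ condition, data = per,
                      ylab = "EPSP after/before (%)",
                      main = "plasticity by induction condition")
    graphics::abline(h = 100, lty = 2)
    grDevices::dev.off()
    open_dev("cv_diagnostic")
    plot(per$mean_norm, per$inv_cv2_norm, pch = 16,
         xlab = "normalized mean", ylab = "normalized 1/CV^2",
         main = "CV quantal diagnostic")
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
  }
  files
}
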