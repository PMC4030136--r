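#' Default pipeline configuration
#'
#' Defaults mirror the analysis settings of the accompanying methods: 1-30 Hz
#' band-pass, 50 ms microstate search window, k = 1..20 clustering with CV
#' model selection, 200 ms Blackman-DFT spectral window at 10 Hz under five
#' references, FDR q = 0.05.
#'
#' @param ... overrides merged into the defaults (one nesting level, e.g.
#'   \code{microstate = list(k_max = 8)}).
#' @return nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = list(n_subjects = 11, k_templates = 5,
                    n_trials_per_condition = 40,
                    state_prob = NULL, alpha = NULL, diff_source = NULL,
                    noise_sd = 1.5, state_amplitude = 5),
    preprocess = list(reference = "average", band = c(1, 30),
                      artifact_threshold_uv = 100, window_ms = 50),
    microstate = list(k_min = 1, k_max = 20, restarts = 100, tol = 1e-6),
    inverse = list(lambda_rel = 0.1, grid_spacing = 0.13, n_terms = 60,
                   fdr_q = 0.05, all_trials = FALSE),
    spectral = list(references = c("average", "mastoids", "Fpz", "Cz", "Oz"),
                    freq = 10, window_ms = 200, flag_deg = 170),
    stats = list(alpha = 0.05))
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]])) {
      extra <- setdiff(names(ov[[nm]]), names(cfg[[nm]]))
      if (length(extra))
        stop("unknown config key(s) in ", nm, ": ", paste(extra, collapse = ", "))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose top-level keys follow
#'   \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pre-stimulus analysis pipeline on a synthetic cohort
#'
#' Stages: simulate cohort (planted templates, condition-dependent structure)
#' -> re-reference + band-pass + artifact rejection -> single-trial peak maps
#' -> polarity-invariant clustering with CV model selection -> labeling and
#' per-condition GEV contrasts -> LAURA-style source contrast on trials
#' labeled with the dissociating templates -> alpha power and phase-lag
#' analysis under multiple references. Fully deterministic given the seed.
#'
#' @param config a \code{\link{pipeline_config}} list or path to a YAML file.
#' @param out_dir optional directory; when given, per-stage tables (CSV/TSV)
#'   and a markdown report are written there.
#' @return list of class \code{ms_pipeline} with per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- do.call(pipeline_config, config)   # validate + fill defaults
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(...) message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0), ...)

  log_stage("setup: montage, head model, lead field")
  montage <- make_montage(204, seed = cfg$seed)
  head <- head_model()
  sources <- source_space(head, spacing = cfg$inverse$grid_spacing)
  lf <- compute_leadfield(montage, head, sources, n_terms = cfg$inverse$n_terms)

  log_stage("simulate: ", cfg$simulate$n_subjects, " subjects, ",
            cfg$simulate$k_templates, " planted templates")
  templates <- make_templates(montage, cfg$simulate$k_templates, lf,
                              seed = cfg$seed)
  sim_over <- cfg$simulate[!vapply(cfg$simulate, is.null, TRUE)]
  sim_over <- sim_over[setdiff(names(sim_over), c("n_subjects", "k_templates"))]
  params <- do.call(sim_params, sim_over)
  cohort <- simulate_cohort(cfg$simulate$n_subjects, templates, montage,
                            params, leadfield = lf, seed = cfg$seed)

  log_stage("preprocess: reference, 1-30 Hz zero-phase band-pass, artifacts")
  spec <- filter_spec(cfg$preprocess$band[1], cfg$preprocess$band[2])
  raw <- lapply(cohort, function(s) rereference(s$epochs, cfg$preprocess$reference))
  filtered <- lapply(raw, function(ep) {
    r <- reject_artifacts(bandpass_filter(ep, spec),
                          cfg$preprocess$artifact_threshold_uv)
    r$epochs
  })

  log_stage("microstates: peak maps + clustering k = ", cfg$microstate$k_min,
            "..", cfg$microstate$k_max)
  pmaps <- lapply(filtered, peak_maps, window_ms = cfg$preprocess$window_ms)
  pooled <- pool_peak_maps(pmaps)
  scan <- cluster_microstates(pooled,
                              k_range = cfg$microstate$k_min:cfg$microstate$k_max,
                              restarts = cfg$microstate$restarts,
                              tol = cfg$microstate$tol, seed = cfg$seed)
  model <- get_model(scan)
  labeling <- label_trials(pooled, model$templates)
  gev <- gev_by_map_condition(labeling)
  gev_tests <- do.call(rbind, lapply(seq_len(model$k), function(j) {
    r <- compare_gev(gev, j)
    data.frame(template = j, t = r$statistic, df = r$df, p = r$p)
  }))
  dissociating <- gev_tests$template[gev_tests$p < cfg$stats$alpha]

  log_stage("sources: LAURA-style inverse + point-wise contrast (",
            length(dissociating), " dissociating template(s))")
  op <- build_laura_operator(lf, lambda_rel = cfg$inverse$lambda_rel)
  subj_ids <- vapply(filtered, `[[`, "", "subject_id")
  mags <- lapply(seq_along(filtered), function(s) {
    tab <- labeling$table[labeling$table$subject == subj_ids[s], ]
    keep <- if (cfg$inverse$all_trials || !length(dissociating)) seq_len(nrow(tab))
            else which(tab$label %in% dissociating)
    if (!length(keep)) keep <- seq_len(nrow(tab))
    m <- estimate_source_magnitudes(pmaps[[s]]$maps[tab$trial[keep], , drop = FALSE], op)
    conds <- tab$condition[keep]
    list(CA = rowMeans(m[, conds == "CA", drop = FALSE]),
         CU = rowMeans(m[, conds == "CU", drop = FALSE]))
  })
  spm <- spm_contrast(do.call(rbind, lapply(mags, `[[`, "CA")),
                      do.call(rbind, lapply(mags, `[[`, "CU")),
                      sources, q = cfg$inverse$fdr_q)

  log_stage("spectral: power contrast + phase lags under ",
            length(cfg$spectral$references), " references")
  power_tab <- alpha_power_contrast(raw, freq = cfg$spectral$freq,
                                    window_ms = cfg$spectral$window_ms,
                                    q = cfg$inverse$fdr_q)
  phase_tabs <- phase_lag_analysis(raw,
                                   references = as.list(cfg$spectral$references),
                                   freq = cfg$spectral$freq,
                                   window_ms = cfg$spectral$window_ms,
                                   flag_deg = cfg$spectral$flag_deg,
                                   alpha = cfg$stats$alpha)

  res <- structure(list(config = cfg, montage = montage, templates = templates,
                        scan = scan, model = model, labeling = labeling,
                        gev = gev, gev_tests = gev_tests,
                        dissociating = dissociating, spm = spm,
                        power = power_tab, phase = phase_tabs,
                        sources = sources),
                   class = "ms_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.ms_pipeline <- function(x, ...) {
  cat("<ms_pipeline> seed ", x$config$seed, "\n", sep = "")
  cat("  CV-selected k = ", x$model$k, "; gev_total = ",
      sprintf("%.3f", x$model$gev_total), "\n", sep = "")
  cat("  dissociating templates (GEV p < ", x$config$stats$alpha, "): ",
      if (length(x$dissociating)) paste(x$dissociating, collapse = ", ")
      else "none", "\n", sep = "")
  pk <- x$spm$table[x$spm$peak, ]
  cat(sprintf("  source peak |t|: t = %.2f, p = %.4g%s\n", pk$t, pk$p,
              if (!is.null(x$spm$peak_point))
                sprintf(" at (%.2f, %.2f, %.2f)", x$spm$peak_point[1],
                        x$spm$peak_point[2], x$spm$peak_point[3]) else ""))
  for (nm in names(x$phase))
    cat("  phase flags (", nm, "): ",
        paste(x$phase[[nm]]$channel[which(x$phase[[nm]]$flagged)],
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

# write per-stage artifacts: CSV/TSV tables + markdown report
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(res$model$templates,
                   file.path(out_dir, "templates.csv"), row.names = FALSE)
  wt(res$labeling$table, "labels.tsv")
  wt(res$gev, "gev.tsv")
  wt(res$gev_tests, "gev_tests.tsv")
  wt(res$spm$table, "source_spm.tsv")
  wt(data.frame(channel = res$power$channel, t = res$power$t,
                p = res$power$p, p_adj = res$power$p_adj,
                significant = res$power$significant), "power_contrast.tsv")
  for (nm in names(res$phase))
    wt(res$phase[[nm]], paste0("phase_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv"))
  cfg_json <- jsonlite::toJSON(res$config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  writeLines(cfg_json, file.path(out_dir, "config.json"))
  rep <- c(
    "# Pre-stimulus analysis report", "",
    paste0("- seed: ", res$config$seed,
           "; config sha: ", substr(digest_string(cfg_json), 1, 12)),
    paste0("- CV-selected k: ", res$model$k, " (GEV total ",
           sprintf("%.3f", res$model$gev_total), ")"),
    paste0("- dissociating templates: ",
           if (length(res$dissociating))
             paste(res$dissociating, collapse = ", ") else "none"),
    paste0("- source peak |t| at point ", res$spm$peak,
           if (!is.null(res$spm$peak_point))
             sprintf(" (%.2f, %.2f, %.2f)", res$spm$peak_point[1],
                     res$spm$peak_point[2], res$spm$peak_point[3]) else "",
           sprintf(": t = %.2f", res$spm$table$t[res$spm$peak])),
    "",
    "## Flagged near-inversion electrodes per reference", "")
  for (nm in names(res$phase)) {
    fl <- res$phase[[nm]]$channel[which(res$phase[[nm]]$flagged)]
    rep <- c(rep, paste0("- ", nm, ": ",
                         if (length(fl)) paste(fl, collapse = ", ") else "none"))
  }
  writeLines(rep, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

# small dependency-free content id (polynomial hash over utf8 bytes, hex)
digest_string <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 68719476736   # mod 2^36, exact in double
  sprintf("%012x", h)
}
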