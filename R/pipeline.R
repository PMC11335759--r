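#' Assemble a run configuration
#'
#' Reads a flat YAML file (or takes a named list) and fills defaults for
#' every stage parameter of [run_all()].  Referenced input paths are
#' checked up front so a misconfigured run fails before any stage starts.
#'
#' @param config path to a YAML file, or a named list.
#' @return list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_input(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1,
    cohort_dir = NULL,            # read an existing cohort instead of simulating
    reference_path = NULL,        # read an existing reference table
    n_per_arm_per_physician = 25,
    n_physicians = 4,
    treatment_effect = 0,
    n_reference = 2000,
    agree_rate_dose = 0.63,
    agree_rate_trigger = 0.78,
    unavailable_rate = 0.045,
    k = 100,
    k_impute = 10,
    degree = 2,
    bootstrap_reps = 200,
    dose_step = 37.5,
    ridge_penalty = 0,
    min_rows = 30,
    from_day = 7,
    gain_threshold = 0.05,
    e2_threshold = 5000,
    n_dose_curves = 3
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort_input(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  for (p in c("cohort_dir", "reference_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      abort_input(sprintf("configured %s does not exist: %s", p, cfg[[p]]))
    }
  }
  structure(cfg, class = "run_config")
}

stamped_csv <- function(df, path, stamp) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.csv(df, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stim_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "stim_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), reference-cohort
#' simulation (or loading), baseline imputation, starting-dose curves for
#' a sample of treatment patients, trigger-model training on the control
#' arm and per-visit predictions, per-physician matching with arm
#' comparisons, and the accordance and survey-agreement subanalyses.
#' Every report CSV carries a first-line comment stamping the config hash
#' and seed; rerunning with the same config is byte-identical.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param out_dir report directory, created if needed.
#' @return `out_dir`, invisibly; the directory holds `table1.csv`,
#'   `table2.csv`, `table3.csv`, `pairs.csv`, `balance.csv`,
#'   `dose_curves.csv`, `recommended_doses.csv`, `accordance_flags.csv`,
#'   `agreement_comparison.csv`, `imputation_log.csv`,
#'   `trigger_model.json`, `config.yaml`, `run_info.txt`, and the cohort
#'   CSVs under `cohort/`.
#' @export
run_all <- function(config = list(), out_dir) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stamp <- sprintf("# stim_run config_hash=%s seed=%d", cfg_hash, cfg$seed)

  # --- cohort -------------------------------------------------------------
  sim_cfg <- sim_config(
    n_per_arm_per_physician = cfg$n_per_arm_per_physician,
    n_physicians = cfg$n_physicians,
    seed = cfg$seed,
    treatment_effect = cfg$treatment_effect
  )
  coh <- run_stage("cohort", {
    if (!is.null(cfg$cohort_dir)) {
      sp <- file.path(cfg$cohort_dir, "surveys.csv")
      read_cohort(file.path(cfg$cohort_dir, "baselines.csv"),
                  file.path(cfg$cohort_dir, "visits.csv"),
                  file.path(cfg$cohort_dir, "outcomes.csv"),
                  if (file.exists(sp)) sp else NULL)
    } else {
      simulate_cohort(sim_cfg)$cohort
    }
  })
  if (is.null(coh$surveys)) {
    coh$surveys <- run_stage("survey", simulate_survey(
      coh, cfg$agree_rate_dose, cfg$agree_rate_trigger,
      seed = (cfg$seed + 2000003) %% MOD31,
      unavailable_rate = cfg$unavailable_rate
    ))
  }
  write_cohort(coh, file.path(out_dir, "cohort"))

  # --- reference ----------------------------------------------------------
  reference <- run_stage("reference", {
    if (!is.null(cfg$reference_path)) {
      utils::read.csv(cfg$reference_path, stringsAsFactors = FALSE)
    } else {
      ref_cfg <- sim_config(seed = (cfg$seed + 1000003) %% MOD31)
      simulate_reference(cfg$n_reference, ref_cfg)
    }
  })

  # --- imputation ---------------------------------------------------------
  imp <- run_stage("imputation",
                   impute_baseline(coh$baselines, reference, cfg$k_impute))
  coh$baselines <- imp$patients
  stamped_csv(imp$log, file.path(out_dir, "imputation_log.csv"), stamp)

  # --- starting-dose curves -----------------------------------------------
  run_stage("starting_dose", {
    treat <- coh$baselines[coh$baselines$arm == "treatment", , drop = FALSE]
    treat <- treat[order(treat$patient_id), , drop = FALSE]
    pick <- utils::head(treat, cfg$n_dose_curves)
    curves <- list(); recs <- list()
    for (i in seq_len(nrow(pick))) {
      cu <- starting_dose_curve(reference, pick[i, , drop = FALSE],
                                k = cfg$k, degree = cfg$degree,
                                bootstrap_reps = cfg$bootstrap_reps,
                                seed = cfg$seed)
      curves[[i]] <- data.frame(patient_id = pick$patient_id[i],
                                dose = cu$dose_grid,
                                pred_mii = cu$predicted_mii,
                                band_low = cu$band_low,
                                band_high = cu$band_high)
      recs[[i]] <- data.frame(patient_id = pick$patient_id[i],
                              recommended_dose = recommend_dose(cu, cfg$dose_step))
    }
    stamped_csv(do.call(rbind, curves), file.path(out_dir, "dose_curves.csv"), stamp)
    stamped_csv(do.call(rbind, recs),
                file.path(out_dir, "recommended_doses.csv"), stamp)
  })

  # --- trigger model (trained on the historical control arm) ---------------
  model <- run_stage("trigger_model", {
    ctrl_ids <- coh$baselines$patient_id[coh$baselines$arm == "control"]
    ctrl <- coh
    ctrl$baselines <- coh$baselines[coh$baselines$arm == "control", , drop = FALSE]
    ctrl$visits <- coh$visits[coh$visits$patient_id %in% ctrl_ids, , drop = FALSE]
    ctrl$outcomes <- coh$outcomes[coh$outcomes$patient_id %in% ctrl_ids, , drop = FALSE]
    m <- train_trigger_model(build_training_rows(ctrl),
                             ridge_penalty = cfg$ridge_penalty,
                             min_rows = cfg$min_rows)
    serialize_model(m, file.path(out_dir, "trigger_model.json"))
    m
  })

  # --- matching and arm comparison ----------------------------------------
  matched <- run_stage("matching", match_patients(coh$baselines))
  comparison <- run_stage("comparison", compare_arms(matched, coh$outcomes))
  stamped_csv(matched$pairs, file.path(out_dir, "pairs.csv"), stamp)
  stamped_csv(matched$smd, file.path(out_dir, "balance.csv"), stamp)
  stamped_csv(baseline_table(matched, coh$baselines),
              file.path(out_dir, "table1.csv"), stamp)
  stamped_csv(as.data.frame(comparison), file.path(out_dir, "table2.csv"), stamp)

  # --- subanalyses ---------------------------------------------------------
  flags <- run_stage("accordance", accordance_flags(
    coh, model, from_day = cfg$from_day,
    gain_threshold = cfg$gain_threshold, e2_threshold = cfg$e2_threshold
  ))
  stamped_csv(flags, file.path(out_dir, "accordance_flags.csv"), stamp)
  acc <- run_stage("accordance_report", accordance_report(coh, flags))
  stamped_csv(as.data.frame(acc$comparison), file.path(out_dir, "table3.csv"), stamp)

  agr <- run_stage("agreement", agreement_groups(coh$surveys, coh))
  agr_tab <- do.call(rbind, lapply(c("agree", "disagree"), function(g) {
    cmp <- agr[[g]]$comparison
    if (is.null(cmp)) return(NULL)
    cbind(group = g, as.data.frame(cmp))
  }))
  stamped_csv(agr_tab %||% data.frame(),
              file.path(out_dir, "agreement_comparison.csv"), stamp)

  writeLines(c(sprintf("config_hash: %s", cfg_hash),
               sprintf("seed: %d", cfg$seed),
               sprintf("n_patients: %d", nrow(coh$baselines)),
               sprintf("n_accordant: %d", acc$n_accordant)),
             file.path(out_dir, "run_info.txt"))
  invisible(out_dir)
}
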