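#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> fit -> roc -> stats -> recover ->
#' pupil -> report over a synthetic cohort, writing plain delimited result
#' tables and a JSON run manifest (config echo, seeds, package version) so a
#' run is exactly reproducible from its manifest.
#'
#' @param config Named list. Recognised entries: `task` ("perceptual" or
#'   "numerical"), `n_subjects`, `n_trials` (numerical task), `stages`
#'   (character subset of the stage names above), `model` (generative model
#'   tag), `weight_means`, `n_boot`, `n_perm`, `design` (task design object),
#'   `pupil` (logical; pupil stage
#'   simulates and preprocesses one block per subject).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param outdir Output directory (created).
#' @return Invisibly, a list of in-memory stage results; side effect: files
#'   under `outdir`.
#' @export
run_pipeline <- function(config = list(), seed = 1, outdir = tempfile("run")) {
  defaults <- list(task = "perceptual", n_subjects = 8, n_trials = 2000,
                   stages = c("simulate", "preprocess", "fit", "roc",
                              "stats", "report"),
                   model = "global",
                   weight_means = c(w1c = 0.7, w2c = 0.3,
                                    w1nc = 0.5, w2nc = 0.5),
                   n_boot = 100, n_perm = 10000, pupil = FALSE,
                   design = NULL)
  config <- utils::modifyList(defaults, config)
  bad <- setdiff(config$stages,
                 c("simulate", "preprocess", "fit", "roc", "stats",
                   "recover", "pupil", "report"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config, seed = seed)
  wtab <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  cohort <- NULL
  if ("simulate" %in% config$stages) {
    cohort <- simulate_cohort(config$n_subjects, config$task, seed = seed,
                              weight_means = config$weight_means,
                              model = config$model, design = config$design,
                              n_trials = config$n_trials)
    res$generative_params <- cohort$params
    all_tr <- do.call(rbind, lapply(seq_along(cohort$subjects), function(s) {
      tr <- cohort$subjects[[s]]$trials
      tr$subject <- s
      tr[, setdiff(names(tr), c("samples1", "samples2"))]
    }))
    wtab(all_tr, "trials.tsv")
    wtab(cohort$params, "generative_params.tsv")
  }
  if (is.null(cohort)) stop("later stages need the simulate stage")

  kept <- lapply(cohort$subjects, function(su) su$trials)
  if ("preprocess" %in% config$stages) {
    reports <- list()
    for (s in seq_along(kept)) {
      ex <- apply_exclusions(kept[[s]])
      kept[[s]] <- label_consistency(ex$trials)
      reports[[s]] <- as.data.frame(ex$report[c("n_total", "n_wrong_button",
                                                "n_fast_rt", "n_outlier",
                                                "fraction_excluded")])
    }
    res$exclusions <- do.call(rbind, reports)
    wtab(cbind(subject = seq_along(kept), res$exclusions), "exclusions.tsv")
  }

  if (any(c("fit", "stats", "recover") %in% config$stages)) {
    res$fits <- vector("list", length(kept))
    rows <- list()
    for (s in seq_along(kept)) {
      tr <- kept[[s]]
      if (config$task == "numerical") tr <- bin_numerical_evidence(tr)
      psych <- fit_psychometric(
        phi1 = if (config$task == "numerical")
          tr$phi1_bin_center[tr$condition == "choice" & !is.na(tr$D)]
        else tr$phi1[tr$condition == "choice" & !is.na(tr$D)],
        D = tr$D[tr$condition == "choice" & !is.na(tr$D)])
      fit <- fit_gain_model(tr, psych, model = "global", starts = 1)
      res$fits[[s]] <- fit
      rows[[s]] <- data.frame(subject = s, alpha = psych$alpha,
                              delta = psych$delta, t(fit$params),
                              loglik = fit$loglik)
    }
    res$fit_table <- do.call(rbind, rows)
    wtab(res$fit_table, "fits.tsv")
  }

  if ("roc" %in% config$stages) {
    rows <- lapply(seq_along(kept), function(s) {
      data.frame(subject = s,
                 roc_choice = weighted_roc_index(kept[[s]], "choice")$overall,
                 roc_nochoice = weighted_roc_index(kept[[s]], "nochoice")$overall)
    })
    res$roc_table <- do.call(rbind, rows)
    wtab(res$roc_table, "roc.tsv")
  }

  if ("stats" %in% config$stages) {
    ft <- res$fit_table
    res$stats <- list(
      w2_perm = paired_permutation_test(ft$w2nc, ft$w2c,
                                        n_perm = config$n_perm,
                                        seed = seed + 1L),
      interaction = rm_anova_2x2(cbind(ft$w1c, ft$w1nc, ft$w2c, ft$w2nc)))
    if (!is.null(res$roc_table))
      res$stats$roc_perm <- paired_permutation_test(
        res$roc_table$roc_nochoice, res$roc_table$roc_choice,
        n_perm = config$n_perm, seed = seed + 2L)
  }

  if ("recover" %in% config$stages)
    res$recovery <- recovery_experiment(res$fits, seed = seed + 3L,
                                        n_rep = config$n_boot * 10)

  if ("pupil" %in% config$stages || isTRUE(config$pupil)) {
    s1 <- kept[[1]][seq_len(min(20, nrow(kept[[1]]))), ]
    trace <- simulate_pupil(s1, fs = 200, seed = seed + 4L)
    trace <- interpolate_blinks(trace)
    trace <- remove_event_responses(trace, window = 4, res = 0.1)
    trace <- filter_normalize(trace, fs_out = 50)
    res$pupil_epochs <- epoch_and_baseline(trace)
    wtab(data.frame(time = trace$time, diameter = trace$diameter),
         "pupil_trace.tsv")
    wtab(trace$events[, c("time", "type", "duration")], "pupil_events.tsv")
  }

  if ("report" %in% config$stages && !is.null(res$stats)) {
    rep <- data.frame(
      measure = c("w2 nochoice - choice (mean)", "w2 permutation p",
                  "interval x condition interaction F", "interaction p"),
      value = c(res$stats$w2_perm$statistic, res$stats$w2_perm$p,
                res$stats$interaction$F, res$stats$interaction$p))
    if (!is.null(res$stats$roc_perm))
      rep <- rbind(rep, data.frame(
        measure = c("ROC nochoice - choice (mean)", "ROC permutation p"),
        value = c(res$stats$roc_perm$statistic, res$stats$roc_perm$p)))
    wtab(rep, "report.tsv")
    res$report <- rep
  }

  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("choicegain")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, force = TRUE),
             file.path(outdir, "manifest.json"))
  invisible(res)
}
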