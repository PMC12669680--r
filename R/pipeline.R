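# End-to-end orchestration: synthesize -> preprocess -> epoch -> classify ->
# behavioural / luminance / field-potential statistics, from a single config.

#' Configuration for a full synthetic-study analysis run
#'
#' Bundles a participant roster (controls see both fields; aware-like
#' patients have reduced blind-field evoked gain; unaware-like patients
#' none), the per-session generator settings, analysis toggles and the
#' master seed. The default roster mirrors an 8 control / 4 aware /
#' 4 unaware study shape; session length is set by `n_blocks` and
#' `trials_per_block`.
#'
#' @param roster Tibble with `participant` and `group` (one of `control`,
#'   `patient-aware`, `patient-unaware`). Default: C1-C8, A1-A4, U1-U4.
#' @param n_blocks,trials_per_block Session scale per participant.
#' @param aware_blind_gain Blind-field evoked gain of aware-like patients.
#' @param aware_blind_perception,unaware_blind_perception Blind-field
#'   target perception probability by group.
#' @param stimulus_category Epoch class contrasted with blanks
#'   (`"nontarget"` or `"target"`).
#' @param folds Cross-validation folds for the stacked classifier.
#' @param feature_end_ms,bin_ms Classifier feature window and bin width.
#' @param presence_n_perm Label permutations behind the eye-metric
#'   presence criterion (0 disables the correspondence stage).
#' @param run_meg Also simulate and test evoked field potentials?
#' @param noise_sd Pupil noise innovation SD passed to the generator.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(roster = NULL,
                       n_blocks = 2, trials_per_block = 40,
                       aware_blind_gain = 0.4,
                       aware_blind_perception = 0.5,
                       unaware_blind_perception = 0.02,
                       stimulus_category = "nontarget",
                       folds = 10,
                       feature_end_ms = 4000, bin_ms = 20,
                       presence_n_perm = 50,
                       run_meg = FALSE,
                       noise_sd = 1.5,
                       seed = 1) {
  if (is.null(roster)) {
    roster <- tibble::tibble(
      participant = c(paste0("C", 1:8), paste0("A", 1:4), paste0("U", 1:4)),
      group = c(rep("control", 8), rep("patient-aware", 4),
                rep("patient-unaware", 4))
    )
  }
  stopifnot(all(c("participant", "group") %in% names(roster)),
            all(roster$group %in% c("control", "patient-aware",
                                    "patient-unaware")))
  stopifnot(stimulus_category %in% c("nontarget", "target"))
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

participant_synth_config <- function(cfg, group, seed) {
  if (group == "control") {
    synth_config(
      n_blocks = cfg$n_blocks, trials_per_block = cfg$trials_per_block,
      field_mix = c(left = 0.5, right = 0.5),
      evoked_gain_by_field = c(left = 1, right = 1),
      perception_prob_by_field = c(left = 0.95, right = 0.95),
      noise_sd = cfg$noise_sd, seed = seed
    )
  } else {
    blind_gain <- if (group == "patient-aware") cfg$aware_blind_gain else 0
    blind_perc <- if (group == "patient-aware") cfg$aware_blind_perception
                  else cfg$unaware_blind_perception
    synth_config(
      n_blocks = cfg$n_blocks, trials_per_block = cfg$trials_per_block,
      evoked_gain_by_field = c(sighted = 1, blind = blind_gain),
      perception_prob_by_field = c(sighted = 0.95, blind = blind_perc),
      noise_sd = cfg$noise_sd, seed = seed
    )
  }
}

# One participant: session -> preprocessing -> epochs -> per-field
# classification + per-class pupil means.
analyse_participant <- function(cfg, participant, group, seed) {
  scfg <- participant_synth_config(cfg, group, seed)
  ses <- generate_session(scfg)
  blinks <- detect_blinks(ses$recording)
  clean <- clean_pupil(ses$recording, blinks)
  msacc <- detect_microsaccades(ses$recording, exclude = blinks)

  blanks <- sample_blank_events(ses$events, ses$block_end_ms, seed = seed + 1)
  all_events <- dplyr::bind_rows(
    dplyr::mutate(ses$events, pair_id = .data$event_id), blanks
  )
  win <- epoch_window()
  raw_ep <- extract_epochs(ses$recording, all_events, win, signal = "pupil")
  validity <- ses$recording
  validity$tracked <- as.numeric(ses$recording$valid)
  valid_ep <- extract_epochs(validity, all_events, win, signal = "tracked")
  pupil_ep <- extract_epochs(clean, all_events, win, signal = "pupil",
                             baseline = TRUE)
  pupil_ep <- apply_pupil_exclusion(pupil_ep, raw = raw_ep)
  blink_ep <- extract_epochs(blinks, all_events, win)
  blink_ep <- apply_binary_exclusion(blink_ep, validity = valid_ep)
  ms_ep <- extract_epochs(msacc, all_events, win)
  ms_ep <- apply_binary_exclusion(ms_ep, validity = valid_ep)

  # the stack needs all three metrics per epoch
  common <- pupil_ep$included & blink_ep$included & ms_ep$included
  for (e in c("pupil_ep", "blink_ep", "ms_ep")) {
    x <- get(e)
    x$included <- common
    assign(e, x)
  }
  pupil_ep <- harmonise_pairs(pupil_ep)
  common <- pupil_ep$included
  blink_ep$included <- common
  ms_ep$included <- common

  fields <- names(scfg$field_mix)
  is_cat <- if (cfg$stimulus_category == "target") {
    pupil_ep$meta$event_class %in% target_classes
  } else {
    pupil_ep$meta$event_class %in% nontarget_classes
  }
  fits <- list()
  for (f in fields) {
    sel <- which(common & is_cat & pupil_ep$meta$field == f)
    if (length(sel) < 8) next  # at least 4 surviving pairs per condition
    sub <- list(pupil = subset_epochs(pupil_ep, sel),
                blink = subset_epochs(blink_ep, sel),
                microsaccade = subset_epochs(ms_ep, sel))
    feats <- purrr::map(sub, build_feature_matrix,
                        feature_end_ms = cfg$feature_end_ms,
                        bin_ms = cfg$bin_ms)
    meta <- attr(feats$pupil, "meta")
    labels <- ifelse(meta$is_blank, "blank", "stimulus")
    k <- min(cfg$folds, length(unique(meta$pair_id)))
    folds <- make_folds(meta, k = k, seed = seed + 2)
    fit <- fit_stacked_classifier(feats, labels, folds)
    null <- NULL
    if (cfg$presence_n_perm > 0 && group != "control" && f == "blind") {
      null <- permutation_null(feats, labels, folds,
                               n_perm = cfg$presence_n_perm, seed = seed + 3)
    }
    fits[[f]] <- list(fit = fit, null = null, features = feats,
                      labels = labels, folds = folds)
  }

  # luminance minima from sighted-side (or field-averaged control) means
  lum_fields <- if (group == "control") fields else "sighted"
  minima <- purrr::map_dbl(c("white", "glare", "nonglare"), function(cl) {
    sel <- which(common & pupil_ep$meta$event_class == cl &
                   !pupil_ep$meta$is_blank &
                   pupil_ep$meta$field %in% lum_fields)
    if (length(sel) == 0) return(NA_real_)
    min_constriction(epoch_mean(subset_epochs(pupil_ep, sel)))
  })

  behaviour <- score_perception(ses$events, ses$responses)
  orientation <- score_orientation(behaviour)

  list(
    participant = participant, group = group,
    fits = fits,
    behaviour = behaviour, orientation = orientation,
    minima = stats::setNames(minima, c("white", "glare", "nonglare")),
    exclusion = glance(pupil_ep)$exclusion_fraction
  )
}

#' Run the full synthetic-study analysis
#'
#' Executes, for every roster participant, session generation,
#' preprocessing, blank sampling, epoching with exclusions, stacked
#' stimulus-vs-blank classification per field, behavioural scoring and
#' luminance minima; then the group-level accuracy tests (against chance,
#' field contrasts, aware vs unaware blind-field contrast), the
#' luminance-ordered slope test per group, and the blind-field
#' correspondence table for patients. All stages derive their randomness
#' from the master seed, so a fixed config reproduces the report exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the machine-readable
#'   summary is written as `summary.json` and the log as `run_log.txt`.
#' @return A list of class `oculaware_run`: `accuracy` (per participant x
#'   field), `group_tests`, `behaviour`, `slope_test`, `correspondence`,
#'   `meg` (when enabled), `params`.
#' @export
run_full_analysis <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- substream_seeds(config$seed,
                           c(config$roster$participant, "meg", "blanks"))
  res <- purrr::pmap(
    list(config$roster$participant, config$roster$group),
    function(p, g) analyse_participant(config, p, g, seeds[[p]])
  )
  names(res) <- config$roster$participant

  accuracy <- purrr::map_dfr(res, function(r) {
    purrr::imap_dfr(r$fits, function(fld, f) {
      tibble::tibble(participant = r$participant, group = r$group,
                     condition = f, accuracy = fld$fit$accuracy,
                     chance = fld$fit$chance)
    })
  })
  conds <- unique(accuracy$condition)
  paired <- if (length(conds) == 2) list(conds) else list()
  group_ct <- if ("blind" %in% conds &&
                  all(c("patient-aware", "patient-unaware") %in% accuracy$group)) {
    list(list(condition = "blind",
              groups = c("patient-aware", "patient-unaware")))
  } else {
    list()
  }
  group_tests <- group_accuracy_stats(accuracy, paired_contrasts = paired,
                                      group_contrasts = group_ct)

  behaviour <- purrr::map_dfr(res, function(r) {
    dplyr::mutate(dplyr::select(r$behaviour, -"rts"),
                  participant = r$participant, group = r$group, .before = 1)
  })

  minima <- purrr::map_dfr(res, function(r) {
    tibble::tibble(participant = r$participant, group = r$group,
                   white = r$minima[["white"]], glare = r$minima[["glare"]],
                   nonglare = r$minima[["nonglare"]])
  })
  minima_ok <- stats::complete.cases(minima[, c("white", "glare", "nonglare")])
  slope <- if (sum(minima_ok) >= 2) {
    luminance_slope_test(minima[minima_ok, ])
  } else {
    NULL
  }

  correspondence <- NULL
  if (config$presence_n_perm > 0) {
    pats <- res[config$roster$group != "control"]
    if (length(pats) > 0) {
      cor_in <- purrr::map_dfr(pats, function(r) {
        blind <- r$fits[["blind"]]
        present <- if (!is.null(blind) && !is.null(blind$null)) {
          any(eye_metric_presence(blind$fit, blind$null)$present)
        } else {
          FALSE
        }
        rate <- r$behaviour$perception_rate[r$behaviour$field == "blind"]
        tibble::tibble(
          participant = r$participant,
          perception_rate = if (length(rate)) rate else 0,
          # verbal-report fraction emulated by the generator's blind-field
          # perception probability realised in this session
          verbal_fraction = if (length(rate)) rate else 0,
          eye_present = present
        )
      })
      correspondence <- correspondence_table(cor_in)
    }
  }

  meg <- NULL
  if (isTRUE(config$run_meg)) {
    amps <- list(
      "sighted-stim" = c(P1 = 40, N2 = 120, LN = 60),
      "blind-stim" = c(P1 = 15, N2 = 45, LN = 20),
      "blank" = c(P1 = 0, N2 = 0, LN = 0)
    )
    fp <- generate_field_potential_epochs(30, amps, noise_sd = 60,
                                          seed = seeds[["meg"]])
    contrasts <- list(c("sighted-stim", "blank"), c("blind-stim", "blank"),
                      c("sighted-stim", "blind-stim"))
    meg <- purrr::map_dfr(contrasts, function(ct) {
      cr <- cluster_permutation(fp, ct[1], ct[2], n_perm = 1000,
                                seed = seeds[["meg"]])
      dplyr::mutate(glance(cr), contrast = paste(ct, collapse = " vs "),
                    .before = 1)
    })
  }

  out <- structure(
    list(accuracy = accuracy, group_tests = group_tests,
         behaviour = behaviour, minima = minima, slope_test = slope,
         correspondence = correspondence, meg = meg,
         params = config),
    class = "oculaware_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary_list(out),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(run_log_lines(out), file.path(out_dir, "run_log.txt"))
  }
  out
}

summary_list <- function(run) {
  list(
    accuracy = run$accuracy,
    group_tests = run$group_tests,
    behaviour = run$behaviour,
    minima = run$minima,
    slope_test = if (!is.null(run$slope_test)) run$slope_test$tests,
    correspondence = run$correspondence,
    meg = run$meg
  )
}

run_log_lines <- function(run) {
  cfg <- run$params
  c("oculaware analysis run",
    sprintf("seed: %d", cfg$seed),
    sprintf("roster: %d participants (%s)", nrow(cfg$roster),
            paste(sprintf("%s=%d", names(table(cfg$roster$group)),
                          table(cfg$roster$group)), collapse = ", ")),
    sprintf("session: %d block(s) x %d trials", cfg$n_blocks,
            cfg$trials_per_block),
    sprintf("classifier: %s vs blank, %d folds, %d-ms bins to %d ms, cost 1",
            cfg$stimulus_category, cfg$folds, cfg$bin_ms, cfg$feature_end_ms),
    sprintf("aware blind-field gain: %.2f; perception aware %.2f / unaware %.2f",
            cfg$aware_blind_gain, cfg$aware_blind_perception,
            cfg$unaware_blind_perception),
    sprintf("presence permutations: %d; meg: %s", cfg$presence_n_perm,
            cfg$run_meg))
}

#' @export
print.oculaware_run <- function(x, ...) {
  cat("<oculaware_run>\n")
  cat(sprintf("  %d participants, %d classifier fits\n",
              length(unique(x$accuracy$participant)), nrow(x$accuracy)))
  print(x$group_tests)
  invisible(x)
}
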