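# End-to-end orchestration of the two-stage analysis:
#   simulate/load -> normalize -> likelihood-ratio screening ->
#   factor-analysis feature selection -> G2DE clustering ->
#   demographics + odds-ratio tables.
# Every stage writes its artifact under one run directory; the run summary
# records every parameter actually used, and two runs with an identical
# configuration produce byte-identical artifacts.

#' Configuration of a full pipeline run
#'
#' @param cohort either a [cohort_config()] (the cohort is simulated) or
#'   the path of an existing subject table.
#' @param k,beta RVKDE hyper-parameters for the screening stage.
#' @param threshold likelihood-ratio selection threshold (strict `>`);
#'   ignored when `target_fraction` is given.
#' @param target_fraction optional selected fraction of cases; when set,
#'   the threshold is computed from the ratio distribution via
#'   [threshold_for_fraction()].
#' @param exclude_self leave-one-out evaluation of case densities during
#'   screening.
#' @param normalize min-max normalize the pooled feature matrix before
#'   density estimation (recorded min/max reused for all projections).
#' @param cutoff factor-loading cutoff for feature selection.
#' @param K number of G2DE components.
#' @param n_restarts EM restarts.
#' @param rng_seed master seed: seeds the cohort simulation (when `cohort`
#'   is a config its own seed is kept) and the EM initialization.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            k = 10, beta = 1,
                            threshold = 1, target_fraction = NULL,
                            exclude_self = TRUE,
                            normalize = TRUE,
                            cutoff = 0.4,
                            K = 2, n_restarts = 5,
                            rng_seed = 1L) {
  stopifnot(k >= 1, beta > 0, threshold >= 0, K >= 1, n_restarts >= 1)
  if (!is.null(target_fraction))
    stopifnot(target_fraction > 0, target_fraction < 1)
  structure(list(
    cohort = cohort, k = k, beta = beta, threshold = threshold,
    target_fraction = target_fraction, exclude_self = exclude_self,
    normalize = normalize, cutoff = cutoff, K = K,
    n_restarts = n_restarts, rng_seed = as.integer(rng_seed)
  ), class = "pipeline_config")
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[comorbscreen] ", fmt), ...))
}

#' Run the two-stage analysis end to end
#'
#' Executes simulate/load, normalization, RVKDE likelihood-ratio screening,
#' factor-analysis feature selection on the cases of interest, G2DE
#' clustering in the selected-feature subspace, and the three between-group
#' comparisons (case vs control, of-interest vs remaining cases, cluster 1
#' vs cluster 0).  Artifacts written under `out_dir`:
#' `subjects.tsv` (subject table with `of_interest` and `cluster` columns),
#' `ratios.tsv`, `factor_report.tsv`, `g2de_model.txt`,
#' `demographics_*.tsv`, `odds_*.tsv` and `summary.yaml`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if missing).
#' @param verbose emit per-stage progress messages.
#' @return Invisibly, a list with the in-memory results: `subjects`,
#'   `screening`, `factor_selection`, `g2de`, `tables`, `summary`.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate/load"
  res <- tryCatch(
    run_pipeline_stages(config, out_dir, verbose),
    error = function(e) {
      stop(sprintf("pipeline failed in stage [%s]: %s",
                   attr(e, "pipeline_stage") %||% stage, conditionMessage(e)),
           call. = FALSE)
    })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    attr(e, "pipeline_stage") <- name
    stop(e)
  })
}

run_pipeline_stages <- function(config, out_dir, verbose) {
  # -- stage 1: cohort -------------------------------------------------------
  subjects <- with_stage("simulate/load", {
    if (inherits(config$cohort, "cohort_config")) {
      pipeline_log(verbose, "simulating cohort: %d cases, 1:%d matching",
                   config$cohort$n_cases, config$cohort$match_ratio)
      generate_cohort(config$cohort)
    } else {
      pipeline_log(verbose, "loading subject table %s", config$cohort)
      read_subject_table(config$cohort)
    }
  })

  is_case <- subjects$group == "case"
  features <- subjects_to_features(subjects)

  # -- stage 2: normalization ------------------------------------------------
  norm <- NULL
  if (config$normalize) {
    norm <- min_max_normalize(features)
    features_n <- norm$matrix
    pipeline_log(verbose, "min-max normalized %d x %d feature matrix",
                 nrow(features_n), ncol(features_n))
  } else {
    features_n <- features
  }

  # -- stage 3: screening ----------------------------------------------------
  screening <- with_stage("screening", {
    scr <- select_of_interest(features_n[is_case, , drop = FALSE],
                              features_n[!is_case, , drop = FALSE],
                              k = config$k, beta = config$beta,
                              threshold = config$threshold,
                              exclude_self = config$exclude_self)
    if (!is.null(config$target_fraction)) {
      thr <- threshold_for_fraction(scr$ratios, config$target_fraction)
      scr$threshold <- thr
      scr$selected <- scr$ratios > thr
      scr$selected_ids <- rownames(features_n[is_case, , drop = FALSE])[scr$selected]
    }
    scr
  })
  n_selected <- sum(screening$selected)
  pipeline_log(verbose, "screening: %d of %d cases of interest (%.1f%%) at threshold %.4g",
               n_selected, sum(is_case), 100 * n_selected / sum(is_case),
               screening$threshold)
  if (n_selected < config$K * (ncol(features_n) + 1))
    stop("too few cases of interest to continue (", n_selected, ")")

  subjects$of_interest <- 0L
  subjects$of_interest[is_case] <- as.integer(screening$selected)

  # -- stage 4: factor selection (on cases of interest) ----------------------
  interest_rows <- which(is_case)[screening$selected]
  fsel <- with_stage("feature selection", {
    run_factor_selection(features_n[interest_rows, , drop = FALSE],
                         cutoff = config$cutoff)
  })
  sel_feats <- fsel$selected_features
  if (length(sel_feats) < 2) {
    warning("fewer than two features selected; falling back to all non-constant features")
    sel_feats <- setdiff(colnames(features_n), fsel$dropped)
  }
  pipeline_log(verbose,
               "factor selection: KMO %.3f, Bartlett p %.3g, %d factor(s), features: %s",
               fsel$kmo, fsel$bartlett_p, fsel$n_factors,
               paste(sel_feats, collapse = ", "))

  # -- stage 5: clustering ---------------------------------------------------
  g2 <- with_stage("clustering", {
    fit_g2de(features_n[interest_rows, sel_feats, drop = FALSE],
             K = config$K, n_restarts = config$n_restarts,
             rng_seed = config$rng_seed)
  })
  labels <- assign_clusters(g2, features_n[interest_rows, sel_feats, drop = FALSE])
  subjects$cluster <- NA_integer_
  subjects$cluster[interest_rows] <- labels
  sizes <- table(factor(labels, levels = 0:(config$K - 1)))
  pipeline_log(verbose, "clustering: sizes %s",
               paste(sprintf("cluster %s: %d", names(sizes), sizes), collapse = ", "))

  # -- stage 6: statistics ---------------------------------------------------
  tables <- with_stage("statistics", {
    cases <- subjects[is_case, , drop = FALSE]
    interest <- subjects[interest_rows, , drop = FALSE]
    out <- list(
      demographics_case_control = build_demographics(
        subjects, subjects$group, group_levels = c("case", "control")),
      odds_case_control = outcome_odds_table(
        subjects, subjects$group, group_levels = c("case", "control")),
      demographics_interest_remaining = build_demographics(
        cases, ifelse(cases$of_interest == 1, "of_interest", "remaining"),
        group_levels = c("of_interest", "remaining")),
      odds_interest_remaining = outcome_odds_table(
        cases, ifelse(cases$of_interest == 1, "of_interest", "remaining"),
        group_levels = c("of_interest", "remaining"))
    )
    if (all(c(0, 1) %in% labels)) {
      part <- paste0("cluster", interest$cluster)
      out$demographics_clusters <- build_demographics(
        interest, part, group_levels = c("cluster1", "cluster0"))
      out$odds_clusters <- outcome_odds_table(
        interest, part, group_levels = c("cluster1", "cluster0"))
    }
    out
  })

  # -- artifacts -------------------------------------------------------------
  summary <- list(
    parameters = list(
      cohort = if (inherits(config$cohort, "cohort_config")) {
        list(source = "simulated",
             n_cases = config$cohort$n_cases,
             match_ratio = config$cohort$match_ratio,
             cluster_fractions = as.list(config$cohort$cluster_fractions),
             rng_seed = config$cohort$rng_seed)
      } else list(source = "file"),
      rvkde = list(k = config$k, beta = config$beta,
                   case_sigma_floor = screening$case_model$sigma_floor,
                   control_sigma_floor = screening$control_model$sigma_floor),
      screening = list(threshold = screening$threshold,
                       target_fraction = config$target_fraction,
                       exclude_self = config$exclude_self),
      normalize = config$normalize,
      factor_selection = list(cutoff = config$cutoff, rotation = "varimax"),
      g2de = list(K = config$K, n_restarts = config$n_restarts,
                  rng_seed = config$rng_seed)
    ),
    results = list(
      n_cases = sum(is_case),
      n_controls = sum(!is_case),
      n_of_interest = n_selected,
      selected_fraction = n_selected / sum(is_case),
      kmo = fsel$kmo,
      bartlett_statistic = fsel$bartlett_stat,
      bartlett_p = fsel$bartlett_p,
      n_factors = fsel$n_factors,
      selected_features = as.list(sel_feats),
      g2de_loglik = g2$loglik,
      g2de_iterations = g2$n_iter,
      cluster_sizes = as.list(stats::setNames(as.integer(sizes),
                                              paste0("cluster", names(sizes))))
    )
  )

  with_stage("write artifacts", {
    write_subject_table(subjects, file.path(out_dir, "subjects.tsv"))
    ratio_tab <- data.frame(
      subject_id = subjects$subject_id[is_case],
      ratio = screening$ratios,
      of_interest = as.integer(screening$selected))
    utils::write.table(ratio_tab, file.path(out_dir, "ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    feat_names <- rownames(fsel$rotated_loadings) %||%
      colnames(features_n)[!colnames(features_n) %in% fsel$dropped]
    factor_report <- data.frame(feature = feat_names)
    if (fsel$n_factors > 0) {
      load_tab <- round(fsel$rotated_loadings, 6)
      colnames(load_tab) <- paste0("factor", seq_len(ncol(load_tab)))
      factor_report <- cbind(factor_report, load_tab,
                             max_abs_loading = apply(abs(fsel$rotated_loadings), 1, max))
    }
    factor_report$selected <- as.integer(feat_names %in% sel_feats)
    utils::write.table(factor_report, file.path(out_dir, "factor_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_g2de(g2, file.path(out_dir, "g2de_model.txt"))
    for (nm in names(tables))
      utils::write.table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"),
                     precision = 15)
  })
  pipeline_log(verbose, "run complete; artifacts in %s", out_dir)

  invisible(list(subjects = subjects, screening = screening,
                 factor_selection = fsel, g2de = g2, tables = tables,
                 summary = summary))
}
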