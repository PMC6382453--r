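#' Run the full model benchmark on a cohort
#'
#' End-to-end orchestration: metabolite columns are minimum-imputed, every
#' model of the grid is restricted to its complete cases and scored by
#' repeated nested cross-validation, per-model ROC performance is summarized
#' (AUC with DeLong CI, F-index cutoff, confusion metrics), every
#' non-reference model is compared with the reference model by the DeLong
#' paired test, and the whole batch of comparison p-values is converted to
#' positive-FDR q-values with the two-decimal rounding significance rule.
#'
#' Because per-model complete-case exclusion can give different participant
#' subsets, each DeLong comparison is made on the participants shared by the
#' model and the reference; the reference scores are recomputed on that
#' common subset whenever it differs from the reference's own subset, so the
#' pairing is always valid (`n_common` and `recomputed` record this per
#' comparison).
#'
#' @param cohort An `ogtt_cohort`.
#' @param grid Either a tibble from [enumerate_grid()] / [enumerate_family()]
#'   or a list of [model_family()] objects; defaults to
#'   [default_model_grid()].
#' @param cv A [cv_config()]; its seed is overridden by `seed`.
#' @param reference Reference model, as a marker vector or `model_id` string
#'   (default the 1-h PG singleton). Added to the grid with a message when
#'   absent.
#' @param ci_method,boot_replicates Passed to [delong_ci()].
#' @param pi0_method Passed to [qvalues()].
#' @param seed Master seed for the whole run.
#' @return An `ogtt_benchmark` object: list with `performance` and
#'   `comparisons` tibbles, `reference`, and a `manifest` echoing every
#'   default actually used.
#' @export
run_benchmark <- function(cohort,
                          grid = default_model_grid(),
                          cv = cv_config(),
                          reference = "PG60",
                          ci_method = c("analytic", "stratified_bootstrap"),
                          boot_replicates = 2000L,
                          pi0_method = c("storey", "fixed_one"),
                          seed = 1L) {
  ci_method <- rlang::arg_match(ci_method)
  pi0_method <- rlang::arg_match(pi0_method)
  if (!tibble::is_tibble(grid)) grid <- enumerate_grid(grid)
  cv$seed <- as.integer(seed)

  ref_id <- model_id_of(reference)
  if (!ref_id %in% grid$model_id) {
    message("reference model `", ref_id, "` absent from grid; added.")
    grid <- dplyr::bind_rows(
      grid,
      tibble::tibble(model_id = ref_id,
                     members = list(canonical_members(reference)),
                     n_markers = length(canonical_members(reference)),
                     family = "reference")
    )
  }
  cohort <- impute_metabolites(cohort)

  score_model <- function(members, sub = cohort) {
    nested_cv_scores(sub, members, cv)
  }
  scores <- purrr::map(grid$members, score_model)
  names(scores) <- grid$model_id

  performance <- purrr::imap_dfr(scores, function(sv, id) {
    roc <- roc_curve(sv$score, sv$outcome)
    cut <- f_index_cutoff(roc)
    ci <- delong_ci(sv$score, sv$outcome, method = ci_method,
                    replicates = boot_replicates,
                    seed = seed + match(id, grid$model_id))
    dplyr::bind_cols(
      tibble::tibble(model_id = id, n = nrow(sv)),
      ci[c("auc", "ci_low", "ci_high")],
      tibble::tibble(cutoff = cut$threshold),
      confusion_metrics(sv$score, sv$outcome, cut$threshold)
    )
  })
  performance <- dplyr::left_join(
    performance, grid[c("model_id", "n_markers", "family")], by = "model_id"
  )

  ref_scores <- scores[[ref_id]]
  comparisons <- purrr::imap_dfr(
    scores[setdiff(names(scores), ref_id)],
    function(sv, id) {
      common <- intersect(sv$participant_id, ref_scores$participant_id)
      recomputed <- FALSE
      a <- sv[match(common, sv$participant_id), ]
      if (length(common) == nrow(sv) && length(common) == nrow(ref_scores)) {
        b <- ref_scores[match(common, ref_scores$participant_id), ]
      } else {
        recomputed <- TRUE
        keep <- cohort$participant_id %in% common
        sub <- cohort[keep, ]
        attr(sub, "marker_names") <- marker_names(cohort)
        class(sub) <- class(cohort)
        b <- score_model(grid$members[[match(ref_id, grid$model_id)]], sub)
        if (length(common) < nrow(sv)) {
          a <- score_model(grid$members[[match(id, grid$model_id)]], sub)
        }
        b <- b[match(common, b$participant_id), ]
        a <- a[match(common, a$participant_id), ]
      }
      dplyr::bind_cols(
        tibble::tibble(model_id = id, n_common = length(common),
                       recomputed = recomputed),
        delong_paired_test(a$score, b$score, a$outcome)
      )
    })
  q <- qvalues(comparisons$p_value, pi0_method = pi0_method)
  comparisons$q_value <- as.numeric(q)
  comparisons$significant <- significance_call(comparisons$q_value)

  structure(
    list(performance = performance,
         comparisons = comparisons,
         reference = ref_id,
         manifest = list(
           n = nrow(cohort), n_progressors = sum(cohort$outcome),
           n_models = nrow(grid), reference = ref_id,
           repetitions = cv$repetitions, outer_folds = cv$outer_folds,
           inner_folds = cv$inner_folds,
           lambda_grid = range(cv$lambda_grid),
           ci_method = ci_method, boot_replicates = boot_replicates,
           pi0_method = pi0_method, pi0 = attr(q, "pi0"),
           rounding = "round-half-even to 2 decimals, q < 0.05",
           seed = seed
         )),
    class = "ogtt_benchmark"
  )
}

#' @export
print.ogtt_benchmark <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "OGTT model benchmark: %d models on %d participants (%d progressors)\n",
    m$n_models, m$n, m$n_progressors))
  cat(sprintf("reference: %s | repetitions: %d | pi0: %.3f\n",
              x$reference, m$repetitions, m$pi0))
  cat(sprintf("%d of %d comparisons significant after rounding rule\n",
              sum(x$comparisons$significant), nrow(x$comparisons)))
  invisible(x)
}

#' Tidy and summarize a benchmark
#'
#' `tidy()` returns one row per model: performance joined with the DeLong
#' comparison against the reference (the reference row has `NA` comparison
#' columns). `glance()` returns a one-row run summary.
#'
#' @param x An `ogtt_benchmark`.
#' @param ... Unused.
#' @method tidy ogtt_benchmark
#' @export
tidy.ogtt_benchmark <- function(x, ...) {
  dplyr::left_join(
    x$performance,
    x$comparisons[c("model_id", "delta_auc", "z", "p_value",
                    "q_value", "significant", "n_common")],
    by = "model_id"
  ) |>
    dplyr::arrange(dplyr::desc(.data$auc))
}

#' @rdname tidy.ogtt_benchmark
#' @method glance ogtt_benchmark
#' @export
glance.ogtt_benchmark <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$performance),
    n_comparisons = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant),
    best_model = x$performance$model_id[which.max(x$performance$auc)],
    best_auc = max(x$performance$auc),
    reference_auc = x$performance$auc[
      x$performance$model_id == x$reference],
    pi0 = x$manifest$pi0
  )
}

#' Benchmark each baseline glycemic stratum separately
#'
#' Reruns the identical pipeline within the IFG/IGT stratum (participants
#' with impaired fasting glucose or impaired glucose tolerance at baseline)
#' and the IFG/IGT-free stratum. Stratified reruns are reported with raw
#' DeLong p-values (the q-value machinery is still run per stratum, but the
#' stratified analyses are conventionally read on p).
#'
#' @inheritParams run_benchmark
#' @return An `ogtt_stratified` list with one `ogtt_benchmark` per stratum.
#' @export
run_stratified <- function(cohort, grid = default_model_grid(),
                           cv = cv_config(), reference = "PG60",
                           ci_method = "analytic",
                           boot_replicates = 2000L,
                           pi0_method = "storey", seed = 1L) {
  if (!"status" %in% names(cohort)) {
    rlang::abort("cohort has no baseline `status` column.")
  }
  strata <- list(
    ifg_igt = cohort$status %in% c("IFG", "IGT"),
    ifg_igt_free = cohort$status == "NORMAL"
  )
  out <- purrr::imap(strata, function(keep, nm) {
    sub <- cohort[keep, ]
    attr(sub, "marker_names") <- marker_names(cohort)
    class(sub) <- class(cohort)
    if (length(unique(sub$outcome)) < 2L) {
      rlang::abort(paste0("stratum `", nm, "` has a single outcome class."))
    }
    run_benchmark(sub, grid = grid, cv = cv, reference = reference,
                  ci_method = ci_method, boot_replicates = boot_replicates,
                  pi0_method = pi0_method, seed = seed)
  })
  structure(out, class = "ogtt_stratified")
}

#' @export
print.ogtt_stratified <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
  }
  invisible(x)
}
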