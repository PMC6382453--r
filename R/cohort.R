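#' Cohort container
#'
#' A cohort is a tibble with one row per participant carrying an opaque
#' `participant_id`, a binary `outcome` (1 = progressor to type 2 diabetes
#' during follow-up), a baseline glycemic `status` (NORMAL/IFG/IGT) and one
#' numeric column per marker. Missing marker measurements are `NA`; the
#' missingness mask of the original specification is therefore `is.na()` on
#' the marker columns. Marker names are stored in the `"marker_names"`
#' attribute and the tibble carries class `ogtt_cohort`.
#'
#' @param data A data frame with `participant_id`, `outcome` and marker
#'   columns; a `status` column is recomputed from PG0/PG120 when absent and
#'   both glucose columns are present.
#' @param marker_names Character vector naming the marker columns. Defaults
#'   to every column other than `participant_id`, `outcome`, `status`.
#' @return An `ogtt_cohort` tibble.
#' @export
as_cohort <- function(data, marker_names = NULL) {
  data <- tibble::as_tibble(data)
  if (!"outcome" %in% names(data)) {
    rlang::abort("cohort data must contain an `outcome` column.")
  }
  if (!"participant_id" %in% names(data)) {
    data$participant_id <- sprintf("P%04d", seq_len(nrow(data)))
  }
  data$participant_id <- as.character(data$participant_id)
  if (anyDuplicated(data$participant_id)) {
    rlang::abort("duplicate participant ids.")
  }
  lev <- sort(unique(data$outcome[!is.na(data$outcome)]))
  if (length(lev) != 2L || !all(lev %in% c(0, 1))) {
    rlang::abort(
      "`outcome` must be binary 0/1 with both levels present."
    )
  }
  data$outcome <- as.integer(data$outcome)
  if (is.null(marker_names)) {
    marker_names <- setdiff(names(data), c("participant_id", "outcome", "status"))
  }
  missing_cols <- setdiff(marker_names, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0("marker columns not found: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(marker_names)) rlang::abort("marker names must be unique.")
  for (m in marker_names) {
    if (!is.numeric(data[[m]])) {
      rlang::abort(paste0("marker column `", m, "` must be numeric."))
    }
  }
  pg <- intersect(pg_markers(), marker_names)
  for (m in pg) {
    if (any(data[[m]] < 0, na.rm = TRUE)) {
      rlang::abort(paste0("glucose column `", m, "` must be nonnegative."))
    }
  }
  if (!"status" %in% names(data) &&
      all(c("PG0", "PG120") %in% marker_names)) {
    ok <- stats::complete.cases(data[c("PG0", "PG120")])
    st <- rep(NA_character_, nrow(data))
    st[ok] <- as.character(classify_glycemic_status(data$PG0[ok], data$PG120[ok]))
    data$status <- factor(st, levels = c("NORMAL", "IFG", "IGT", "T2D"))
  }
  front <- intersect(c("participant_id", "outcome", "status"), names(data))
  data <- data[c(front, marker_names)]
  attr(data, "marker_names") <- marker_names
  class(data) <- unique(c("ogtt_cohort", class(data)))
  data
}

#' @rdname as_cohort
#' @param x An object.
#' @export
marker_names <- function(x) attr(x, "marker_names")

#' Read a delimited cohort table
#'
#' Reads a comma- or tab-delimited per-participant marker table (header row
#' required; delimiter sniffed from the header line). Empty cells and the
#' literal strings `NA` are treated as missing. Column roles can be remapped
#' through `schema`, a named character vector `c(canonical = "file_column")`
#' covering at least `outcome` when the file uses different header names.
#'
#' @param path Path to a CSV/TSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (see [marker_order()], plus `participant_id`, `outcome`) to the
#'   file's header names.
#' @return An [as_cohort()] tibble.
#' @export
load_cohort <- function(path, schema = NULL) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      rlang::abort("`schema` must be a fully named character vector.")
    }
    missing_cols <- setdiff(unname(schema), names(raw))
    if (length(missing_cols)) {
      rlang::abort(paste0("schema refers to absent columns: ",
                          paste(missing_cols, collapse = ", ")))
    }
    idx <- match(unname(schema), names(raw))
    names(raw)[idx] <- names(schema)
  }
  if (!"outcome" %in% names(raw)) {
    rlang::abort("no `outcome` column after schema mapping.")
  }
  as_cohort(raw)
}

#' Write a cohort to the same delimited format `load_cohort()` reads
#'
#' @param cohort An `ogtt_cohort`.
#' @param path Output path; `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(tibble::as_tibble(unclass_cohort(cohort)), path,
                     delim = delim, na = "NA")
  invisible(path)
}

unclass_cohort <- function(cohort) {
  class(cohort) <- setdiff(class(cohort), "ogtt_cohort")
  cohort
}

#' Standardize a numeric vector to zero mean and unit variance
#'
#' Missing entries are ignored when estimating the location and scale and are
#' left untouched in the output, mirroring per-metabolite standardization of
#' an abundance column that still carries missing cells.
#'
#' @param x Numeric vector, at least two nonmissing values with nonzero
#'   variance.
#' @return Numeric vector of the same length.
#' @export
standardize <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2L) rlang::abort("need >= 2 nonmissing values.")
  s <- stats::sd(obs)
  if (!is.finite(s) || s == 0) {
    rlang::abort("cannot standardize a constant vector.")
  }
  (x - mean(obs)) / s
}

#' Impute missing values with the minimum nonmissing measurement
#'
#' The minimum-imputation rule used for metabolite abundances: every missing
#' cell of a column is replaced by the smallest observed value of that
#' column (missingness in untargeted metabolomics is largely
#' below-detection-limit, so the minimum is the natural fill-in).
#'
#' @param x Numeric vector with at least one nonmissing value.
#' @return Numeric vector with no missing entries.
#' @export
impute_min <- function(x) {
  if (all(is.na(x))) rlang::abort("cannot impute an all-missing vector.")
  x[is.na(x)] <- min(x, na.rm = TRUE)
  x
}

#' Impute metabolite columns of a cohort by column minimum
#'
#' Applies [impute_min()] to every metabolite column present in the cohort,
#' leaving clinical, glucose, insulin and HbA1c columns untouched (those are
#' handled by per-model complete-case exclusion instead; the two missingness
#' policies are deliberately split by variable class).
#'
#' @param cohort An `ogtt_cohort`.
#' @param vars Columns to impute; defaults to [metabolite_markers()].
#' @return The cohort with the selected columns imputed.
#' @export
impute_metabolites <- function(cohort, vars = metabolite_markers()) {
  vars <- intersect(vars, marker_names(cohort))
  for (m in vars) cohort[[m]] <- impute_min(cohort[[m]])
  cohort
}

#' Restrict a cohort to complete cases for a variable set
#'
#' Drops every participant with a missing measurement in any of `vars`
#' (per-variable-set exclusion). Errors if the restriction loses an outcome
#' level, since no two-class analysis is then possible.
#'
#' @param cohort An `ogtt_cohort`.
#' @param vars Character vector of marker names (subset of
#'   `marker_names(cohort)`).
#' @return The row subset, still an `ogtt_cohort`.
#' @export
complete_cases <- function(cohort, vars) {
  bad <- setdiff(vars, marker_names(cohort))
  if (length(bad)) {
    rlang::abort(paste0("unknown markers: ", paste(bad, collapse = ", ")))
  }
  keep <- stats::complete.cases(as.data.frame(cohort[vars]))
  out <- cohort[keep, ]
  if (length(unique(out$outcome)) < 2L) {
    rlang::abort("complete-case restriction lost an outcome level.")
  }
  attr(out, "marker_names") <- marker_names(cohort)
  class(out) <- unique(c("ogtt_cohort", class(out)))
  out
}

#' Baseline cohort description table
#'
#' Per-marker association with the progression outcome: the Fisher exact test
#' for binary markers (sex, family history) and the Welch t test for
#' continuous markers, each computed on that marker's nonmissing rows.
#'
#' @param cohort An `ogtt_cohort`.
#' @return A tibble with marker, test used, group summaries and p-value.
#' @export
cohort_summary <- function(cohort) {
  purrr::map_dfr(marker_names(cohort), function(m) {
    x <- cohort[[m]]
    ok <- !is.na(x)
    x <- x[ok]
    y <- cohort$outcome[ok]
    binary <- all(x %in% c(0, 1))
    if (binary) {
      tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
      p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        fisher_exact(tab)
      } else NA_real_
      tibble::tibble(
        marker = m, test = "fisher", n = length(x),
        progressor = mean(x[y == 1]), nonprogressor = mean(x[y == 0]),
        p_value = p
      )
    } else {
      wt <- welch_t(x[y == 1], x[y == 0])
      tibble::tibble(
        marker = m, test = "welch", n = length(x),
        progressor = mean(x[y == 1]), nonprogressor = mean(x[y == 0]),
        p_value = wt$p_value
      )
    }
  })
}
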