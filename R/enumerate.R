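#' Combinatorial unit pools
#'
#' A pool is a set of combinatorial units from which a model family draws
#' between `min` and `max` units. A unit is either a single marker or a named
#' block of markers that always enters together — the four clinical risk
#' factors (age, sex, BMI, family history) form one such atomic block, which
#' is why e.g. "all combinations of 1-h PG, >= 1 of 6 metabolites, optional
#' HbA1c and optional clinical factors" counts (2^6 - 1) * 2 * 2 = 252
#' models rather than thousands.
#'
#' @param units Either a character vector (each element one single-marker
#'   unit) or a named list of character vectors (blocks).
#' @param min,max Minimum/maximum number of units drawn from this pool.
#' @return A `unit_pool` list.
#' @export
pool <- function(units, min = 0L, max = Inf) {
  if (is.character(units)) units <- stats::setNames(as.list(units), units)
  if (!length(units) || is.null(names(units)) || any(names(units) == "")) {
    rlang::abort("`units` must be non-empty and fully named.")
  }
  if (anyDuplicated(names(units))) rlang::abort("duplicate unit names.")
  max <- min(max, length(units))
  if (min > max) rlang::abort("unsatisfiable pool constraint (min > max).")
  structure(list(units = units, min = as.integer(min), max = as.integer(max)),
            class = "unit_pool")
}

#' Define a family of candidate variable sets
#'
#' @param name Family label carried through as provenance.
#' @param base Marker names included in every model of the family.
#' @param pools List of [pool()]s; the family enumerates every way of
#'   drawing the allowed number of units from each pool.
#' @return A `model_family` object.
#' @export
model_family <- function(name, base = character(), pools = list()) {
  if (!length(base) && !length(pools)) {
    rlang::abort("a family needs a base or at least one pool.")
  }
  if (length(pools) && !all(purrr::map_lgl(pools, inherits, "unit_pool"))) {
    rlang::abort("`pools` must be a list of pool() objects.")
  }
  structure(list(name = name, base = base, pools = pools),
            class = "model_family")
}

#' Closed-form size of a family
#'
#' Product over pools of the number of admissible unit subsets.
#'
#' @param family A [model_family()].
#' @return Integer count.
#' @export
family_count <- function(family) {
  if (!length(family$pools)) return(1L)
  prod(purrr::map_dbl(family$pools, function(p) {
    sum(choose(length(p$units), seq(p$min, p$max)))
  }))
}

canonical_members <- function(members) {
  members <- unique(members)
  members[order(match(members, marker_order(), nomatch = 10000L), members)]
}

model_id_of <- function(members) paste(canonical_members(members), collapse = "+")

#' Enumerate every variable set of a family
#'
#' Exact (non-sampled) enumeration: for each pool, all unit subsets of
#' admissible size; the family's models are the Cartesian product of those
#' choices unioned with the base markers. Sets are deduplicated within the
#' family after expanding blocks to markers and canonically ordered so set
#' equality is well defined.
#'
#' @param family A [model_family()].
#' @return Tibble with `model_id`, `members` (list column of marker names),
#'   `n_markers`, `family`.
#' @export
enumerate_family <- function(family) {
  stopifnot(inherits(family, "model_family"))
  pool_subsets <- purrr::map(family$pools, function(p) {
    ks <- seq(p$min, p$max)
    purrr::flatten(purrr::map(ks, function(k) {
      if (k == 0L) return(list(character()))
      utils::combn(names(p$units), k, simplify = FALSE)
    }))
  })
  choices <- if (length(pool_subsets)) {
    purrr::reduce(pool_subsets, function(acc, subs) {
      purrr::flatten(purrr::map(acc, function(a) {
        purrr::map(subs, function(s) c(a, s))
      }))
    }, .init = list(character()))
  } else list(character())
  unit_members <- purrr::flatten(purrr::map(family$pools, "units"))
  sets <- purrr::map(choices, function(unit_names) {
    canonical_members(c(family$base,
                        unlist(unit_members[unit_names], use.names = FALSE)))
  })
  out <- tibble::tibble(
    model_id = purrr::map_chr(sets, model_id_of),
    members = sets,
    n_markers = lengths(sets),
    family = family$name
  )
  out <- dplyr::distinct(out, .data$model_id, .keep_all = TRUE)
  if (any(out$n_markers == 0L)) {
    rlang::abort("family enumerates an empty variable set.")
  }
  out
}

#' Enumerate and deduplicate a grid of families
#'
#' Union of the family enumerations; a set produced by several families
#' appears once, with all contributing families recorded in `family`
#' (comma separated). Output order is deterministic (first appearance).
#'
#' @param families List of [model_family()] objects.
#' @return Tibble as in [enumerate_family()] plus the merged provenance.
#' @export
enumerate_grid <- function(families) {
  if (!length(families)) rlang::abort("need at least one family.")
  all <- purrr::map_dfr(families, enumerate_family)
  all |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(
      members = .data$members[1],
      n_markers = .data$n_markers[1],
      family = paste(unique(.data$family), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$model_id, unique(all$model_id)))
}

#' The default benchmarking grid
#'
#' The families of candidate models the benchmark evaluates: OGTT glucose
#' combinations; glucose plus the clinical block; the clinical block alone;
#' HbA1c with optional glucose and clinical factors; metabolite subsets with
#' and without clinical factors and HbA1c; each single glucose time point
#' crossed with metabolite subsets, optional HbA1c and optional clinical
#' factors; and insulin singles/pairs with and without clinical factors.
#' The grid is configuration, not a hard-coded list: the returned families
#' can be filtered, extended or replaced before [enumerate_grid()].
#'
#' @return Named list of [model_family()] objects.
#' @export
default_model_grid <- function() {
  met <- pool(metabolite_markers(), min = 1)
  opt_hba1c_clin <- pool(list(hba1c = "hba1c", clinical = clinical_block()))
  fams <- list(
    model_family("pg", pools = list(pool(pg_markers(), min = 1))),
    model_family("pg_clinical", base = clinical_block(),
                 pools = list(pool(pg_markers(), min = 1))),
    model_family("clinical", base = clinical_block()),
    model_family("hba1c", base = "hba1c",
                 pools = list(pool(pg_markers()),
                              pool(list(clinical = clinical_block())))),
    model_family("metabolites", pools = list(met)),
    model_family("metabolites_clinical", base = clinical_block(),
                 pools = list(met)),
    model_family("metabolites_hba1c_clinical",
                 pools = list(met, opt_hba1c_clin)),
    model_family("fpg_metabolites", base = "PG0",
                 pools = list(met, opt_hba1c_clin)),
    model_family("pg30_metabolites", base = "PG30",
                 pools = list(met, opt_hba1c_clin)),
    model_family("pg60_metabolites", base = "PG60",
                 pools = list(met, opt_hba1c_clin)),
    model_family("pg120_metabolites", base = "PG120",
                 pools = list(met, opt_hba1c_clin)),
    model_family("insulin", pools = list(pool(insulin_markers(),
                                              min = 1, max = 2))),
    model_family("insulin_clinical", base = clinical_block(),
                 pools = list(pool(insulin_markers(), min = 1, max = 2)))
  )
  stats::setNames(fams, purrr::map_chr(fams, "name"))
}
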