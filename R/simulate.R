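#' Theoretical AUC of a binormal marker
#'
#' For a marker whose within-class distributions are normal with common unit
#' variance and standardized mean shift `delta` between progressors and
#' non-progressors, the area under the ROC curve is `pnorm(delta / sqrt(2))`.
#'
#' @param delta Standardized mean shift (finite).
#' @return AUC in (0, 1), strictly increasing in `delta`.
#' @export
binormal_auc <- function(delta) {
  if (any(!is.finite(delta))) rlang::abort("`delta` must be finite.")
  stats::pnorm(delta / sqrt(2))
}

#' Mean shift achieving a target binormal AUC
#'
#' Inverse of [binormal_auc()]: the standardized shift a marker needs so that
#' its single-marker AUC equals `target_auc` under the equal-variance
#' binormal model.
#'
#' @param target_auc AUC in the open interval (0.5, 1).
#' @return The shift `delta` with `binormal_auc(delta) == target_auc`.
#' @export
calibrate_effect <- function(target_auc) {
  if (any(!is.finite(target_auc)) ||
      any(target_auc <= 0.5) || any(target_auc >= 1)) {
    rlang::abort("`target_auc` must lie in (0.5, 1).")
  }
  sqrt(2) * stats::qnorm(target_auc)
}

#' Default single-marker discrimination targets
#'
#' Target AUC (and effect direction) for each marker, used to calibrate the
#' generator's class-conditional mean shifts. Glucose, HbA1c and mannose
#' targets follow the reported single-marker performance levels of the
#' emulated cohort (1-h PG strongest at 0.75, then 30-min PG 0.71, mannose
#' 0.70, 2-h PG 0.68, HbA1c 0.67, FPG 0.63); the remaining metabolite,
#' insulin and clinical targets are plausible values below the 1-h PG level,
#' chosen once and documented as assumptions. Bradykinin-hydroxyproline acts
#' protectively (negative shift); sex carries no marginal effect.
#'
#' @return Named numeric vector of signed standardized mean shifts.
#' @export
default_effects <- function() {
  auc <- c(PG0 = 0.63, PG30 = 0.71, PG60 = 0.75, PG120 = 0.68,
           INS0 = 0.60, INS30 = 0.62, INS60 = 0.63, INS120 = 0.61,
           hba1c = 0.67, age = 0.58, bmi = 0.62, fh = 0.57,
           mannose = 0.70, AHB = 0.66, hyp3_bk = 0.62,
           a_tocopherol = 0.60, carnitine_10_1 = 0.62, x_12063 = 0.64)
  sign <- rep(1, length(auc))
  names(sign) <- names(auc)
  sign["hyp3_bk"] <- -1
  delta <- sign * calibrate_effect(auc)
  out <- c(delta, sex = 0)
  out[marker_order()]
}

#' Default pairwise correlation targets
#'
#' Target Pearson correlation matrix for the generated (observed-scale)
#' markers. The metabolite-glucose entries are the reported values of the
#' emulated cohort (e.g. mannose with FPG 0.30, with 30-min PG 0.32, with
#' 1-h PG 0.26, with 2-h PG 0.14; AHB with 1-h PG 0.37; bradykinin-
#' hydroxyproline with 1-h PG -0.25; X-12063 with 2-h PG 0.35; HbA1c with
#' mannose and X-12063 0.16). Adjacent OGTT time points correlate more
#' strongly than distant ones, with the 30-min/1-h pair strongest. Entries
#' not reported (notably insulin correlations) are stated assumptions at
#' modest positive values; sex and family history are uncorrelated with
#' everything.
#'
#' @return Symmetric unit-diagonal matrix over [marker_order()].
#' @export
default_corr_targets <- function() {
  mk <- marker_order()
  k <- length(mk)
  R <- matrix(0.05, k, k, dimnames = list(mk, mk))
  diag(R) <- 1
  set <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  # OGTT glucose block: adjacent time points more correlated, 30/60 highest
  set("PG0", "PG30", 0.55); set("PG0", "PG60", 0.45); set("PG0", "PG120", 0.35)
  set("PG30", "PG60", 0.68); set("PG30", "PG120", 0.45)
  set("PG60", "PG120", 0.60)
  # insulin block (assumed, analogous shape)
  set("INS0", "INS30", 0.50); set("INS0", "INS60", 0.45)
  set("INS0", "INS120", 0.40); set("INS30", "INS60", 0.65)
  set("INS30", "INS120", 0.50); set("INS60", "INS120", 0.60)
  for (g in pg_markers()) for (i in insulin_markers()) set(i, g, 0.25)
  set("INS0", "PG0", 0.30); set("INS120", "PG120", 0.35)
  # HbA1c: stronger with post-load glucose than fasting
  set("hba1c", "PG0", 0.25); set("hba1c", "PG30", 0.30)
  set("hba1c", "PG60", 0.32); set("hba1c", "PG120", 0.30)
  for (i in insulin_markers()) set("hba1c", i, 0.15)
  set("hba1c", "age", 0.20); set("hba1c", "bmi", 0.15)
  # metabolite-glucose targets
  set("mannose", "PG0", 0.30); set("mannose", "PG30", 0.32)
  set("mannose", "PG60", 0.26); set("mannose", "PG120", 0.14)
  set("AHB", "PG0", 0.08); set("AHB", "PG30", 0.25)
  set("AHB", "PG60", 0.37); set("AHB", "PG120", 0.25)
  set("hyp3_bk", "PG0", -0.05); set("hyp3_bk", "PG30", -0.18)
  set("hyp3_bk", "PG60", -0.25); set("hyp3_bk", "PG120", -0.15)
  set("x_12063", "PG0", 0.10); set("x_12063", "PG30", 0.20)
  set("x_12063", "PG60", 0.25); set("x_12063", "PG120", 0.35)
  for (g in pg_markers()) {
    set("a_tocopherol", g, 0.03)
    set("carnitine_10_1", g, 0.03)
  }
  # metabolite-HbA1c and metabolite-metabolite
  met <- metabolite_markers()
  for (m in met) set("hba1c", m, 0.08)
  set("hba1c", "mannose", 0.16); set("hba1c", "x_12063", 0.16)
  for (a in met) for (b in met) if (a < b) {
    r <- if (any(c(a, b) %in% c("a_tocopherol", "carnitine_10_1"))) 0.05 else 0.15
    set(a, b, r)
  }
  for (m in met) for (i in insulin_markers()) set(m, i, 0.10)
  # clinical
  set("age", "bmi", 0.10)
  for (g in pg_markers()) { set("age", g, 0.15); set("bmi", g, 0.20) }
  for (i in insulin_markers()) { set("age", i, 0.05); set("bmi", i, 0.30) }
  for (m in met) set("age", m, 0.05)
  set("bmi", "mannose", 0.20); set("bmi", "AHB", 0.20)
  R["sex", ] <- 0; R[, "sex"] <- 0
  R["fh", ] <- 0; R[, "fh"] <- 0
  diag(R) <- 1
  R
}

#' Default marginal location and scale of the continuous markers
#'
#' Means and SDs used to map latent standardized values onto measurement
#' scales: plasma glucose in mmol/L (chosen so that roughly 16% of a
#' generated baseline cohort falls in the IFG stratum and 21% in IGT),
#' insulin in pmol/L, HbA1c in %, age in years, BMI in kg/m^2. Metabolites
#' stay on their standardized (zero-mean, unit-variance) abundance scale.
#'
#' @return Tibble with `marker`, `mean`, `sd`.
#' @export
default_location_scale <- function() {
  tibble::tribble(
    ~marker, ~mean, ~sd,
    "PG0",    5.72,  0.55,
    "PG30",   8.60,  1.70,
    "PG60",   8.40,  2.10,
    "PG120",  6.45,  1.70,
    "INS0",     60,    35,
    "INS30",   350,   180,
    "INS60",   320,   180,
    "INS120",  260,   160,
    "hba1c",  5.60,  0.50,
    "age",      50,    10,
    "bmi",    26.5,   4.0,
    "mannose", 0, 1, "AHB", 0, 1, "hyp3_bk", 0, 1,
    "a_tocopherol", 0, 1, "carnitine_10_1", 0, 1, "x_12063", 0, 1
  )
}

#' Simulation configuration
#'
#' Bundles everything [generate_cohort()] needs: cohort size and progressor
#' count (543 with 146 progressors by default, the structure of the emulated
#' prospective subcohort), the target observed-scale correlation matrix, the
#' signed class mean shifts, marginal location/scale maps, binary-marker
#' prevalences (sex 0.50, family history 0.45, assumptions), per-marker
#' completely-at-random missingness rates, and the seed.
#'
#' @param n Number of participants.
#' @param n_progressors Number with outcome 1 (exact, stratified generation).
#' @param corr Target correlation matrix over `markers` (symmetric, unit
#'   diagonal; indefinite inputs are repaired by eigenvalue clipping with a
#'   message).
#' @param effects Named signed standardized mean shifts per marker.
#' @param location_scale Tibble of marker/mean/sd for continuous markers.
#' @param binary_prevalence Named vector of overall prevalences for binary
#'   markers (dichotomized from the latent scale at the matching empirical
#'   quantile).
#' @param missing_rate Named per-marker missingness probabilities in \[0, 1);
#'   unnamed markers get 0. Defaults: 0.02 for metabolites, 0.01 for insulin
#'   and HbA1c, 0 elsewhere.
#' @param seed Integer seed; every draw in [generate_cohort()] flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 543L,
                       n_progressors = 146L,
                       corr = default_corr_targets(),
                       effects = default_effects(),
                       location_scale = default_location_scale(),
                       binary_prevalence = c(sex = 0.50, fh = 0.45),
                       missing_rate = NULL,
                       seed = 1L) {
  markers <- rownames(corr)
  if (is.null(markers) || !identical(rownames(corr), colnames(corr))) {
    rlang::abort("`corr` must have matching row/column marker names.")
  }
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)) ||
      any(abs(diag(corr) - 1) > 1e-8)) {
    rlang::abort("`corr` must be symmetric with unit diagonal.")
  }
  if (n_progressors <= 0 || n_progressors >= n) {
    rlang::abort("need 0 < n_progressors < n.")
  }
  if (!all(markers %in% names(effects))) {
    rlang::abort("`effects` must name every marker in `corr`.")
  }
  mr <- stats::setNames(rep(0, length(markers)), markers)
  if (is.null(missing_rate)) {
    mr[intersect(metabolite_markers(), markers)] <- 0.02
    mr[intersect(c(insulin_markers(), "hba1c"), markers)] <- 0.01
  } else {
    if (is.null(names(missing_rate))) {
      rlang::abort("`missing_rate` must be a named vector.")
    }
    mr[names(missing_rate)] <- missing_rate
  }
  if (any(mr < 0 | mr >= 1)) rlang::abort("missing rates must be in [0, 1).")
  structure(
    list(n = as.integer(n), n_progressors = as.integer(n_progressors),
         markers = markers, corr = corr,
         effects = effects[markers],
         location_scale = location_scale,
         binary_prevalence = binary_prevalence,
         missing_rate = mr, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Residual (within-class) covariance implied by the observed-scale
# correlation targets and the class mean shifts. With prevalence p and shift
# vector d, the observed mixture has Var_i = 1 + p(1-p) d_i^2 and
# Cov_ij = p(1-p) d_i d_j + S_ij, so the residual S that reproduces target
# correlation t_ij is t_ij * sd_i * sd_j - p(1-p) d_i d_j with unit diagonal.
residual_covariance <- function(corr, effects, prev) {
  v <- prev * (1 - prev)
  sds <- sqrt(1 + v * effects^2)
  S <- corr * outer(sds, sds) - v * outer(effects, effects)
  diag(S) <- 1
  S
}

# Symmetric square root with eigenvalue clipping; messages when repair is
# needed so an indefinite user-supplied target is never silently accepted.
cov_sqrt <- function(S, label = "residual covariance") {
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < -1e-8) {
    message(sprintf(
      "%s is indefinite (min eigenvalue %.3g); repaired by eigenvalue clipping.",
      label, min(es$values)))
  }
  vals <- pmax(es$values, 1e-10)
  es$vectors %*% (sqrt(vals) * t(es$vectors))
}

#' Generate a synthetic baseline cohort
#'
#' Draws a cohort from a latent-Gaussian model: a fixed number of progressors
#' is assigned at random; each marker's latent value is a class-centred mean
#' shift plus correlated Gaussian noise whose covariance is chosen so the
#' observed mixture reproduces the configured correlation targets while every
#' within-class distribution keeps unit variance (so [binormal_auc()] applies
#' exactly to the configured shifts). Continuous markers are mapped affinely
#' to their measurement scales and truncated at zero where negative values
#' are physically impossible (glucose, insulin); binary markers are
#' dichotomized at the empirical quantile matching their prevalence. Rows
#' whose baseline glucose meets the WHO diabetes criteria are redrawn
#' (rejection), since the emulated cohort is nondiabetic at baseline.
#' Missingness is finally injected completely at random per marker.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return An [as_cohort()] tibble with `n` rows and exactly
#'   `n_progressors` progressors.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  withr::with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n
  mk <- config$markers
  p <- config$n_progressors / n
  d <- config$effects
  S <- residual_covariance(config$corr, d, p)
  A <- cov_sqrt(S)

  outcome <- sample(rep(c(1L, 0L), c(config$n_progressors,
                                     n - config$n_progressors)))
  cshift <- (outcome - p)
  draw_latent <- function(idx) {
    Z <- matrix(stats::rnorm(length(idx) * length(mk)), length(idx))
    L <- Z %*% A + outer(cshift[idx], d)
    colnames(L) <- mk
    L
  }
  latent <- draw_latent(seq_len(n))

  ls <- config$location_scale
  to_observed <- function(L) {
    out <- L
    for (j in seq_along(mk)) {
      m <- mk[j]
      i <- match(m, ls$marker)
      if (!is.na(i)) out[, j] <- ls$mean[i] + ls$sd[i] * L[, j]
    }
    ins <- intersect(insulin_markers(), mk)
    out[, ins] <- pmax(out[, ins, drop = FALSE], 0)
    # glucose floored just above zero so WHO classification stays defined
    pg <- intersect(pg_markers(), mk)
    out[, pg] <- pmax(out[, pg, drop = FALSE], 0.1)
    out
  }
  obs <- to_observed(latent)

  # baseline nondiabetic: redraw rows meeting WHO T2D glucose criteria
  if (all(c("PG0", "PG120") %in% mk)) {
    for (iter in seq_len(100L)) {
      t2d <- which(obs[, "PG0"] >= 7.0 | obs[, "PG120"] >= 11.1)
      if (!length(t2d)) break
      latent[t2d, ] <- draw_latent(t2d)
      obs[t2d, ] <- to_observed(latent[t2d, , drop = FALSE])
    }
    if (length(which(obs[, "PG0"] >= 7.0 | obs[, "PG120"] >= 11.1))) {
      rlang::abort("could not reject baseline-diabetic rows in 100 passes.")
    }
  }

  # binary markers: threshold the latent column at the prevalence quantile
  for (b in intersect(names(config$binary_prevalence), mk)) {
    prev <- config$binary_prevalence[[b]]
    thr <- stats::quantile(latent[, b], 1 - prev, names = FALSE)
    obs[, b] <- as.numeric(latent[, b] >= thr)
  }

  dat <- tibble::as_tibble(as.data.frame(obs))
  for (m in mk) {
    r <- config$missing_rate[[m]]
    if (r > 0) dat[[m]][stats::runif(n) < r] <- NA_real_
  }
  dat$participant_id <- sprintf("S%05d", seq_len(n))
  dat$outcome <- outcome
  as_cohort(dat, marker_names = mk)
}
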