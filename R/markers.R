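#' Marker vocabulary
#'
#' Canonical names for the markers handled by the pipeline: plasma glucose
#' (PG) and serum insulin (INS) at 0, 30, 60 and 120 minutes of a 75-g OGTT,
#' HbA1c, the four clinical risk factors (age, sex, BMI, family history of
#' type 2 diabetes), and the six serum metabolic markers (mannose,
#' alpha-hydroxybutyrate, bradykinin-hydroxyproline, alpha-tocopherol,
#' 10:1 carnitine and the unidentified metabolite X-12063).
#'
#' `marker_order()` gives the canonical column ordering used to make variable
#' sets comparable across enumeration families.
#'
#' @return Character vectors of marker names.
#' @export
pg_markers <- function() c("PG0", "PG30", "PG60", "PG120")

#' @rdname pg_markers
#' @export
insulin_markers <- function() c("INS0", "INS30", "INS60", "INS120")

#' @rdname pg_markers
#' @export
metabolite_markers <- function() {
  c("mannose", "AHB", "hyp3_bk", "a_tocopherol", "carnitine_10_1", "x_12063")
}

#' @rdname pg_markers
#' @export
clinical_block <- function() c("age", "sex", "bmi", "fh")

#' @rdname pg_markers
#' @export
marker_order <- function() {
  c(pg_markers(), insulin_markers(), "hba1c", clinical_block(),
    metabolite_markers())
}

#' WHO glycemic classification from fasting and 2-hour plasma glucose
#'
#' Assigns each participant to exactly one category using the WHO windows:
#' impaired fasting glucose (IFG) when 6.1 <= FPG < 7.0 mmol/L and
#' 2-h PG < 7.8 mmol/L; impaired glucose tolerance (IGT) when FPG < 7.0 mmol/L
#' and 7.8 <= 2-h PG < 11.1 mmol/L; type 2 diabetes (T2D) when FPG >= 7.0 or
#' 2-h PG >= 11.1 mmol/L, taking precedence over both prediabetic windows;
#' NORMAL otherwise. The IFG and IGT windows are disjoint by construction
#' (they split on the 7.8 mmol/L 2-h PG boundary).
#'
#' @param fpg Fasting plasma glucose, mmol/L (positive, finite).
#' @param pg2h 2-hour post-load plasma glucose, mmol/L (positive, finite).
#' @return Factor with levels NORMAL, IFG, IGT, T2D, same length as `fpg`.
#' @examples
#' classify_glycemic_status(c(5.2, 6.5, 6.0, 7.2), c(6.0, 7.0, 8.0, 6.0))
#' @export
classify_glycemic_status <- function(fpg, pg2h) {
  if (length(fpg) != length(pg2h)) {
    rlang::abort("`fpg` and `pg2h` must have the same length.")
  }
  bad <- !is.finite(fpg) | !is.finite(pg2h) | fpg <= 0 | pg2h <= 0
  if (any(bad)) {
    rlang::abort("`fpg` and `pg2h` must be finite and positive.")
  }
  status <- rep("NORMAL", length(fpg))
  status[fpg >= 6.1 & fpg < 7.0 & pg2h < 7.8] <- "IFG"
  status[fpg < 7.0 & pg2h >= 7.8 & pg2h < 11.1] <- "IGT"
  status[fpg >= 7.0 | pg2h >= 11.1] <- "T2D"
  factor(status, levels = c("NORMAL", "IFG", "IGT", "T2D"))
}
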