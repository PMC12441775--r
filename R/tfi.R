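#' Treatment frequency index (TFI)
#'
#' The TFI sums, over all herbicide applications of one field x treatment
#' within a cropping year, the applied dose divided by the registered
#' (authorized) dose of the product.  One full registered dose of one
#' product contributes 1; tank-mix partners each contribute their own
#' dose ratio; follow-up treatments within the year simply add.  An empty
#' record set (untreated control) has TFI 0.
#'
#' @param applied Numeric vector of applied doses (product units per ha),
#'   or a data frame with columns `applied_dose` and `registered_dose`.
#' @param registered Numeric vector of registered doses, same units and
#'   length as `applied`; ignored when `applied` is a data frame.
#' @return Single nonnegative number, dimensionless.
#' @examples
#' compute_tfi(c(1.0, 0.5), c(2.0, 1.0))  # two half-dose products -> 1
#' compute_tfi(numeric(0), numeric(0))    # untreated control -> 0
#' @export
compute_tfi <- function(applied, registered = NULL) {
  if (is.data.frame(applied)) {
    registered <- applied$registered_dose
    applied <- applied$applied_dose
  }
  if (length(applied) != length(registered)) {
    stop("applied and registered doses must have equal length", call. = FALSE)
  }
  if (length(applied) == 0L) return(0)
  bad <- which(!is.finite(applied) | !is.finite(registered) |
                 applied <= 0 | registered <= 0)
  if (length(bad)) {
    stop("nonpositive or missing dose in application record(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  over <- which(applied > registered)
  if (length(over)) {
    warning("applied dose exceeds registered dose in record(s) ",
            paste(over, collapse = ", "),
            " (products are authorized up to the registered dose)",
            call. = FALSE)
  }
  sum(applied / registered)
}

#' Per-field, per-treatment TFI table from application records
#'
#' @param applications Data frame with columns `field`, `treatment`,
#'   `applied_dose`, `registered_dose` (one row per product application).
#'   Field x treatment combinations absent from the table get TFI 0 only
#'   if listed in `complete`.
#' @param complete Optional data frame of `field`, `treatment`
#'   combinations to complete with TFI 0 (e.g. untreated plots).
#' @return Tibble (`field`, `treatment`, `tfi`).
#' @export
tfi_table <- function(applications, complete = NULL) {
  need <- c("field", "treatment", "applied_dose", "registered_dose")
  if (!all(need %in% names(applications))) {
    stop("applications table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- applications |>
    dplyr::group_by(.data$field, .data$treatment) |>
    dplyr::summarise(
      tfi = compute_tfi(.data$applied_dose, .data$registered_dose),
      .groups = "drop")
  if (!is.null(complete)) {
    out <- dplyr::bind_rows(
      out,
      dplyr::anti_join(
        dplyr::distinct(complete[, c("field", "treatment")]),
        out, by = c("field", "treatment")) |>
        dplyr::mutate(tfi = 0))
    out <- dplyr::arrange(out, .data$field, .data$treatment)
  }
  tibble::as_tibble(out)
}

#' Round half away from zero
#'
#' Report-style rounding: 0.5 rounds up in magnitude (base `round()`
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Relative biomass of a treated plot group, percent of untreated
#'
#' `100 * treated / untreated`.  In report mode the result is rounded
#' half-away-from-zero to a whole percent, the convention used in summary
#' tables of treated-vs-control biomass.
#'
#' @param treated Mean dry biomass of the treated group (g m^-2), >= 0.
#' @param untreated Mean dry biomass of the untreated control, > 0.
#' @param report If `TRUE` (default) round to integer percent; otherwise
#'   return full precision.
#' @return Percentage (vectorized over `treated`/`untreated`).
#' @examples
#' relative_biomass(16.3, 159.1)        # 10
#' relative_biomass(0.30, 0.42)         # 71
#' relative_biomass(16.3, 159.1, report = FALSE)
#' @export
relative_biomass <- function(treated, untreated, report = TRUE) {
  if (any(!is.finite(untreated)) || any(untreated <= 0)) {
    stop("untreated mean biomass must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(treated)) || any(treated < 0)) {
    stop("treated mean biomass must be nonnegative", call. = FALSE)
  }
  pct <- 100 * treated / untreated
  if (report) round_half_up(pct) else pct
}
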