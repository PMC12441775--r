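#' Validate trial tables
#'
#' Schema and plausibility checks for the three trial tables before
#' analysis: required columns, nonnegative quantities, positive doses,
#' applied dose not exceeding the registered dose (warning only:
#' products are authorized up to the registered dose), and completeness
#' of the field x treatment biomass layout.
#'
#' @param tables List with any of `autumn_survey` (field, block,
#'   species, count), `applications` (field, treatment, product,
#'   applied_dose, registered_dose), `summer_biomass` (field, treatment,
#'   species, biomass).
#' @return List with `ok` (no errors) and `report` (tibble `severity`,
#'   `table`, `row`, `message`).
#' @export
validate_tables <- function(tables) {
  rep_rows <- list()
  note <- function(severity, table, row, message) {
    rep_rows[[length(rep_rows) + 1L]] <<- tibble::tibble(
      severity = severity, table = table, row = row, message = message)
  }
  check_cols <- function(df, need, name) {
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      note("error", name, NA_integer_,
           paste("missing column(s):", paste(miss, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }
  check_filled <- function(df, col, name) {
    bad <- which(is.na(df[[col]]) |
                   (is.character(df[[col]]) & df[[col]] == ""))
    for (r in bad) note("error", name, r, paste("empty", col))
    length(bad) == 0L
  }
  if (!is.null(tables$autumn_survey)) {
    df <- tables$autumn_survey
    if (check_cols(df, c("field", "block", "species", "count"),
                   "autumn_survey")) {
      bad <- which(!is.finite(df$count) | df$count < 0)
      for (r in bad) note("error", "autumn_survey", r, "negative count")
      check_filled(df, "species", "autumn_survey")
    }
  }
  if (!is.null(tables$applications)) {
    df <- tables$applications
    if (check_cols(df, c("field", "treatment", "product",
                         "applied_dose", "registered_dose"),
                   "applications")) {
      check_filled(df, "treatment", "applications")
      bad <- which(!is.finite(df$applied_dose) | df$applied_dose <= 0 |
                     !is.finite(df$registered_dose) |
                     df$registered_dose <= 0)
      for (r in bad) note("error", "applications", r, "nonpositive dose")
      over <- setdiff(which(df$applied_dose > df$registered_dose), bad)
      for (r in over) {
        note("warning", "applications", r,
             "applied dose exceeds registered dose")
      }
    }
  }
  if (!is.null(tables$summer_biomass)) {
    df <- tables$summer_biomass
    if (check_cols(df, c("field", "treatment", "species", "biomass"),
                   "summer_biomass")) {
      check_filled(df, "treatment", "summer_biomass")
      bad <- which(!is.finite(df$biomass) | df$biomass < 0)
      for (r in bad) note("error", "summer_biomass", r, "negative biomass")
      cells <- unique(df[, c("field", "treatment")])
      grid <- expand.grid(field = unique(df$field),
                          treatment = unique(df$treatment),
                          stringsAsFactors = FALSE)
      missing <- dplyr::anti_join(grid, cells,
                                  by = c("field", "treatment"))
      if (nrow(missing)) {
        note("error", "summer_biomass", NA_integer_,
             paste("incomplete field x treatment layout:",
                   nrow(missing), "missing cell(s)"))
      }
    }
  }
  report <- if (length(rep_rows)) dplyr::bind_rows(rep_rows) else
    tibble::tibble(severity = character(0), table = character(0),
                   row = integer(0), message = character(0))
  list(ok = !any(report$severity == "error"), report = report)
}

# wide field x treatment matrix from a long (field, treatment, value) table
wide_matrix <- function(df, value) {
  w <- tidyr::pivot_wider(df[, c("field", "treatment", value)],
                          names_from = "treatment",
                          values_from = dplyr::all_of(value))
  m <- as.matrix(w[, -1, drop = FALSE])
  rownames(m) <- w$field
  m
}

#' Treatment-level summary with ranks and letters
#'
#' Mirrors the classic trial report layout: per treatment the mean TFI
#' and mean total weed biomass over fields, biomass as a percent of the
#' untreated control, and mean Friedman ranks with compact letters from
#' the exact all-pairs test.  TFI is ranked over the treated groups,
#' biomass over all treatments including the control.
#'
#' @param tfi_by_field Tibble `field`, `treatment`, `tfi` (treated
#'   groups).
#' @param biomass_by_field Tibble `field`, `treatment`, `biomass`
#'   (total g m^-2, all treatments incl. `"Untreated"`).
#' @param alpha Letter-display significance level.
#' @param control Name of the untreated control level.
#' @return Tibble, one row per treatment.
#' @export
treatment_summary <- function(tfi_by_field, biomass_by_field,
                              alpha = 0.05, control = "Untreated") {
  tfi_m <- wide_matrix(tfi_by_field, "tfi")
  bio_m <- wide_matrix(biomass_by_field, "biomass")
  tfi_test <- all_pairs_test(tfi_m, alpha = alpha)
  bio_test <- all_pairs_test(bio_m, alpha = alpha)
  untreated_mean <- if (control %in% colnames(bio_m)) {
    mean(bio_m[, control])
  } else NA_real_
  treatments <- colnames(bio_m)
  tibble::tibble(
    treatment = treatments,
    tfi = unname(ifelse(treatments %in% colnames(tfi_m),
                        colMeans(tfi_m)[treatments], NA_real_)),
    tfi_rank = tfi_test$letters$mean_rank[
      match(treatments, tfi_test$letters$treatment)],
    tfi_letters = tfi_test$letters$letters[
      match(treatments, tfi_test$letters$treatment)],
    biomass = unname(colMeans(bio_m)[treatments]),
    biomass_pct = if (is.na(untreated_mean)) NA_real_ else
      unname(relative_biomass(colMeans(bio_m)[treatments],
                              untreated_mean)),
    biomass_rank = bio_test$letters$mean_rank[
      match(treatments, bio_test$letters$treatment)],
    biomass_letters = bio_test$letters$letters[
      match(treatments, bio_test$letters$treatment)])
}

#' Run the full trial analysis pipeline
#'
#' Orchestrates generate -> diversity metrics -> TFI -> rank tests ->
#' path models on a synthetic mechanistic trial (or user-supplied
#' tables), and optionally writes all outputs as CSV plus a JSON
#' manifest.
#'
#' @param config A [trial_config()]; ignored when `trial` is given.
#' @param trial Optional pre-generated trial list (see
#'   [generate_mechanistic()]); when `NULL` one is generated from
#'   `config` and `seed`.
#' @param seed Integer seed controlling generation and any Monte-Carlo
#'   fallback.
#' @param metric Diversity metric entering the path model.
#' @param orders Hill-order grid for the profile outputs.
#' @param alpha Significance level for letter displays.
#' @param alpha_keep Stepwise constraint-retention level.
#' @param outdir Output directory; `NULL` skips writing.
#' @return List with `summary` (Table-1 style), `alpha_gamma` (Table-2
#'   style), `profiles` and `profile_letters` (Hill series), `pairs`
#'   (rank tests), `observations`, `path` (stepwise result), `effects`,
#'   `r_squared`, `validation`, `manifest`.  Invisibly when `outdir` is
#'   set.
#' @export
run_pipeline <- function(config = trial_config(), trial = NULL,
                         seed = 1L, metric = c("richness", "shannon"),
                         orders = c(0, 0.5, 1, 2, 4, Inf),
                         alpha = 0.05, alpha_keep = 0.05,
                         outdir = NULL) {
  metric <- match.arg(metric)
  if (is.null(trial)) trial <- generate_mechanistic(config, seed = seed)
  val <- validate_tables(trial)
  if (!val$ok) {
    stop("input validation failed:\n",
         paste(utils::capture.output(
           print(as.data.frame(val$report))), collapse = "\n"),
         call. = FALSE)
  }
  treatments <- unique(trial$summer_biomass$treatment)
  groups <- setdiff(treatments, "Untreated")

  bio_field <- trial$summer_biomass |>
    dplyr::group_by(.data$field, .data$treatment) |>
    dplyr::summarise(biomass = sum(.data$biomass), .groups = "drop")
  tfi_field <- tfi_table(trial$applications)
  summary_tbl <- treatment_summary(tfi_field, bio_field, alpha = alpha)

  # Table-2 style: per treatment, gamma over fields and mean alpha,
  # for richness and equivalent species richness on summer biomass
  ag_rows <- lapply(treatments, function(tr) {
    comms <- trial$summer_biomass |>
      dplyr::filter(.data$treatment == tr, .data$biomass > 0)
    comms <- split(setNames(comms$biomass, comms$species), comms$field)
    r <- alpha_gamma(comms, a = 0)
    eq <- alpha_gamma(comms, a = 1)
    tibble::tibble(treatment = tr,
                   richness_gamma = r$gamma, richness_alpha = r$alpha,
                   eq_richness_gamma = eq$gamma,
                   eq_richness_alpha = eq$alpha)
  })
  ag_tbl <- dplyr::bind_rows(ag_rows)

  profiles <- trial$summer_biomass |>
    dplyr::filter(.data$biomass > 0) |>
    dplyr::group_by(.data$field, .data$treatment) |>
    dplyr::reframe(diversity_profile(
      setNames(.data$biomass, .data$species), orders))
  profile_letters <- dplyr::bind_rows(lapply(orders, function(a) {
    sub <- profiles[profiles$order_a == a, ]
    m <- wide_matrix(dplyr::rename(sub, value = "diversity"), "value")
    res <- all_pairs_test(m, alpha = alpha, seed = seed)
    dplyr::mutate(res$letters, order_a = a, .before = 1L)
  }))

  pairs_tbl <- all_pairs_test(
    wide_matrix(tfi_field, "tfi"), alpha = alpha, seed = seed)$pairs

  obs <- assemble_observations(trial, groups = groups, metric = metric)
  path <- stepwise_constrain(obs, alpha_keep = alpha_keep)
  eff <- dplyr::bind_rows(lapply(path$fit$groups, function(g) {
    e <- path_effects(path$fit, g)
    tibble::tibble(group = g, direct = e$direct, indirect = e$indirect,
                   total = e$total)
  }))

  manifest <- list(
    package = "weedpath",
    version = as.character(utils::packageVersion("weedpath")),
    seed = seed, metric = metric, alpha = alpha,
    alpha_keep = alpha_keep, orders = orders,
    config_hash = rlang::hash(config))

  out <- list(summary = summary_tbl, alpha_gamma = ag_tbl,
              profiles = profiles, profile_letters = profile_letters,
              pairs = pairs_tbl, observations = obs, path = path,
              effects = eff, r_squared = path_r_squared(path$fit),
              validation = val$report, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      write.csv(df, file.path(outdir, paste0(name, ".csv")),
                row.names = FALSE)
    }
    wr(summary_tbl, "treatment_summary")
    wr(ag_tbl, "alpha_gamma")
    wr(profiles, "hill_profiles")
    wr(profile_letters, "hill_profile_letters")
    wr(pairs_tbl, "tfi_pairs")
    wr(obs, "observations")
    wr(path$fit$coefficients, "path_coefficients")
    wr(path$trail, "path_decision_trail")
    wr(eff, "path_effects")
    wr(path_r_squared(path$fit), "path_r_squared")
    jsonlite::write_json(manifest,
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
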