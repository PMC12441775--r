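#' Default weed species pool
#'
#' Twenty-one EPPO-coded species typical of winter-wheat weed floras in
#' north-eastern Germany, dominated by *Viola arvensis* (VIOAR),
#' *Matricaria* spec. (MATSS) and *Papaver rhoeas* (PAPRH), with
#' volunteer oilseed rape (BRSNN) locally important.  `weight` sets the
#' expected share of the total autumn density, `presence` the per-field
#' occurrence probability, `unit_mass` the dry mass of one mature plant
#' (g), `competitiveness` the weight a decision rule puts on controlling
#' the species, and `guild` the herbicide-susceptibility group.
#'
#' @return Tibble with one row per species.
#' @export
default_species_pool <- function() {
  tibble::tribble(
    ~species, ~weight, ~presence, ~unit_mass, ~competitiveness, ~guild,
    "VIOAR",  30,   0.98, 0.9, 0.55, "dicot",
    "MATSS",  25,   0.95, 3.0, 0.85, "dicot",
    "PAPRH",  15,   0.88, 1.5, 0.75, "dicot",
    "BRSNN",  12,   0.75, 2.5, 0.90, "volunteer",
    "STEME",  10,   0.78, 1.5, 0.65, "dicot",
    "CAPBP",   8,   0.62, 1.2, 0.55, "dicot",
    "APESV",   6,   0.52, 1.1, 0.95, "grass",
    "GALAP",   5,   0.48, 2.8, 0.95, "dicot",
    "CHEAL",   4,   0.42, 1.8, 0.80, "dicot",
    "VERHE",   4,   0.42, 0.7, 0.45, "dicot",
    "MYOAR",   3,   0.40, 0.8, 0.45, "dicot",
    "POLAV",   2,   0.35, 1.3, 0.60, "dicot",
    "POAAN",   2,   0.40, 0.5, 0.60, "grass",
    "HORVX",   2,   0.40, 6.0, 0.85, "grass",
    "LAMPU",   2,   0.35, 0.9, 0.45, "dicot",
    "CENCY",   1.5, 0.32, 1.6, 0.60, "dicot",
    "AGGRE",   1,   0.32, 1.2, 0.90, "grass",
    "CIRAR",   1,   0.28, 2.2, 0.85, "dicot",
    "TTLWI",   1,   0.26, 4.0, 0.80, "grass",
    "EQUAR",   0.8, 0.22, 1.0, 0.50, "dicot",
    "IUNSS",   0.5, 0.13, 0.4, 0.40, "grass")
}

#' Default herbicide portfolio
#'
#' Six invented products with a registered dose (product units per ha)
#' and a cost per full registered dose.  Product names and parameters are
#' synthetic; they stand in for a DSS herbicide database that is not
#' public.
#'
#' @return Tibble `product`, `registered_dose`, `cost`.
#' @export
default_portfolio <- function() {
  tibble::tribble(
    ~product,       ~registered_dose, ~cost,
    "ProWheat500",  1.5, 30,
    "GrassEx",      1.0, 45,
    "DicoPlus",     2.0, 25,
    "BroadMaster",  1.2, 60,
    "RapeOff",      0.8, 20,
    "HerbUltra",    1.0, 80)
}

# guild-level maximum efficacy of each product
.guild_eff <- list(
  ProWheat500 = c(dicot = 0.97, grass = 0.45, volunteer = 0.80),
  GrassEx     = c(dicot = 0.35, grass = 0.975, volunteer = 0.40),
  DicoPlus    = c(dicot = 0.975, grass = 0.35, volunteer = 0.65),
  BroadMaster = c(dicot = 0.90, grass = 0.92, volunteer = 0.90),
  RapeOff     = c(dicot = 0.45, grass = 0.30, volunteer = 0.98),
  HerbUltra   = c(dicot = 0.985, grass = 0.985, volunteer = 0.985))

.product_ed50 <- c(ProWheat500 = 0.35, GrassEx = 0.36, DicoPlus = 0.33,
                   BroadMaster = 0.32, RapeOff = 0.26, HerbUltra = 0.26)

#' Default dose-response curves
#'
#' One log-logistic curve per species x product:
#' `efficacy(x) = Emax * x^s / (x^s + ED50^s)` with `x` the dose as a
#' fraction of the registered dose.  Efficacy is 0 at dose 0 and strictly
#' increasing, approaching the product- and guild-specific maximum
#' efficacy `Emax`.  A small deterministic per-species offset
#' differentiates species within a guild.
#'
#' @param pool Species pool as from [default_species_pool()].
#' @param portfolio Portfolio as from [default_portfolio()].
#' @return Tibble `species`, `product`, `max_efficacy`, `ed50`, `slope`.
#' @export
default_curves <- function(pool = default_species_pool(),
                           portfolio = default_portfolio()) {
  grid <- expand.grid(species = pool$species,
                      product = portfolio$product,
                      stringsAsFactors = FALSE)
  guild <- setNames(pool$guild, pool$species)
  sp_idx <- setNames(seq_len(nrow(pool)), pool$species)
  grid$max_efficacy <- mapply(function(s, h) {
    base <- .guild_eff[[h]][[guild[[s]]]]
    # deterministic within-guild variation, kept away from 1
    min(base + 0.008 * cos(sp_idx[[s]] + nchar(h)), 0.995)
  }, grid$species, grid$product)
  grid$ed50 <- .product_ed50[grid$product]
  grid$slope <- 3.2
  tibble::as_tibble(grid)
}

#' Log-logistic dose-response efficacy
#'
#' @param fraction Dose as a fraction of the registered dose, >= 0.
#' @param ed50 Dose fraction giving half the maximum efficacy.
#' @param slope Hill slope (> 0).
#' @param max_efficacy Upper asymptote in (0, 1].
#' @return Efficacy in `[0, max_efficacy)`; 0 at dose 0.
#' @export
dose_response_efficacy <- function(fraction, ed50, slope, max_efficacy) {
  ifelse(fraction <= 0, 0,
         max_efficacy * fraction^slope / (fraction^slope + ed50^slope))
}

#' Invert a dose-response curve at a target efficacy
#'
#' @param target Required efficacy, must be below `max_efficacy`.
#' @inheritParams dose_response_efficacy
#' @return Dose fraction `x` with `efficacy(x) == target`.
#' @export
invert_dose_response <- function(target, ed50, slope, max_efficacy) {
  if (any(target >= max_efficacy)) {
    stop("target efficacy not reachable: exceeds the curve maximum",
         call. = FALSE)
  }
  ifelse(target <= 0, 0,
         ed50 * (target / (max_efficacy - target))^(1 / slope))
}

# Fixed species -> product assignment: the most cost-efficient product
# able to deliver the highest target the DSS may ever request (cap).
# Making the assignment independent of the realized targets guarantees
# that lowering target efficacies never increases the TFI.
assign_herbicides <- function(curves, portfolio, cap = 0.95) {
  cost <- setNames(portfolio$cost, portfolio$product)
  out <- curves |>
    dplyr::filter(.data$max_efficacy > cap) |>
    dplyr::mutate(score = cost[.data$product] * .data$ed50 /
                    .data$max_efficacy) |>
    dplyr::group_by(.data$species) |>
    dplyr::slice_min(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  missing <- setdiff(unique(curves$species), out$species)
  if (length(missing)) {
    stop("no product reaches the target cap for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  setNames(out$product, out$species)
}

#' Density-dependent target efficacies
#'
#' The required control level of a species rises with its density and
#' competitiveness, saturating below a cap; the risk-accepting (reduced)
#' variant lowers each species' target by 3 to 15 percentage points, with
#' larger reductions for less competitive species.
#'
#' @param densities Named vector of autumn densities (plants m^-2).
#' @param pool Species pool (for competitiveness weights).
#' @param reduced Use the reduced-target variant?
#' @return Named vector of target efficacies in `[0, 0.95)`.
#' @export
target_efficacies <- function(densities, pool = default_species_pool(),
                              reduced = FALSE) {
  comp <- setNames(pool$competitiveness, pool$species)
  sp <- names(densities)
  w <- comp[sp]
  t <- (0.55 + 0.40 * (1 - exp(-densities / 15))) * (0.75 + 0.25 * w)
  if (reduced) {
    # risk-accepting variant: 3-15 point reduction, larger for less
    # competitive species
    t <- t - (0.035 + 0.08 * (1 - w))
  }
  pmin(pmax(t, 0), 0.949)
}

#' DSS dose plan from field densities
#'
#' Emulates a cost-minimizing herbicide decision rule: every species with
#' positive density and a positive target is assigned its fixed
#' most-cost-efficient product (see the package's methods vignette); each
#' selected product is applied at the smallest dose fraction (capped at
#' the registered dose) that meets the targets of all species assigned to
#' it.  The TFI of the plan is the sum of the dose fractions.  Because
#' the assignment does not depend on the targets, reducing all target
#' efficacies can never increase the TFI.
#'
#' @param densities Named vector of species densities (plants m^-2).
#' @param curves Dose-response table, see [default_curves()].
#' @param targets Named vector of target efficacies (same names as
#'   `densities`), e.g. from [target_efficacies()].
#' @param portfolio Herbicide portfolio table.
#' @return List `plan` (tibble `product`, `dose_fraction`,
#'   `registered_dose`) and `tfi`.
#' @export
dss_decide <- function(densities, curves, targets,
                       portfolio = default_portfolio()) {
  densities <- densities[densities > 0]
  if (length(densities) == 0L) {
    return(list(plan = tibble::tibble(product = character(0),
                                      dose_fraction = numeric(0),
                                      registered_dose = numeric(0)),
                tfi = 0))
  }
  sp <- names(densities)
  no_curve <- sp[!sp %in% curves$species]
  if (length(no_curve)) {
    stop("no dose-response curve for species: ",
         paste(no_curve, collapse = ", "), call. = FALSE)
  }
  assigned <- assign_herbicides(
    curves[curves$species %in% sp, , drop = FALSE], portfolio)
  need <- targets[sp]
  unreachable <- character(0)
  frac_needed <- vapply(sp, function(s) {
    cu <- curves[curves$species == s & curves$product == assigned[[s]], ]
    if (need[[s]] >= cu$max_efficacy) {
      unreachable <<- c(unreachable, s)
      return(NA_real_)
    }
    invert_dose_response(need[[s]], cu$ed50, cu$slope, cu$max_efficacy)
  }, numeric(1))
  if (length(unreachable)) {
    stop("target efficacy unreachable for species: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  }
  doses <- tapply(frac_needed, assigned[sp], max)
  doses <- pmin(doses, 1)
  doses <- doses[doses > 0]
  reg <- setNames(portfolio$registered_dose, portfolio$product)
  plan <- tibble::tibble(
    product = names(doses),
    dose_fraction = as.numeric(doses),
    registered_dose = as.numeric(reg[names(doses)]))
  list(plan = plan, tfi = sum(plan$dose_fraction))
}

# Table 3-style standardized coefficient defaults (species-richness
# model) and the group scales used to convert them to natural units.
.default_std_coef <- list(
  a = c(DSSstd = -0.12, DSSred = -0.22, AdvLoc = -0.15, AdvSer = -0.24),
  b = c(DSSstd = 0.73, DSSred = 0.67, AdvLoc = 0.40, AdvSer = 0.00),
  c = c(DSSstd = -0.40, DSSred = -0.23, AdvLoc = -0.30, AdvSer = -0.21),
  d = c(DSSstd = 0.32, DSSred = 0.33, AdvLoc = 0.28, AdvSer = 0.33),
  e = c(DSSstd = 0.45, DSSred = 0.47, AdvLoc = 0.40, AdvSer = 0.46),
  f = c(DSSstd = 0.54, DSSred = 0.54, AdvLoc = 0.54, AdvSer = 0.54))

#' Configuration for the synthetic trial generator
#'
#' Defaults emulate the trial series: 15 fields, four treated plot
#' groups, autumn densities log-normal within roughly 17-662 plants
#' m^-2, species richness around 6-14 correlated with density
#' (standardized exogenous correlation 0.54), and structural coefficients
#' whose standardized values match the reported richness path model.
#' Structural coefficients are supplied standardized per group and are
#' converted to natural units at the configured variable scales; residual
#' variances follow from the implied R-squared so the generated data
#' reproduce the standardized pattern in expectation.
#'
#' @param n_fields Number of experimental fields.
#' @param groups Treated group labels.
#' @param mean_d_aut,sd_d_aut Mean/SD of autumn diversity (species
#'   richness per field).
#' @param mean_logn,sd_logn Mean/SD of log autumn density
#'   (ln plants m^-2).
#' @param tfi_mean Named per-group mean TFI.
#' @param sd_tfi Target SD of TFI within each group.
#' @param dsum_mean Named per-group mean summer diversity (richness).
#' @param sd_dsum Target SD of summer diversity within each group.
#' @param std_coef List of per-group standardized coefficients for paths
#'   `a`..`f` (each a named vector over `groups`, or a scalar recycled).
#' @param species_pool,portfolio,curves Mechanistic-mode inputs.
#' @return Object of class `trial_config`; includes the derived
#'   unstandardized coefficients (`$coef`), intercepts and residual SDs
#'   used by [generate_structural()].
#' @export
trial_config <- function(n_fields = 15L,
                         groups = c("DSSstd", "DSSred", "AdvLoc", "AdvSer"),
                         mean_d_aut = 10, sd_d_aut = 2,
                         mean_logn = 4.66, sd_logn = 0.92,
                         tfi_mean = c(DSSstd = 1.37, DSSred = 1.07,
                                      AdvLoc = 1.40, AdvSer = 1.53),
                         sd_tfi = 0.35,
                         dsum_mean = c(DSSstd = 9.0, DSSred = 9.2,
                                       AdvLoc = 9.5, AdvSer = 5.9),
                         sd_dsum = 2.5,
                         std_coef = .default_std_coef,
                         species_pool = default_species_pool(),
                         portfolio = default_portfolio(),
                         curves = default_curves(species_pool, portfolio)) {
  expand <- function(x) {
    if (length(x) == 1L) x <- rep(x, length(groups))
    if (is.null(names(x))) names(x) <- groups
    x[groups]
  }
  std <- lapply(std_coef, expand)
  tfi_mean <- expand(tfi_mean)
  dsum_mean <- expand(dsum_mean)
  # natural-unit coefficients from standardized ones at the fixed scales
  coef <- list(
    a = std$a * sd_tfi / sd_d_aut,
    b = std$b * sd_tfi / sd_logn,
    c = std$c * sd_dsum / sd_tfi,
    d = std$d * sd_dsum / sd_d_aut,
    e = std$e * sd_dsum / sd_logn,
    f = std$f * sd_d_aut * sd_logn)
  # residual variances from the implied R-squared per group
  r2_tfi <- std$a^2 + std$b^2 + 2 * std$a * std$b * std$f
  r_td <- std$a + std$b * std$f     # corr(TFI, D_aut), standardized
  r_tn <- std$b + std$a * std$f     # corr(TFI, logN)
  r2_dsum <- std$c^2 + std$d^2 + std$e^2 +
    2 * std$c * std$d * r_td + 2 * std$c * std$e * r_tn +
    2 * std$d * std$e * std$f
  if (any(r2_tfi >= 1) || any(r2_dsum >= 1)) {
    stop("standardized coefficients imply R-squared >= 1", call. = FALSE)
  }
  structure(list(
    n_fields = as.integer(n_fields), groups = groups,
    mean_d_aut = mean_d_aut, sd_d_aut = sd_d_aut,
    mean_logn = mean_logn, sd_logn = sd_logn,
    tfi_mean = tfi_mean, sd_tfi = sd_tfi,
    dsum_mean = dsum_mean, sd_dsum = sd_dsum,
    std_coef = std, coef = coef,
    alpha1 = tfi_mean - coef$a * mean_d_aut - coef$b * mean_logn,
    alpha2 = dsum_mean - coef$c * tfi_mean - coef$d * mean_d_aut -
      coef$e * mean_logn,
    psi1 = sd_tfi^2 * (1 - r2_tfi),
    psi2 = sd_dsum^2 * (1 - r2_dsum),
    species_pool = species_pool, portfolio = portfolio, curves = curves
  ), class = "trial_config")
}

#' Generate structural-mode path observations
#'
#' Draws, per group and field, (autumn diversity, log autumn density)
#' from a bivariate normal with the configured exogenous covariance,
#' then herbicide intensity and summer diversity from the structural
#' equations plus Gaussian residual noise.
#'
#' @param config A [trial_config()] object.
#' @param seed Integer seed; fully determines the output.
#' @param residual_scale Multiplier(s) on the residual SDs, recycled to
#'   one value per structural equation (TFI, summer diversity).  A zero
#'   makes that equation hold exactly; note that a noise-free TFI
#'   equation makes the summer-diversity design collinear, since TFI is
#'   then an exact linear combination of its own predictors.
#' @return Tibble `field`, `group`, `d_aut`, `logn_aut`, `tfi`, `d_sum`.
#' @export
generate_structural <- function(config, seed = 1L, residual_scale = 1) {
  stopifnot(inherits(config, "trial_config"))
  residual_scale <- rep_len(residual_scale, 2L)
  sig2 <- config$sd_d_aut^2 * config$sd_logn^2
  if (any(config$coef$f^2 >= sig2)) {
    stop("exogenous covariance not positive definite", call. = FALSE)
  }
  withr::with_seed(seed, {
    out <- lapply(config$groups, function(g) {
      n <- config$n_fields
      zn <- rnorm(n)
      zd <- rnorm(n)
      rho <- config$coef$f[[g]] / (config$sd_d_aut * config$sd_logn)
      d_aut <- config$mean_d_aut + config$sd_d_aut * zd
      logn <- config$mean_logn + config$sd_logn *
        (rho * zd + sqrt(1 - rho^2) * zn)
      tfi <- config$alpha1[[g]] + config$coef$a[[g]] * d_aut +
        config$coef$b[[g]] * logn +
        rnorm(n, 0, residual_scale[1L] * sqrt(config$psi1[[g]]))
      d_sum <- config$alpha2[[g]] + config$coef$c[[g]] * tfi +
        config$coef$d[[g]] * d_aut + config$coef$e[[g]] * logn +
        rnorm(n, 0, residual_scale[2L] * sqrt(config$psi2[[g]]))
      tibble::tibble(field = seq_len(n), group = g,
                     d_aut = d_aut, logn_aut = logn,
                     tfi = tfi, d_sum = d_sum)
    })
    dplyr::bind_rows(out)
  })
}

# advisor plans ----------------------------------------------------------

# local advisor: inspects the field, treats the dominant species (by
# density x competitiveness) with their portfolio products at a fixed
# strong dose plus noise
advloc_plan <- function(densities, pool, curves, portfolio, n_top = 4L) {
  comp <- setNames(pool$competitiveness, pool$species)
  pressure <- densities * comp[names(densities)]
  top <- names(sort(pressure, decreasing = TRUE))
  top <- head(top[densities[top] > 0], n_top)
  if (length(top) == 0L) {
    return(tibble::tibble(product = character(0),
                          dose_fraction = numeric(0),
                          registered_dose = numeric(0)))
  }
  assigned <- assign_herbicides(
    curves[curves$species %in% names(densities)[densities > 0], ],
    portfolio)
  prods <- unique(assigned[top])
  reg <- setNames(portfolio$registered_dose, portfolio$product)
  tibble::tibble(
    product = prods,
    dose_fraction = pmin(0.75 * exp(rnorm(length(prods), 0, 0.10)), 1),
    registered_dose = as.numeric(reg[prods]))
}

# official advisory service: fixed broad-spectrum plan, field not
# inspected; only small application noise
advser_plan <- function(portfolio) {
  reg <- setNames(portfolio$registered_dose, portfolio$product)
  tibble::tibble(
    product = c("ProWheat500", "GrassEx"),
    dose_fraction = pmin(c(1, 0.55) * exp(rnorm(2, 0, 0.05)), 1),
    registered_dose = as.numeric(reg[c("ProWheat500", "GrassEx")]))
}

#' Generate a mechanistic synthetic trial dataset
#'
#' Full trial emulation: per field, species densities are drawn from the
#' configured composition; autumn counts are Poisson samples of density
#' over ten 0.1-m^2 quadrats per block (four blocks); each treated group
#' converts the infestation into a dose plan (DSS groups via
#' [dss_decide()] with standard or reduced density-dependent targets,
#' advisor groups via fixed-dose rules); species survival follows the
#' dose-response curves with independent product action; summer dry
#' biomass is surviving density times per-species unit mass under
#' baseline mortality and log-normal plot noise.  The untreated control
#' receives an empty plan.
#'
#' @inheritParams generate_structural
#' @return List of tibbles: `autumn_survey` (field, block, species,
#'   count; counts per 1 m^2 counted area), `applications` (field,
#'   treatment, product, applied_dose, registered_dose, season),
#'   `summer_biomass` (field, treatment, species, biomass g m^-2),
#'   `field_density` (field, species, true density), and `manifest`.
#' @export
generate_mechanistic <- function(config, seed = 1L) {
  stopifnot(inherits(config, "trial_config"))
  pool <- config$species_pool
  portfolio <- config$portfolio
  curves <- config$curves
  treatments <- c(config$groups, "Untreated")
  baseline_survival <- 0.6   # natural + crop-competition mortality
  withr::with_seed(seed, {
    surveys <- list(); apps <- list(); biom <- list(); dens_rows <- list()
    for (f in seq_len(config$n_fields)) {
      present <- runif(nrow(pool)) < pool$presence
      # guarantee a minimally realistic community
      if (sum(present) < 3L) present[order(-pool$presence)[1:3]] <- TRUE
      total <- rlnorm(1, meanlog = config$mean_logn,
                      sdlog = config$sd_logn)
      w <- pool$weight * present * rlnorm(nrow(pool), 0, 0.6)
      dens <- setNames(total * w / sum(w), pool$species)
      dens_rows[[f]] <- tibble::tibble(
        field = f, species = pool$species, density = as.numeric(dens))
      keep <- dens > 0
      for (blk in 1:4) {
        counts <- rpois(sum(keep), dens[keep] * 1.0)  # 10 x 0.1 m^2
        surveys[[length(surveys) + 1L]] <- tibble::tibble(
          field = f, block = blk, species = names(dens)[keep],
          count = counts)
      }
      plans <- list()
      for (tr in treatments) {
        plan <- switch(tr,
          DSSstd = dss_decide(dens, curves,
                              target_efficacies(dens, pool),
                              portfolio)$plan,
          DSSred = dss_decide(dens, curves,
                              target_efficacies(dens, pool,
                                                reduced = TRUE),
                              portfolio)$plan,
          AdvLoc = advloc_plan(dens, pool, curves, portfolio),
          AdvSer = advser_plan(portfolio),
          Untreated = tibble::tibble(product = character(0),
                                     dose_fraction = numeric(0),
                                     registered_dose = numeric(0)))
        plans[[tr]] <- plan
        if (nrow(plan)) {
          apps[[length(apps) + 1L]] <- tibble::tibble(
            field = f, treatment = tr, product = plan$product,
            applied_dose = plan$dose_fraction * plan$registered_dose,
            registered_dose = plan$registered_dose, season = "autumn")
        }
      }
      mass <- setNames(pool$unit_mass, pool$species)
      for (tr in treatments) {
        plan <- plans[[tr]]
        surv <- setNames(rep(1, sum(keep)), names(dens)[keep])
        if (nrow(plan)) {
          for (r in seq_len(nrow(plan))) {
            cu <- curves[curves$product == plan$product[r] &
                           curves$species %in% names(surv), ]
            # application quality: spray conditions, shading, timing
            quality <- runif(1, 0.95, 0.998)
            eff <- quality * dose_response_efficacy(
              plan$dose_fraction[r], cu$ed50, cu$slope, cu$max_efficacy)
            surv[cu$species] <- surv[cu$species] * (1 - eff)
          }
        }
        sp <- names(surv)
        # survivors counted over the 4 x 1 m^2 cut plots; species with
        # no surviving individuals in the sampled area are absent
        lambda <- dens[sp] * surv * baseline_survival * 4
        n_surv <- rpois(length(sp), lambda)
        # no plot is ever entirely weed-free at milk ripeness
        if (all(n_surv == 0L)) n_surv[which.max(lambda)] <- 1L
        b <- n_surv / 4 * mass[sp] * rlnorm(length(sp), 0, 0.35)
        pos <- n_surv > 0
        biom[[length(biom) + 1L]] <- tibble::tibble(
          field = f, treatment = tr, species = sp[pos],
          biomass = as.numeric(b[pos]))
      }
    }
    list(
      autumn_survey = dplyr::bind_rows(surveys),
      applications = dplyr::bind_rows(apps),
      summer_biomass = dplyr::bind_rows(biom),
      field_density = dplyr::bind_rows(dens_rows),
      manifest = list(seed = seed, mode = "mechanistic",
                      n_fields = config$n_fields,
                      groups = config$groups))
  })
}

#' Assemble path-model observations from mechanistic trial tables
#'
#' Computes, per field and treated group: autumn diversity (richness or
#' Shannon index of block-pooled counts), log total autumn density,
#' TFI from the application records, and summer diversity from the
#' biomass table.
#'
#' @param trial Output of [generate_mechanistic()], or a list with
#'   elements `autumn_survey`, `applications`, `summer_biomass`.
#' @param groups Treated group labels to keep.
#' @param metric `"richness"` or `"shannon"`.
#' @return Tibble suitable for [fit_multigroup()].
#' @export
assemble_observations <- function(trial,
                                  groups = c("DSSstd", "DSSred",
                                             "AdvLoc", "AdvSer"),
                                  metric = c("richness", "shannon")) {
  metric <- match.arg(metric)
  div <- function(x) {
    if (metric == "richness") hill_diversity(x, 0) else shannon_index(x)
  }
  aut <- trial$autumn_survey |>
    dplyr::group_by(.data$field, .data$species) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::summarise(
      d_aut = div(setNames(.data$count, .data$species)),
      # counted area: 4 blocks x 10 x 0.1 m^2 = 4 m^2
      logn_aut = log(sum(.data$count) / 4),
      .groups = "drop")
  tfi <- tfi_table(trial$applications)
  summer <- trial$summer_biomass |>
    dplyr::filter(.data$treatment %in% groups, .data$biomass > 0) |>
    dplyr::group_by(.data$field, .data$treatment) |>
    dplyr::summarise(
      d_sum = div(setNames(.data$biomass, .data$species)),
      .groups = "drop")
  summer |>
    dplyr::left_join(aut, by = "field") |>
    dplyr::left_join(tfi, by = c("field", "treatment")) |>
    dplyr::transmute(field = .data$field, group = .data$treatment,
                     d_aut = .data$d_aut, logn_aut = .data$logn_aut,
                     tfi = .data$tfi, d_sum = .data$d_sum)
}
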