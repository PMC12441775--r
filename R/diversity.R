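#' Species proportions of a community
#'
#' Normalizes a vector of nonnegative species quantities (plant counts per
#' m^2 in autumn, or g m^-2 dry biomass in early summer) to proportions.
#' Species with zero abundance are dropped before normalization, so the
#' returned proportions are strictly positive and sum to one.
#'
#' @param x Numeric vector of nonnegative quantities; names, if present,
#'   are retained (EPPO-style species codes such as `"VIOAR"`).
#' @return Named numeric vector of proportions `p_i > 0`, `sum(p) == 1`.
#' @examples
#' species_proportions(c(VIOAR = 7, MATSS = 2, PAPRH = 1))
#' @export
species_proportions <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("community must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(x)) stop("community contains missing quantities", call. = FALSE)
  if (any(x < 0)) stop("species quantities must be nonnegative", call. = FALSE)
  x <- x[x > 0]
  if (length(x) == 0L) {
    stop("empty community: no species with positive abundance", call. = FALSE)
  }
  x / sum(x)
}

#' Hill diversity of order a
#'
#' Effective species number `(sum_i p_i^a)^(1/(1-a))` for Hill power
#' `a >= 0`.  Order 0 is species richness, order 1 the exponential of
#' Shannon entropy (equivalent species richness, computed by its analytic
#' limit), order 2 the inverse Simpson index, and `a = Inf` the reciprocal
#' of the Berger-Parker dominance index `1/max(p)`.
#'
#' @param p Proportion vector as returned by [species_proportions()], or raw
#'   nonnegative quantities (normalized internally).
#' @param a Hill power(s), nonnegative; `Inf` allowed.  Vectorized.
#' @return Numeric vector of effective species numbers, one per order;
#'   each value lies in `[1, S]` where `S = length(p)` after dropping
#'   zero-abundance species.
#' @examples
#' hill_diversity(c(0.5, 0.5), 2)            # 2: even pair, inverse Simpson
#' hill_diversity(c(7, 2, 1), c(0, 1, Inf))  # richness, exp(H'), 1/max p
#' @export
hill_diversity <- function(p, a) {
  if (any(is.na(a)) || any(a < 0)) {
    stop("Hill power a must be nonnegative (Inf allowed)", call. = FALSE)
  }
  p <- species_proportions(p)
  vapply(a, function(ai) {
    if (is.infinite(ai)) return(1 / max(p))
    if (abs(ai - 1) < 1e-9) return(exp(-sum(p * log(p))))
    sum(p^ai)^(1 / (1 - ai))
  }, numeric(1))
}

#' Shannon entropy of a community
#'
#' `H' = -sum_i p_i log(p_i)` in nats, i.e. the natural logarithm of the
#' equivalent species richness: `exp(shannon_index(p))` equals
#' `hill_diversity(p, 1)` exactly.
#'
#' @inheritParams hill_diversity
#' @return Shannon entropy in `[0, log(S)]`.
#' @export
shannon_index <- function(p) {
  log(hill_diversity(p, 1))
}

#' Diversity profile along the Hill series
#'
#' Evaluates [hill_diversity()] on a grid of Hill powers for one
#' community.  The default grid is the conventional series
#' 0, 0.5, 1, 2, 4, Inf.
#'
#' @inheritParams hill_diversity
#' @param orders Numeric vector of Hill powers.
#' @return A tibble with columns `order_a` and `diversity`; the profile is
#'   non-increasing in `order_a`.
#' @examples
#' diversity_profile(c(A = 90, B = 9, C = 1))
#' @export
diversity_profile <- function(p, orders = c(0, 0.5, 1, 2, 4, Inf)) {
  tibble::tibble(order_a = orders, diversity = hill_diversity(p, orders))
}

#' Whittaker alpha- and gamma-diversity over fields
#'
#' Gamma-diversity is the Hill diversity of the pooled community (raw
#' quantities summed over fields before normalization); alpha-diversity is
#' the unweighted arithmetic mean of the per-field Hill diversities.
#'
#' @param communities A list of named numeric vectors, one community per
#'   field, all on the same measurement basis (counts or biomass).
#' @param a Single Hill power.
#' @return Named list with elements `gamma` and `alpha`; `alpha <= gamma`
#'   holds at `a = 0`.
#' @examples
#' alpha_gamma(list(f1 = c(A = 1, B = 1), f2 = c(B = 1, C = 1)), a = 0)
#' @export
alpha_gamma <- function(communities, a) {
  if (!is.list(communities) || length(communities) == 0L) {
    stop("communities must be a non-empty list of abundance vectors",
         call. = FALSE)
  }
  if (length(a) != 1L) stop("a must be a single Hill power", call. = FALSE)
  pooled <- Reduce(function(acc, x) {
    x <- x[x > 0]
    keys <- union(names(acc), names(x))
    if (is.null(names(x)) || is.null(names(acc)) && length(acc)) {
      stop("communities must be named by species code for pooling",
           call. = FALSE)
    }
    out <- setNames(numeric(length(keys)), keys)
    out[names(acc)] <- acc
    out[names(x)] <- out[names(x)] + x
    out
  }, communities, init = setNames(numeric(0), character(0)))
  list(
    gamma = hill_diversity(pooled, a),
    alpha = mean(vapply(communities, hill_diversity, numeric(1), a = a))
  )
}

#' Per-field diversity profiles from a long survey table
#'
#' Computes Hill profiles for every field x treatment community in a long
#' survey table, pooling quantities over blocks/plots within a field and
#' treatment (surveys are aggregated by species but pooled across blocks
#' for data processing).
#'
#' @param survey Data frame with columns `field`, `treatment`, `species`,
#'   `quantity`, and optionally `basis` (must be uniform if present).
#' @param orders Hill power grid.
#' @return Tidy tibble (`field`, `treatment`, `order_a`, `diversity`).
#' @export
survey_profiles <- function(survey, orders = c(0, 0.5, 1, 2, 4, Inf)) {
  need <- c("field", "treatment", "species", "quantity")
  if (!all(need %in% names(survey))) {
    stop("survey table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if ("basis" %in% names(survey) &&
      length(unique(survey$basis)) > 1L) {
    stop("mixed measurement basis in one survey table", call. = FALSE)
  }
  survey |>
    dplyr::group_by(.data$field, .data$treatment, .data$species) |>
    dplyr::summarise(quantity = sum(.data$quantity), .groups = "drop") |>
    dplyr::group_by(.data$field, .data$treatment) |>
    dplyr::reframe(diversity_profile(
      setNames(.data$quantity, .data$species), orders))
}
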