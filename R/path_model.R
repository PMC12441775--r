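#' @title Multi-group recursive path model of weed diversity and
#'   herbicide intensity
#'
#' @description
#' The model links four observed variables per treatment group g:
#' autumn diversity `D_aut`, log autumn weed density `logN_aut`,
#' herbicide intensity `TFI`, and summer diversity `D_sum`, through two
#' recursive regressions and one exogenous correlation:
#'
#' \deqn{TFI = \alpha_1 + a D_{aut} + b \log N_{aut} + \epsilon_1}
#' \deqn{D_{sum} = \alpha_2 + c\, TFI + d D_{aut} + e \log N_{aut} + \epsilon_2}
#' \deqn{f = cov(D_{aut}, \log N_{aut})}
#'
#' Estimation is normal-theory maximum likelihood; sample moments use the
#' ML (1/n) convention.  Any subset of the path families
#' `a, b, c, d, e, f` (and the residual variances `psi1`, `psi2`) can be
#' constrained equal across groups.  With no constraints the coefficient
#' estimates coincide with per-group ordinary least squares.
#'
#' @name path_model
NULL

path_families <- c("a", "b", "c", "d", "e", "f")

# column roles in the observation table
.obs_cols <- c("group", "d_aut", "logn_aut", "tfi", "d_sum")

check_observations <- function(data) {
  miss <- setdiff(.obs_cols, names(data))
  if (length(miss)) {
    stop("observations need columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- c("d_aut", "logn_aut", "tfi", "d_sum")
  if (any(!complete.cases(data[, num]))) {
    stop("missing values in path-model variables", call. = FALSE)
  }
  data
}

# ML (1/n) variance and covariance
var_ml <- function(x) mean((x - mean(x))^2)
cov_ml <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

# Maximise one regression equation's Gaussian likelihood across groups
# with a subset of slope coefficients constrained equal.  Coordinate
# ascent: weighted least squares given the group residual variances,
# closed-form ML variance update given the coefficients.  Both half-steps
# are exact maximisations, so the log-likelihood is non-decreasing.
fit_equation <- function(y_by_g, X_by_g, coef_names, shared,
                         share_psi = FALSE, tol = 1e-10, max_iter = 200L) {
  G <- length(y_by_g)
  groups <- names(y_by_g)
  p <- length(coef_names)
  # degenerate-input checks
  for (g in groups) {
    X <- X_by_g[[g]]
    for (j in seq_len(p)) {
      if (var_ml(X[, j + 1L]) == 0) {
        stop("zero-variance predictor '", coef_names[j],
             "' in group ", g, call. = FALSE)
      }
    }
    if (var_ml(y_by_g[[g]]) == 0) {
      stop("constant response in group ", g,
           " (zero residual variance breaks the likelihood)", call. = FALSE)
    }
  }
  # parameter layout: per-group intercepts, then slopes
  par_names <- c(paste0("alpha.", groups),
                 unlist(lapply(coef_names, function(cn) {
                   if (cn %in% shared) cn else paste0(cn, ".", groups)
                 })))
  P <- length(par_names)
  n_g <- vapply(y_by_g, length, 1L)
  N <- sum(n_g)
  Z <- matrix(0, N, P, dimnames = list(NULL, par_names))
  yvec <- numeric(N)
  grow <- rep(groups, n_g)
  pos <- 0L
  for (g in groups) {
    idx <- pos + seq_len(n_g[[g]])
    X <- X_by_g[[g]]
    Z[idx, paste0("alpha.", g)] <- 1
    for (j in seq_len(p)) {
      cn <- coef_names[j]
      col <- if (cn %in% shared) cn else paste0(cn, ".", g)
      Z[idx, col] <- X[, j + 1L]
    }
    yvec[idx] <- y_by_g[[g]]
    pos <- pos + n_g[[g]]
  }
  psi <- setNames(rep(var_ml(yvec), G), groups)
  loglik <- -Inf
  beta <- NULL
  for (iter in seq_len(max_iter)) {
    w <- 1 / sqrt(psi[grow])
    fit <- lm.fit(Z * w, yvec * w)
    if (fit$rank < P) {
      stop("singular design in equation fit (collinear predictors)",
           call. = FALSE)
    }
    beta <- fit$coefficients
    resid <- yvec - drop(Z %*% beta)
    rss_g <- setNames(as.numeric(tapply(resid^2, grow, sum)[groups]),
                      groups)
    psi_new <- if (share_psi) {
      setNames(rep(max(sum(rss_g) / N, 1e-12), G), groups)
    } else {
      pmax(rss_g / n_g, 1e-12)
    }
    ll <- -sum(n_g / 2 * (log(2 * pi * psi_new) + rss_g / (n_g * psi_new)))
    psi <- psi_new
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      loglik <- ll
      break
    }
    loglik <- ll
  }
  # standard errors use degrees-of-freedom-corrected residual variances
  # (n - p per group, as in least-squares practice); the likelihood and
  # the reported residual variances keep the ML (1/n) convention
  psi_se <- pmax(rss_g / pmax(n_g - (p + 1L), 1L), 1e-12)
  if (share_psi) {
    psi_se[] <- max(sum(rss_g) / max(N - G * (p + 1L), 1L), 1e-12)
  }
  w_se <- 1 / sqrt(psi_se[grow])
  info <- crossprod(Z * w_se)
  vcov_beta <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, P, P, dimnames = list(par_names, par_names))
  })
  # expand to per-group coefficient tables
  coefs <- lapply(groups, function(g) {
    est <- se <- setNames(numeric(p + 1L), c("(Intercept)", coef_names))
    for (nm in c("(Intercept)", coef_names)) {
      col <- if (nm == "(Intercept)") paste0("alpha.", g)
             else if (nm %in% shared) nm else paste0(nm, ".", g)
      est[nm] <- beta[col]
      se[nm] <- sqrt(diag(vcov_beta))[col]
    }
    list(est = est, se = se)
  })
  names(coefs) <- groups
  npar <- P + if (share_psi) 1L else G
  list(coefs = coefs, psi = psi, loglik = loglik, npar = npar,
       iterations = iter, converged = iter < max_iter)
}

# Exogenous bivariate block (D_aut, logN_aut): means always saturated
# per group; covariance matrix saturated per group unless the covariance
# f is constrained equal across groups, in which case group variances
# stay free and the common covariance is found numerically.
fit_exogenous <- function(xy_by_g, share_f = FALSE) {
  groups <- names(xy_by_g)
  G <- length(groups)
  n_g <- vapply(xy_by_g, nrow, 1L)
  mom <- lapply(xy_by_g, function(m) {
    list(mu = colMeans(m),
         v1 = var_ml(m[, 1L]), v2 = var_ml(m[, 2L]),
         cv = cov_ml(m[, 1L], m[, 2L]))
  })
  ll_group <- function(m, v1, v2, cv, S) {
    det <- v1 * v2 - cv^2
    # smooth infeasibility penalty steers optimisers back to PD region
    if (det <= 0) return(-1e8 * (1 + cv^2 - v1 * v2))
    Sig_inv <- matrix(c(v2, -cv, -cv, v1), 2L) / det
    -nrow(m) / 2 * (2 * log(2 * pi) + log(det) +
                      sum(Sig_inv * S) )
  }
  smat <- lapply(groups, function(g) {
    m <- xy_by_g[[g]]
    mu <- mom[[g]]$mu
    crossprod(sweep(m, 2L, mu)) / nrow(m)
  })
  names(smat) <- groups
  if (!share_f) {
    ll <- sum(vapply(groups, function(g) {
      with(mom[[g]], ll_group(xy_by_g[[g]], v1, v2, cv,
                              smat[[g]]))
    }, numeric(1)))
    # reported covariance uses the unbiased (n-1) convention; its
    # asymptotic variance (v1 v2 + cv^2)/n gets the matching df
    # correction.  The likelihood itself stays on ML (1/n) moments.
    f_est <- vapply(groups, function(g) {
      mom[[g]]$cv * n_g[[g]] / (n_g[[g]] - 1L)
    }, numeric(1))
    f_se <- vapply(groups, function(g) {
      with(mom[[g]], sqrt((v1 * v2 + cv^2) / max(n_g[[g]] - 3L, 1L)))
    }, numeric(1))
    f_std <- vapply(groups, function(g) {
      with(mom[[g]], cv / sqrt(v1 * v2))
    }, numeric(1))
    return(list(
      mom = mom, loglik = ll, npar = 5L * G,
      f = setNames(f_est, groups),
      f_se = setNames(f_se, groups),
      f_std = setNames(f_std, groups),
      v1 = setNames(vapply(mom, `[[`, 1, "v1"), groups),
      v2 = setNames(vapply(mom, `[[`, 1, "v2"), groups)))
  }
  # shared covariance: block-coordinate ascent.  Given the common
  # covariance, each group's variances are maximised by a 2-d BFGS on
  # the log scale (the likelihood tends to -Inf at the PD boundary, so
  # the optimum is interior); given the variances, the covariance is
  # maximised on its admissible interval by 1-d search.  Each half-step
  # is a maximisation, so the joint log-likelihood is non-decreasing.
  v1 <- vapply(mom, `[[`, 1, "v1")
  v2 <- vapply(mom, `[[`, 1, "v2")
  cv <- mean(vapply(mom, `[[`, 1, "cv"))
  bound <- function() sqrt(min(v1 * v2)) * (1 - 1e-9)
  cv <- max(min(cv, 0.95 * bound()), -0.95 * bound())
  ll_total <- function() {
    sum(vapply(seq_along(groups), function(i) {
      ll_group(xy_by_g[[i]], v1[i], v2[i], cv, smat[[i]])
    }, numeric(1)))
  }
  ll_old <- ll_total()
  for (iter in seq_len(500L)) {
    for (i in seq_along(groups)) {
      oi <- optim(log(c(v1[i], v2[i])), function(lv) {
        -ll_group(xy_by_g[[i]], exp(lv[1L]), exp(lv[2L]), cv, smat[[i]])
      }, method = "BFGS", control = list(reltol = 1e-14))
      v1[i] <- exp(oi$par[1L]); v2[i] <- exp(oi$par[2L])
    }
    b <- bound()
    oc <- stats::optimize(function(ccv) {
      -sum(vapply(seq_along(groups), function(i) {
        ll_group(xy_by_g[[i]], v1[i], v2[i], ccv, smat[[i]])
      }, numeric(1)))
    }, interval = c(-b, b), tol = 1e-12)
    cv <- oc$minimum
    ll_new <- ll_total()
    if (abs(ll_new - ll_old) < 1e-10) break
    ll_old <- ll_new
  }
  obj <- function(par) {
    vv1 <- exp(par[seq_len(G)])
    vv2 <- exp(par[G + seq_len(G)])
    ccv <- par[2L * G + 1L]
    -sum(vapply(seq_along(groups), function(i) {
      ll_group(xy_by_g[[i]], vv1[i], vv2[i], ccv, smat[[i]])
    }, numeric(1)))
  }
  h <- tryCatch(stats::optimHess(c(log(v1), log(v2), cv), obj),
                error = function(e) NULL)
  f_se_val <- if (!is.null(h)) {
    vc <- tryCatch(solve(h), error = function(e) NULL)
    if (!is.null(vc) && vc[2L * G + 1L, 2L * G + 1L] > 0) {
      sqrt(vc[2L * G + 1L, 2L * G + 1L])
    } else NA_real_
  } else NA_real_
  for (i in seq_along(groups)) {
    mom[[i]]$v1 <- v1[i]; mom[[i]]$v2 <- v2[i]; mom[[i]]$cv <- cv
  }
  N <- sum(n_g)
  list(mom = mom, loglik = ll_total(), npar = 4L * G + 1L,
       f = setNames(rep(cv * N / (N - 1L), G), groups),
       f_se = setNames(rep(f_se_val * sqrt(N / max(N - 3L, 1L)), G),
                       groups),
       f_std = setNames(cv / sqrt(v1 * v2), groups),
       v1 = setNames(v1, groups), v2 = setNames(v2, groups))
}

#' Fit the multi-group path model
#'
#' Maximum-likelihood fit of the recursive two-equation path model (see
#' [path_model]) to one observation per field and treatment group, with
#' an optional set of parameters constrained equal across groups.
#'
#' @param data Data frame with columns `group`, `d_aut` (autumn
#'   diversity), `logn_aut` (log autumn density), `tfi`, `d_sum` (summer
#'   diversity); one row per field x group, treated groups only.
#' @param constrained Character vector naming the parameter families held
#'   equal across groups: any of `"a", "b", "c", "d", "e", "f"` and the
#'   residual variances `"psi1"`, `"psi2"`.
#' @return Object of class `path_fit` with elements `coefficients`
#'   (tibble: `group`, `path`, `estimate`, `se`, `z`, `p`,
#'   `standardized`, `shared`), `intercepts`, `psi` (residual variances),
#'   `r_squared`, `loglik`, `npar`, `n_by_group`, `constrained`,
#'   `converged`.
#' @examples
#' cfg <- trial_config()
#' obs <- generate_structural(cfg, seed = 42)
#' fit <- fit_multigroup(obs)
#' subset(fit$coefficients, path == "b")
#' @export
fit_multigroup <- function(data, constrained = character(0)) {
  data <- check_observations(as.data.frame(data))
  ok <- c(path_families, "psi1", "psi2")
  if (!all(constrained %in% ok)) {
    stop("unknown constrained parameter(s): ",
         paste(setdiff(constrained, ok), collapse = ", "), call. = FALSE)
  }
  groups <- if (is.factor(data$group)) levels(droplevels(data$group))
            else unique(data$group)
  G <- length(groups)
  if (G < 2L && length(intersect(constrained, ok))) {
    # constraints are vacuous with a single group
    constrained <- character(0)
  }
  split_g <- split(data, factor(data$group, levels = groups))
  n_g <- vapply(split_g, nrow, 1L)
  if (any(n_g < 5L)) {
    stop("each group needs at least 5 observations", call. = FALSE)
  }
  y1 <- lapply(split_g, `[[`, "tfi")
  X1 <- lapply(split_g, function(d) {
    cbind(1, d$d_aut, d$logn_aut)
  })
  y2 <- lapply(split_g, `[[`, "d_sum")
  X2 <- lapply(split_g, function(d) {
    cbind(1, d$tfi, d$d_aut, d$logn_aut)
  })
  eq1 <- fit_equation(y1, X1, c("a", "b"),
                      shared = intersect(constrained, c("a", "b")),
                      share_psi = "psi1" %in% constrained)
  eq2 <- fit_equation(y2, X2, c("c", "d", "e"),
                      shared = intersect(constrained, c("c", "d", "e")),
                      share_psi = "psi2" %in% constrained)
  xy <- lapply(split_g, function(d) cbind(d$d_aut, d$logn_aut))
  exo <- fit_exogenous(xy, share_f = "f" %in% constrained)

  sds <- lapply(split_g, function(d) {
    vapply(d[, c("d_aut", "logn_aut", "tfi", "d_sum")],
           function(x) sqrt(var_ml(x)), numeric(1))
  })
  pred_of <- c(a = "d_aut", b = "logn_aut", c = "tfi", d = "d_aut",
               e = "logn_aut")
  resp_of <- c(a = "tfi", b = "tfi", c = "d_sum", d = "d_sum",
               e = "d_sum")
  paths <- c("a", "b", "c", "d", "e", "f")
  grp_col <- rep(groups, each = length(paths))
  path_col <- rep(paths, G)
  est_col <- se_col <- std_col <- numeric(length(grp_col))
  for (i in seq_along(grp_col)) {
    g <- grp_col[i]; pth <- path_col[i]
    if (pth %in% c("a", "b")) {
      est <- eq1$coefs[[g]]$est[[pth]]; se <- eq1$coefs[[g]]$se[[pth]]
    } else if (pth %in% c("c", "d", "e")) {
      est <- eq2$coefs[[g]]$est[[pth]]; se <- eq2$coefs[[g]]$se[[pth]]
    } else {
      est <- exo$f[[g]]; se <- exo$f_se[[g]]
    }
    est_col[i] <- est; se_col[i] <- se
    std_col[i] <- if (pth == "f") {
      exo$f_std[[g]]
    } else {
      est * sds[[g]][[pred_of[[pth]]]] / sds[[g]][[resp_of[[pth]]]]
    }
  }
  coefs <- tibble::tibble(
    group = grp_col, path = path_col, estimate = est_col, se = se_col,
    standardized = std_col, shared = path_col %in% constrained)
  coefs$z <- coefs$estimate / coefs$se
  coefs$p <- 2 * pnorm(-abs(coefs$z))
  coefs <- coefs[, c("group", "path", "estimate", "se", "z", "p",
                     "standardized", "shared")]
  r2 <- tibble::tibble(
    group = rep(groups, each = 2L),
    response = rep(c("tfi", "d_sum"), G),
    r_squared = unname(unlist(lapply(groups, function(g) {
      pmin(pmax(c(
        1 - eq1$psi[[g]] / var_ml(y1[[g]]),
        1 - eq2$psi[[g]] / var_ml(y2[[g]])), 0), 1)
    }))))
  structure(list(
    coefficients = coefs,
    intercepts = tibble::tibble(
      group = rep(groups, 2L),
      equation = rep(c("tfi", "d_sum"), each = G),
      estimate = c(
        vapply(groups, function(g) eq1$coefs[[g]]$est[["(Intercept)"]], 1),
        vapply(groups, function(g) eq2$coefs[[g]]$est[["(Intercept)"]], 1))),
    psi = tibble::tibble(
      group = rep(groups, 2L),
      equation = rep(c("tfi", "d_sum"), each = G),
      variance = c(eq1$psi, eq2$psi)),
    exogenous = exo,
    r_squared = r2,
    loglik = eq1$loglik + eq2$loglik + exo$loglik,
    npar = eq1$npar + eq2$npar + exo$npar,
    n_by_group = n_g,
    groups = groups,
    constrained = sort(constrained),
    converged = eq1$converged && eq2$converged
  ), class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Multi-group path model fit\n")
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  cat("  n per group:", paste(x$n_by_group, collapse = ", "), "\n")
  cat("  constrained across groups:",
      if (length(x$constrained)) paste(x$constrained, collapse = ", ")
      else "(none)", "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " free parameters:", x$npar, "\n\n")
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test between nested path-model fits
#'
#' @param full Fit with the smaller constraint set (more free parameters).
#' @param reduced Fit whose constraint set contains the full fit's.
#' @return List `chi2`, `df`, `p`.  Constraining one path family across G
#'   groups costs G - 1 degrees of freedom.
#' @export
path_lrt <- function(full, reduced) {
  stopifnot(inherits(full, "path_fit"), inherits(reduced, "path_fit"))
  if (!all(full$constrained %in% reduced$constrained)) {
    stop("models are not nested: the reduced model must carry every ",
         "constraint of the full model", call. = FALSE)
  }
  if (!identical(full$groups, reduced$groups) ||
      !identical(full$n_by_group, reduced$n_by_group)) {
    stop("fits must come from the same data", call. = FALSE)
  }
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$npar - reduced$npar
  p <- if (df == 0L) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Stepwise cross-group equality-constraint selection
#'
#' Starting from the fully group-specific model, repeatedly tries to
#' constrain each still-free parameter family equal across groups,
#' accepts the candidate with the largest likelihood-ratio p-value if it
#' exceeds `alpha_keep`, refits, and repeats until no candidate is
#' acceptable.
#'
#' @inheritParams fit_multigroup
#' @param families Parameter families eligible for constraining.
#' @param alpha_keep A constraint is kept only while its LRT p-value
#'   against the current model exceeds this level (default 0.05).
#' @return List with `fit` (final [fit_multigroup()] object),
#'   `constrained` (accepted families), and `trail` (tibble of every
#'   candidate tested: `step`, `parameter`, `chi2`, `df`, `p`,
#'   `accepted`).
#' @export
stepwise_constrain <- function(data, families = path_families,
                               alpha_keep = 0.05) {
  data <- check_observations(as.data.frame(data))
  ngroups <- length(unique(data$group))
  current <- fit_multigroup(data)
  if (ngroups < 2L) {
    return(list(fit = current, constrained = character(0),
                trail = tibble::tibble(
                  step = integer(0), parameter = character(0),
                  chi2 = numeric(0), df = integer(0), p = numeric(0),
                  accepted = logical(0))))
  }
  kept <- character(0)
  trail <- list()
  step <- 0L
  free <- setdiff(families, kept)
  while (length(free)) {
    step <- step + 1L
    cand <- lapply(free, function(fam) {
      red <- fit_multigroup(data, constrained = c(kept, fam))
      c(list(fam = fam, fit = red), path_lrt(current, red))
    })
    ps <- vapply(cand, `[[`, 1, "p")
    best <- which.max(ps)
    for (i in seq_along(cand)) {
      trail[[length(trail) + 1L]] <- tibble::tibble(
        step = step, parameter = cand[[i]]$fam,
        chi2 = cand[[i]]$chi2, df = cand[[i]]$df, p = cand[[i]]$p,
        accepted = (i == best) && (ps[best] > alpha_keep))
    }
    if (ps[best] > alpha_keep) {
      kept <- c(kept, cand[[best]]$fam)
      current <- cand[[best]]$fit
      free <- setdiff(families, kept)
    } else {
      break
    }
  }
  list(fit = current, constrained = sort(kept),
       trail = dplyr::bind_rows(trail))
}

#' Direct, indirect and total effect of autumn density on summer diversity
#'
#' The direct effect is path `e`; the indirect effect runs through
#' herbicide intensity as `b * c`; the total effect is their sum.
#'
#' @param fit A [fit_multigroup()] object.
#' @param group Treatment group label.
#' @return List `direct`, `indirect`, `total` (unstandardized units).
#' @export
path_effects <- function(fit, group) {
  stopifnot(inherits(fit, "path_fit"))
  if (!group %in% fit$groups) {
    stop("unknown group: ", group, call. = FALSE)
  }
  cf <- fit$coefficients
  pick <- function(pth) cf$estimate[cf$group == group & cf$path == pth]
  b <- pick("b"); cc <- pick("c"); e <- pick("e")
  list(direct = e, indirect = b * cc, total = e + b * cc)
}

#' Total effect from a direct and an indirect component
#'
#' Mediation arithmetic on already-computed components: the total effect
#' of a predictor is its direct effect plus the product-path indirect
#' effect (here `b * c` through herbicide intensity).
#'
#' @param direct Direct-path coefficient (path `e`).
#' @param indirect Indirect effect, i.e. the product `b * c`.
#' @return `direct + indirect`.
#' @examples
#' total_effect(1.21, -0.78)  # 0.43
#' @export
total_effect <- function(direct, indirect) {
  direct + indirect
}

#' R-squared of the endogenous variables per group
#'
#' `1 - residual variance / ML sample variance of the response`, clipped
#' to `[0, 1]`.
#'
#' @param fit A [fit_multigroup()] object.
#' @return Tibble `group`, `response`, `r_squared`.
#' @export
path_r_squared <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  fit$r_squared
}
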