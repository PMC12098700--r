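#' Model specification for the drought panel regression
#'
#' Describes the benchmark regression of plant-month PM2.5 on market drought
#' exposure: outcome, exposure term(s), linear controls, the three absorbed
#' fixed-effect factors (plant, month-by-year, market-by-calendar-month) and
#' the cluster factor for the sandwich covariance.
#'
#' @param outcome Outcome column name (default `"pm25"`).
#' @param exposure Exposure column name(s); the first is the headline
#'   drought coefficient (default `"fhd"`).
#' @param controls Character vector of control column names.
#' @param fe Character vector of fixed-effect factor columns.
#' @param cluster Cluster factor column (default `"market"`).
#' @param sample_flag Logical column selecting the estimation sample, or
#'   `NULL` to use all complete rows.
#' @return A list of class `fhd_model_spec`.
#' @export
fhd_model_spec <- function(outcome = "pm25",
                           exposure = "fhd",
                           controls = c("temp_c", "precip_mm_h", "rh_pct",
                                        "pressure_pa", "wind10_ms",
                                        "wind100_ms", "local_drought",
                                        "hdd", "cdd"),
                           fe = c("plant_id", "month", "market_cm"),
                           cluster = "market",
                           sample_flag = "analysis_sample") {
  structure(list(outcome = outcome, exposure = exposure, controls = controls,
                 fe = fe, cluster = cluster, sample_flag = sample_flag),
            class = "fhd_model_spec")
}

# Iteratively drop observations in fixed-effect levels with one observation;
# such singletons are fit perfectly by their own effect and distort inference.
.drop_singletons <- function(df, fe) {
  dropped <- 0L
  repeat {
    keep <- rep(TRUE, nrow(df))
    for (f in fe) {
      tab <- table(df[[f]])
      keep <- keep & df[[f]] %in% names(tab)[tab > 1L]
    }
    if (all(keep)) break
    dropped <- dropped + sum(!keep)
    df <- df[keep, , drop = FALSE]
    if (!nrow(df)) break
  }
  list(data = df, n_dropped = dropped)
}

# Alternating projections: demean the columns of M within each factor in
# turn until the largest adjustment falls below tol (absolute, on data that
# is centered first so the scale is comparable).
.demean_fe <- function(M, factors, tol = 1e-10, max_sweeps = 10000L) {
  M <- as.matrix(M)
  fs <- lapply(factors, function(f) {
    f <- factor(f)
    list(f = f, n = as.vector(table(f)))
  })
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (ff in fs) {
      gm <- rowsum(M, ff$f, reorder = TRUE) / ff$n
      adj <- gm[as.integer(ff$f), , drop = FALSE]
      M <- M - adj
      delta <- max(delta, max(abs(adj)))
    }
    if (delta < tol) return(list(values = M, sweeps = sweep, converged = TRUE))
  }
  warning("fixed-effect demeaning did not reach tolerance after ",
          max_sweeps, " sweeps (last adjustment ", signif(delta, 3), ")",
          call. = FALSE)
  list(values = M, sweeps = max_sweeps, converged = FALSE)
}

#' Cluster-robust (CR1) sandwich covariance
#'
#' Computes the CR1 sandwich
#' `(X'X)^-1 [ sum_g X_g' e_g e_g' X_g ] (X'X)^-1` scaled by
#' `G/(G-1) * (N-1)/(N-K)`, allowing arbitrary error correlation within each
#' cluster.
#'
#' @param X Design matrix (the regressors whose covariance is wanted; for a
#'   fixed-effects fit, either the full dummy design or the within-demeaned
#'   design).
#' @param resid Residual vector.
#' @param cluster Cluster id vector (length `nrow(X)`), at least two
#'   distinct values.
#' @param K Model degrees of freedom (total number of estimated parameters,
#'   including absorbed fixed effects); defaults to `ncol(X)`.
#' @return Covariance matrix for the coefficients of `X`.
#' @export
cluster_vcov <- function(X, resid, cluster, K = ncol(X)) {
  X <- as.matrix(X)
  G <- length(unique(cluster))
  if (G < 2L) {
    stop("only one cluster: cluster-robust inference is undefined ",
         "(a wild cluster bootstrap would be needed)", call. = FALSE)
  }
  N <- nrow(X)
  # column scaling for numerical stability (regressor units differ by
  # orders of magnitude); V is invariant to it
  s <- sqrt(colSums(X^2))
  s[s == 0] <- 1
  Xs <- sweep(X, 2L, s, "/")
  bread <- solve(crossprod(Xs))
  scores <- rowsum(Xs * resid, cluster)
  meat <- crossprod(scores)
  adj <- (G / (G - 1)) * ((N - 1) / (N - K))
  V <- adj * (bread %*% meat %*% bread) / tcrossprod(s)
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Fit the multi-way fixed-effects drought regression
#'
#' Ordinary least squares of the outcome on the exposure(s) and controls,
#' absorbing plant, month-by-year and market-by-calendar-month fixed
#' effects, with CR1 market-clustered standard errors.  Small samples
#' (up to `dummy_threshold` rows) are solved exactly on the full dummy
#' design; larger samples use alternating-projections demeaning (tolerance
#' 1e-10), whose coefficients agree with the dummy solution by the
#' Frisch-Waugh-Lovell theorem.
#'
#' @param panel Panel data frame (see [assemble_panel()]).
#' @param spec A [fhd_model_spec()].
#' @param dummy_threshold Row count at or below which the exact
#'   dummy-variable solve is used.
#' @param demean_tol,max_sweeps Convergence controls for the demeaning
#'   route.
#' @return An object of class `fhd_fit`: coefficients for exposure and
#'   controls, CR1 `vcov`, `se`, `t`, `p` (two-sided t with G-1 degrees of
#'   freedom), `n_obs`, `n_clusters`, `n_dropped_singletons`, `residuals`,
#'   `baseline_prediction` (sample-mean prediction at zero exposure) and
#'   bookkeeping fields.
#' @export
fit_fe_ols <- function(panel, spec = fhd_model_spec(),
                       dummy_threshold = 5000L,
                       demean_tol = 1e-10, max_sweeps = 10000L) {
  stopifnot(inherits(spec, "fhd_model_spec"))
  cols <- c(spec$outcome, spec$exposure, spec$controls, spec$fe, spec$cluster)
  miss <- setdiff(cols, names(panel))
  if (length(miss)) stop("panel is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- tibble::as_tibble(panel)
  if (!is.null(spec$sample_flag)) {
    df <- df[df[[spec$sample_flag]] %in% TRUE, ]
  }
  df <- df[stats::complete.cases(df[, cols]), ]
  sing <- .drop_singletons(df, spec$fe)
  df <- sing$data
  if (!nrow(df)) stop("no observations left after sample selection", call. = FALSE)
  cl <- df[[spec$cluster]]
  if (length(unique(cl)) < 2L) {
    stop("cluster factor has fewer than 2 levels in the sample", call. = FALSE)
  }

  y <- df[[spec$outcome]]
  rhs <- c(spec$exposure, spec$controls)
  Xr <- as.matrix(df[, rhs, drop = FALSE])

  # a regressor with no variation within the fixed-effect groups is
  # absorbed; report it by name rather than silently dropping it
  chk <- suppressWarnings(.demean_fe(Xr, lapply(spec$fe, function(f) df[[f]]),
                                     tol = 1e-8, max_sweeps = 50L))
  chk_sds <- apply(chk$values, 2L, stats::sd)
  orig_sds <- pmax(apply(Xr, 2L, stats::sd), .Machine$double.eps)
  absorbed_chk <- chk_sds < 1e-6 * orig_sds
  if (any(absorbed_chk)) {
    stop("regressor absorbed by the fixed effects (no within variation): ",
         paste(rhs[absorbed_chk], collapse = ", "), call. = FALSE)
  }

  if (nrow(df) <= dummy_threshold) {
    fe_terms <- paste0("factor(", spec$fe, ")", collapse = " + ")
    mm <- stats::model.matrix(
      stats::as.formula(paste("~", fe_terms)), data = df)
    Xfull <- cbind(Xr, mm)
    qr_x <- qr(Xfull, LAPACK = FALSE)
    K <- qr_x$rank
    # drop aliased columns so the sandwich bread is invertible
    keep <- qr_x$pivot[seq_len(K)]
    Xuse <- Xfull[, keep, drop = FALSE]
    fit <- stats::lm.fit(Xuse, y)
    beta_all <- fit$coefficients
    resid <- fit$residuals
    b <- beta_all[rhs]
    if (anyNA(b)) {
      stop("exposure or control collinear with the fixed effects: ",
           paste(rhs[is.na(b)], collapse = ", "), call. = FALSE)
    }
    V_all <- cluster_vcov(Xuse, resid, cl, K = K)
    V <- V_all[rhs, rhs, drop = FALSE]
    route <- "dummy"
    sweeps <- NA_integer_
  } else {
    factors <- lapply(spec$fe, function(f) df[[f]])
    dm <- .demean_fe(cbind(y = y, Xr), factors,
                     tol = demean_tol, max_sweeps = max_sweeps)
    yd <- dm$values[, 1L]
    Xd <- dm$values[, -1L, drop = FALSE]
    sds <- apply(Xd, 2L, stats::sd)
    orig_sds <- pmax(apply(Xr, 2L, stats::sd), .Machine$double.eps)
    absorbed <- sds < 1e-8 * orig_sds
    if (any(absorbed)) {
      stop("regressor absorbed by the fixed effects (no within variation): ",
           paste(rhs[absorbed], collapse = ", "), call. = FALSE)
    }
    fit <- stats::lm.fit(Xd, yd)
    b <- fit$coefficients
    resid <- fit$residuals
    K <- .fe_dof(df, spec) + length(rhs)
    V <- cluster_vcov(Xd, resid, cl, K = K)
    V <- V[rhs, rhs, drop = FALSE]
    route <- "demean"
    sweeps <- dm$sweeps
  }

  G <- length(unique(cl))
  se <- sqrt(diag(V))
  tval <- b / se
  pval <- 2 * stats::pt(abs(tval), df = G - 1, lower.tail = FALSE)
  expo_means <- colMeans(as.matrix(df[, spec$exposure, drop = FALSE]))
  baseline <- mean(y) - sum(b[spec$exposure] * expo_means)

  structure(list(
    coefficients = b, vcov = V, se = se, t = tval, p = pval,
    df = G - 1L, n_obs = nrow(df), n_clusters = G,
    n_dropped_singletons = sing$n_dropped,
    residuals = resid, baseline_prediction = unname(baseline),
    exposure = spec$exposure, controls = spec$controls,
    exposure_means = expo_means,
    spec = spec, route = route, sweeps = sweeps, K = K,
    sample_index = df[, intersect(c("plant_id", "month"), names(df))]
  ), class = "fhd_fit")
}

# Degrees of freedom absorbed by the FE triple (plant, month-year,
# market-calendar-month): the span of the three dummy blocks loses two
# global constants plus one market-level redundancy per market beyond the
# first, because market indicators lie in the span of both the plant and the
# market-month blocks.  Exact for connected designs; used only on the
# demeaning route (the dummy route takes the QR rank).
.fe_dof <- function(df, spec) {
  L <- vapply(spec$fe, function(f) length(unique(df[[f]])), integer(1))
  n_markets <- length(unique(df[[spec$cluster]]))
  standard <- identical(sort(spec$fe), sort(c("plant_id", "month", "market_cm")))
  if (standard) sum(L) - 2L - (n_markets - 1L) else sum(L) - (length(L) - 1L)
}

#' @export
print.fhd_fit <- function(x, ...) {
  cat(sprintf("Fixed-effects drought regression (%s route)\n", x$route))
  cat(sprintf("  N = %d, clusters = %d, singletons dropped = %d\n",
              x$n_obs, x$n_clusters, x$n_dropped_singletons))
  print(results_table(x), n = Inf)
  cat(sprintf("  baseline prediction (exposure = 0): %.3f\n",
              x$baseline_prediction))
  invisible(x)
}

#' Tidy coefficient table for a fitted drought regression
#'
#' @param fit An `fhd_fit`.
#' @param conf_level Confidence level for the t-interval (G-1 df).
#' @return Tibble with `term`, `estimate`, `se`, `t`, `p`, `ci_low`,
#'   `ci_high`, `n_obs`, `n_clusters`.
#' @export
results_table <- function(fit, conf_level = 0.95) {
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df)
  tibble::tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$se),
    t = unname(fit$t),
    p = unname(fit$p),
    ci_low = unname(fit$coefficients - crit * fit$se),
    ci_high = unname(fit$coefficients + crit * fit$se),
    n_obs = fit$n_obs,
    n_clusters = fit$n_clusters
  )
}

#' Dose-response model: drought exposure in ordered bins
#'
#' Replaces the continuous exposure with indicator variables for the bins
#' `[0.25, 0.5)`, `[0.5, 0.75)` and `[0.75, 1]`; the reference group is
#' exposure below 0.25.  Coefficients are relative to the reference bin.
#'
#' @inheritParams fit_fe_ols
#' @param breaks Interior bin breaks (default `c(0.25, 0.5, 0.75)`).
#' @param ... Passed to [fit_fe_ols()].
#' @return An `fhd_fit` whose exposure terms are the non-reference bins,
#'   with a `bins` attribute holding occupancy and mean exposure per bin.
#' @export
dose_response <- function(panel, spec = fhd_model_spec(),
                          breaks = c(0.25, 0.5, 0.75), ...) {
  expo <- spec$exposure[1L]
  df <- tibble::as_tibble(panel)
  all_breaks <- c(0, breaks, Inf)
  labs <- paste0(expo, "_bin", seq_len(length(breaks) + 1L))
  bin <- cut(df[[expo]], breaks = all_breaks, labels = labs,
             right = FALSE, include.lowest = TRUE)
  sel <- if (!is.null(spec$sample_flag)) df[[spec$sample_flag]] %in% TRUE else TRUE
  occ <- table(bin[sel & !is.na(df[[expo]])])
  if (any(occ[-1L] == 0L) || occ[1L] == 0L) {
    stop("empty dose-response bin; occupancy: ",
         paste(names(occ), occ, sep = "=", collapse = ", "), call. = FALSE)
  }
  for (j in 2:length(labs)) df[[labs[j]]] <- as.numeric(bin == labs[j])
  spec2 <- spec
  spec2$exposure <- labs[-1L]
  fit <- fit_fe_ols(df, spec2, ...)
  means <- tapply(df[[expo]][sel], bin[sel], mean)
  attr(fit, "bins") <- tibble::tibble(bin = names(occ),
                                      n = as.integer(occ),
                                      mean_exposure = as.vector(means))
  fit
}

#' Heterogeneous drought effects by plant subgroup
#'
#' Augments the benchmark model with interactions between the exposure and a
#' plant subgroup factor (plant size class at the 30 MW cut, or fuel type)
#' and reports the marginal drought effect for each subgroup, with pairwise
#' difference tests against the reference subgroup from the cluster-robust
#' covariance.
#'
#' @inheritParams fit_fe_ols
#' @param group `"size30"` (indicator for capacity >= 30 MW), `"fuel"`, or
#'   the name of a factor column in the panel.
#' @param ... Passed to [fit_fe_ols()].
#' @return A list with `effects` (tibble: `group`, `level`, `estimate`,
#'   `se`, `t`, `p`, `n`), `difference_tests` (each non-reference level vs
#'   the reference) and the underlying `fit`.
#' @export
heterogeneous_effects <- function(panel, spec = fhd_model_spec(),
                                  group = c("size30", "fuel"), ...) {
  if (length(group) > 1L) group <- match.arg(group)
  df <- tibble::as_tibble(panel)
  expo <- spec$exposure[1L]
  if (group == "size30") {
    df$.group <- factor(ifelse(df$capacity_mw >= 30, "ge30MW", "lt30MW"),
                        levels = c("lt30MW", "ge30MW"))
  } else if (group == "fuel") {
    df$.group <- factor(df$fuel)
  } else {
    df$.group <- factor(df[[group]])
  }
  levs <- levels(droplevels(df$.group))
  if (length(levs) < 2L) stop("subgroup factor has a single level", call. = FALSE)
  sel <- if (!is.null(spec$sample_flag)) df[[spec$sample_flag]] %in% TRUE else TRUE
  for (l in levs[-1L]) {
    df[[paste0(expo, ":", l)]] <- df[[expo]] * (df$.group == l)
  }
  spec2 <- spec
  spec2$exposure <- c(expo, paste0(expo, ":", levs[-1L]))
  fit <- fit_fe_ols(df, spec2, ...)
  b <- fit$coefficients[spec2$exposure]
  V <- fit$vcov[spec2$exposure, spec2$exposure]
  Lmat <- cbind(1, rbind(0, diag(length(levs) - 1L)))  # level effects = base + interaction
  eff <- as.vector(Lmat %*% b)
  eff_se <- sqrt(diag(Lmat %*% V %*% t(Lmat)))
  n_by <- table(droplevels(df$.group[sel]))
  effects <- tibble::tibble(
    group = group, level = levs, estimate = eff, se = eff_se,
    t = eff / eff_se,
    p = 2 * stats::pt(abs(eff / eff_se), df = fit$df, lower.tail = FALSE),
    n = as.integer(n_by[levs])
  )
  dt <- results_table(fit)
  diffs <- dt[dt$term %in% paste0(expo, ":", levs[-1L]), ]
  diffs$comparison <- paste(levs[-1L], "vs", levs[1L])
  list(effects = effects, difference_tests = diffs, fit = fit)
}

#' Implied total PM2.5 at a given drought exposure
#'
#' The predicted PM2.5 level in the absence of drought (the fit's baseline
#' prediction) plus the marginal effect of the exposure.
#'
#' @param fit An `fhd_fit` (or a list with `baseline_prediction` and a
#'   headline coefficient as produced by [fit_fe_ols()]).
#' @param fhd_value Exposure value in `[0, 1]`.
#' @return Implied total concentration (ug/m3).
#' @export
implied_total <- function(fit, fhd_value) {
  stopifnot(all(fhd_value >= 0 & fhd_value <= 1))
  beta <- unname(fit$coefficients[fit$exposure[1L]])
  fit$baseline_prediction + beta * fhd_value
}

#' Placebo regressions
#'
#' Re-estimates the benchmark model on samples where no generation-shift
#' effect should exist: PM2.5 around non-combustion plants (wind, solar,
#' geothermal, nuclear) with no combustion plant within the dispersion
#' radius, or combustion plant-months in years strictly before the
#' commissioning year.
#'
#' @param panel For `"non_combustion"`, a panel assembled over the
#'   non-combustion registry; for `"pre_operational"`, the combustion panel.
#' @param mode `"non_combustion"` or `"pre_operational"`.
#' @param spec A [fhd_model_spec()]; its sample flag is replaced by the
#'   placebo selection rule.
#' @param combustion_plants For `"non_combustion"`: data frame of combustion
#'   plants (`plant_id`, `lon`, `lat`) used to exclude placebo plants with a
#'   combustion plant within `radius_km`.
#' @param radius_km Exclusion radius for nearby combustion plants (km).
#' @param ... Passed to [fit_fe_ols()].
#' @return An `fhd_fit` on the placebo sample.
#' @export
placebo_run <- function(panel, mode = c("non_combustion", "pre_operational"),
                        spec = fhd_model_spec(), combustion_plants = NULL,
                        radius_km = 50, ...) {
  mode <- match.arg(mode)
  df <- tibble::as_tibble(panel)
  if (mode == "pre_operational") {
    df$placebo_sample <- df$year < df$commissioning_year &
      !df$fire_within & df$market_has_hydro & !is.na(df$fhd)
  } else {
    if (is.null(combustion_plants)) {
      stop("combustion_plants required for the non-combustion placebo",
           call. = FALSE)
    }
    # nearest combustion plant distance per placebo plant
    ppos <- attr(panel, "plant_coords")
    if (is.null(ppos)) {
      stop("panel lacks a 'plant_coords' attribute (plant_id, lon, lat) ",
           "needed to screen nearby combustion plants", call. = FALSE)
    }
    keep_ids <- vapply(seq_len(nrow(ppos)), function(i) {
      d <- geosphere::distHaversine(
        cbind(combustion_plants$lon, combustion_plants$lat),
        c(ppos$lon[i], ppos$lat[i])) / 1000
      min(d) > radius_km
    }, logical(1))
    ok <- ppos$plant_id[keep_ids]
    df$placebo_sample <- df$plant_id %in% ok & df$operational &
      !df$fire_within & df$market_has_hydro & !is.na(df$fhd)
  }
  if (!any(df$placebo_sample)) stop("empty placebo sample", call. = FALSE)
  spec2 <- spec
  spec2$sample_flag <- "placebo_sample"
  fit_fe_ols(df, spec2, ...)
}
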