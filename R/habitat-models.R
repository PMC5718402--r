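# Additive mixed habitat models: each daily foraging index is regressed on
# standardized bathymetry and SST via penalized-regression-spline smooths
# (optionally class-specific), with Gaussian random intercepts for animal and
# trip, fitted with mgcv. Candidate models (all combinations of the smooth
# terms) are ranked by AIC; among candidates within 2 AIC units the model
# with fewest terms wins.

#' Standardize covariate columns (z-scores) with a stored transform
#'
#' @param data data.frame
#' @param cols columns to standardize
#' @return `data` with the columns replaced by z-scores; attribute
#'   `standardize_transform` holds per-column center/scale for inversion via
#'   [unstandardize()].
#' @export
standardize <- function(data, cols) {
  tr <- list()
  for (v in cols) {
    x <- data[[v]]
    if (!all(is.finite(x))) stop("non-finite values in ", v)
    s <- stats::sd(x)
    if (s == 0) stop("covariate ", v, " is constant; cannot standardize")
    tr[[v]] <- c(center = mean(x), scale = s)
    data[[v]] <- (x - mean(x)) / s
  }
  attr(data, "standardize_transform") <- tr
  data
}

#' Invert a stored standardization for one column
#' @param z standardized values
#' @param transform the `standardize_transform` attribute
#' @param col column name
#' @export
unstandardize <- function(z, transform, col) {
  z * transform[[col]]["scale"] + transform[[col]]["center"]
}

#' Pairwise collinearity screen
#'
#' @param data data.frame of covariates
#' @param cols columns to check
#' @param threshold maximum tolerated absolute Pearson correlation
#' @return list: pass (all |r| <= threshold), pairs (data.frame of all pairs
#'   with their correlations), offending (subset failing)
#' @export
check_collinearity <- function(data, cols, threshold = 0.8) {
  if (length(cols) < 2) stop("need at least 2 covariates")
  cm <- stats::cor(data[, cols])
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(var1 = cols[idx[, 1]], var2 = cols[idx[, 2]],
                      r = cm[idx])
  off <- pairs[abs(pairs$r) > threshold, ]
  list(pass = nrow(off) == 0, pairs = pairs, offending = off)
}

#' Define a habitat-model specification
#'
#' @param response response column name (a daily foraging index)
#' @param smooths character subset of the covariates to enter as smooths
#' @param by_class if TRUE each smooth is fitted per age/sex class (requires
#'   >1 class) and a class main effect is included
#' @param k basis dimension per smooth
#' @return object of class `habitat_spec`
#' @export
habitat_spec <- function(response, smooths = character(), by_class = FALSE,
                         k = 5) {
  structure(list(response = response, smooths = smooths, by_class = by_class,
                 k = k), class = "habitat_spec")
}

#' All combinations of smooth terms for a response
#'
#' @param response response column name
#' @param covariates covariates available as smooths
#' @inheritParams habitat_spec
#' @return list of `habitat_spec`s (power set of the smooth terms, including
#'   the intercept-plus-random-effects null model)
#' @export
enumerate_habitat_specs <- function(response,
                                    covariates = c("bathymetry_m", "sst_C"),
                                    by_class = FALSE, k = 5) {
  specs <- list()
  for (m in 0:(2^length(covariates) - 1)) {
    sel <- covariates[bitwAnd(m, 2^(seq_along(covariates) - 1)) > 0]
    specs[[m + 1]] <- habitat_spec(response, sel, by_class = by_class, k = k)
  }
  specs
}

#' Fit an additive mixed habitat model
#'
#' Gaussian additive model with penalized-regression-spline smooths for the
#' requested covariates (per class when `by_class`), random intercepts for
#' animal and trip (`bs = "re"`), fitted by maximum likelihood so AICs are
#' comparable across fixed-effect structures.
#'
#' @param table daily modelling table with the response, standardized
#'   covariates, `class`, `animal_id`, `trip_id`
#' @param spec a [habitat_spec()]
#' @return object of class `gamm_fit`: spec, mgcv model, aic, adj_r2,
#'   n_params (count of model terms: intercept + class effect + smooths)
#' @export
fit_gamm <- function(table, spec) {
  stopifnot(inherits(spec, "habitat_spec"))
  table$animal_id <- factor(table$animal_id)
  table$trip_id <- factor(table$trip_id)
  table$class <- factor(table$class)
  if (spec$by_class && nlevels(table$class) < 2)
    stop("class-specific smooths need more than one class")
  rhs <- c("1")
  if (spec$by_class) rhs <- c(rhs, "class")
  for (v in spec$smooths)
    rhs <- c(rhs, if (spec$by_class)
      sprintf("s(%s, k = %d, by = class)", v, spec$k)
      else sprintf("s(%s, k = %d)", v, spec$k))
  n_params <- length(rhs)
  if (nlevels(table$animal_id) > 1) rhs <- c(rhs, 's(animal_id, bs = "re")')
  if (nlevels(table$trip_id) > 1) rhs <- c(rhs, 's(trip_id, bs = "re")')
  form <- stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
  m <- mgcv::gam(form, data = table, method = "ML")
  structure(list(spec = spec, model = m, aic = stats::AIC(m),
                 adj_r2 = summary(m)$r.sq, n_params = n_params),
            class = "gamm_fit")
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat("<gamm_fit>", x$spec$response, "~",
      if (length(x$spec$smooths)) paste(x$spec$smooths, collapse = " + ")
      else "1",
      sprintf("| AIC %.2f, adj-R2 %.3f, %d terms\n", x$aic, x$adj_r2,
              x$n_params))
  invisible(x)
}

#' Extract a fitted smooth curve with pointwise CIs
#'
#' @param fit a `gamm_fit`
#' @param covariate covariate name
#' @param n grid size
#' @param class class level for by-class smooths (default first level)
#' @return data.frame: x (standardized scale), fit, se
#' @export
smooth_curve <- function(fit, covariate, n = 100, class = NULL) {
  dat <- fit$model$model
  xr <- range(dat[[covariate]])
  nd <- data.frame(x = seq(xr[1], xr[2], length.out = n))
  names(nd) <- covariate
  for (v in setdiff(names(dat), c(covariate, fit$spec$response)))
    nd[[v]] <- if (is.factor(dat[[v]])) {
      if (!is.null(class) && v == "class")
        factor(class, levels = levels(dat[[v]]))
      else factor(levels(dat[[v]])[1], levels = levels(dat[[v]]))
    } else mean(dat[[v]])
  pr <- stats::predict(fit$model, nd, type = "terms", se.fit = TRUE)
  keep <- grep(paste0("s\\(", covariate), colnames(pr$fit))
  if (!length(keep)) keep <- grep(covariate, colnames(pr$fit))
  data.frame(x = nd[[covariate]],
             fit = rowSums(pr$fit[, keep, drop = FALSE]),
             se = sqrt(rowSums(pr$se.fit[, keep, drop = FALSE]^2)))
}

#' AIC-based model selection with a parsimony rule
#'
#' Candidates are fits within 2 AIC units of the best; among candidates the
#' one with the fewest model terms is selected (ties broken by lower AIC,
#' then by the lexicographic order of the smooth-term signature).
#'
#' @param fits list of `gamm_fit`s
#' @return the selected `gamm_fit`; attribute `ranking` holds the AIC table
#' @export
select_model <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  npar <- vapply(fits, function(f) f$n_params, numeric(1))
  sig <- vapply(fits, function(f) paste(sort(f$spec$smooths), collapse = "+"),
                character(1))
  cand <- which(aic - min(aic) < 2)
  ord <- cand[order(npar[cand], aic[cand], sig[cand])]
  best <- fits[[ord[1]]]
  attr(best, "ranking") <- data.frame(terms = sig, aic = aic,
                                      delta_aic = aic - min(aic),
                                      n_params = npar,
                                      candidate = seq_along(fits) %in% cand)
  best
}
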