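# PCA-based vertical foraging-intensity index. Descent and ascent rates are
# standardized and combined on the first principal axis (oriented so both
# loadings are positive: high scores = fast transit both ways = likely
# feeding at depth). Because lung air dominates buoyancy above ~100 m, each
# dive's score is weighted by a nonlinear function of its mean transit depth:
# 0 at the surface rising to 1 at 100 m and beyond.

#' Fit the transit-rate PCA
#'
#' @param rates data.frame from [compute_transit_rates()] with descent_rate
#'   and ascent_rate
#' @return object of class `transit_pca`: means, sds, loadings (axis 1,
#'   unit norm, both positive), variance_explained
#' @export
fit_transit_pca <- function(rates) {
  if (nrow(rates) < 10) stop("need at least 10 dives with finite rates")
  for (v in c("descent_rate", "ascent_rate"))
    if (stats::sd(rates[[v]]) == 0)
      stop("zero variance in ", v, "; PCA is degenerate")
  pc <- stats::prcomp(rates[, c("descent_rate", "ascent_rate")],
                      center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  # deterministic orientation: descent loading positive (both loadings end up
  # positive whenever the rates correlate positively, the realistic case)
  if (load1[["descent_rate"]] < 0) load1 <- -load1
  structure(list(means = pc$center, sds = pc$scale, loadings = load1,
                 variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2)),
            class = "transit_pca")
}

#' Score dives on the fitted first principal axis
#'
#' @param model a `transit_pca`
#' @param rates data.frame with descent_rate, ascent_rate
#' @return numeric PC1 score per dive (0 at the variable means)
#' @export
transit_score <- function(model, rates) {
  z <- sweep(sweep(as.matrix(rates[, c("descent_rate", "ascent_rate")]),
                   2, model$means), 2, model$sds, "/")
  as.numeric(z %*% model$loadings)
}

#' Nonlinear transit-depth weighting
#'
#' Weight 0 at 0 m rising monotonically to 1 at 100 m and beyond; default is
#' a quadratic ramp `(d/100)^exponent` with exponent 2, the simplest smooth
#' monotone curve through both endpoints (the exponent is configurable, and
#' any custom monotone curve can be supplied).
#'
#' @param depth_m mean transit depth, m (>= 0)
#' @param ref_depth_m depth at which the weight saturates at 1
#' @param exponent power of the ramp
#' @param curve optional function depth -> weight overriding the ramp below
#'   `ref_depth_m`
#' @return weights in `[0, 1]`
#' @export
depth_weight <- function(depth_m, ref_depth_m = 100, exponent = 2,
                         curve = NULL) {
  if (any(depth_m < 0)) stop("negative transit depth")
  w <- if (is.null(curve)) (depth_m / ref_depth_m)^exponent
       else curve(depth_m)
  pmin(w, 1)
}

#' Daily transit foraging index per animal UTC day
#'
#' Depth-weighted PC1 scores averaged within each day. The default divides
#' the summed weighted scores by the number of dives; `variant = "weighted"`
#' divides by the summed weights instead.
#'
#' @param scored data.frame with animal_id, start_time (or day), score,
#'   weight
#' @param variant "count" (sum(w*s)/n) or "weighted" (sum(w*s)/sum(w))
#' @return data.frame: animal_id, day, transit_index, n_dives
#' @export
daily_transit_index <- function(scored, variant = c("count", "weighted")) {
  variant <- match.arg(variant)
  day <- if ("day" %in% names(scored)) as.Date(scored$day)
         else as.Date(scored$start_time, tz = "UTC")
  ws <- scored$weight * scored$score
  num <- stats::aggregate(ws, by = list(animal_id = scored$animal_id, day = day),
                          FUN = sum)
  den <- stats::aggregate(if (variant == "count") rep(1, nrow(scored))
                          else scored$weight,
                          by = list(animal_id = scored$animal_id, day = day),
                          FUN = sum)
  out <- num
  # a day whose weights all vanish (all near-surface dives) gets index 0
  # under the count variant and NA under the weighted variant
  out$x <- ifelse(den$x > 0, num$x / den$x,
                  if (variant == "count") 0 else NA_real_)
  names(out)[3] <- "transit_index"
  cnt <- stats::aggregate(rep(1, nrow(scored)),
                          by = list(animal_id = scored$animal_id, day = day),
                          FUN = sum)
  out$n_dives <- cnt$x
  out[order(out$animal_id, out$day), ]
}
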