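# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive step-by-step logic and share
# no code with the functions they verify.

# FPT by explicit segment walking: for the circle centred at point i, walk
# forward segment by segment until the distance first exceeds r (linear
# interpolation on the crossing segment), and likewise backward.
oracle_fpt <- function(points, r) {
  n <- nrow(points)
  t_hr <- as.numeric(points$time) / 3600
  d_ij <- function(i, j) gc_dist_km(points$lon[i], points$lat[i],
                                    points$lon[j], points$lat[j])
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    t_exit <- NA
    if (i < n) for (j in (i + 1):n) {
      dj <- d_ij(i, j)
      if (dj > r) {
        dp <- d_ij(i, j - 1)
        f <- (r - dp) / (dj - dp)
        t_exit <- t_hr[j - 1] + f * (t_hr[j] - t_hr[j - 1])
        break
      }
    }
    t_entry <- NA
    if (i > 1) for (j in (i - 1):1) {
      dj <- d_ij(i, j)
      if (dj > r) {
        dp <- d_ij(i, j + 1)
        f <- (r - dp) / (dj - dp)
        t_entry <- t_hr[j + 1] - f * (t_hr[j + 1] - t_hr[j])
        break
      }
    }
    if (!is.na(t_exit) && !is.na(t_entry)) out[i] <- t_exit - t_entry
  }
  out
}

# group-by daily mean via an explicit loop over unique keys
oracle_daily_mean <- function(id, day, value) {
  keys <- unique(data.frame(id = id, day = day))
  keys <- keys[order(keys$id, keys$day), ]
  keys$mean <- NA_real_
  for (k in seq_len(nrow(keys))) {
    sel <- id == keys$id[k] & day == keys$day[k]
    keys$mean[k] <- sum(value[sel]) / sum(sel)
  }
  keys
}

# Mann-Whitney U by explicit pairwise comparison
oracle_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# random short track for oracle comparisons
random_track <- function(n = 50, seed = 1) {
  set.seed(seed)
  data.frame(time = as.POSIXct("2008-01-01", tz = "UTC") +
               cumsum(runif(n, 1800, 7200)),
             lon = cumsum(rnorm(n, 0.03, 0.08)),
             lat = 70 + cumsum(rnorm(n, -0.01, 0.04)))
}
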