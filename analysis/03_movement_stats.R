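#!/usr/bin/env Rscript
# Trip-level movement descriptors and class comparisons: overall azimuth per
# trip, Rayleigh test of directional randomness, and Wilcoxon-Mann-Whitney
# comparisons of dive depth between classes.

suppressMessages(library(sealforage))

tracks <- read_srdl_csv("results/tracks.csv")
trips <- read_srdl_csv("results/trips.csv")
dives <- read_srdl_csv("results/data/dives.csv")

summ <- do.call(rbind, lapply(seq_len(nrow(trips)), function(k) {
  ti <- trips[k, ]
  pts <- tracks[!is.na(tracks$trip_id) & tracks$trip_id == ti$trip_id, ]
  if (nrow(pts) < 2) return(NULL)
  cbind(trip_id = ti$trip_id, animal_id = ti$animal_id, class = ti$class,
        season = ti$season, trip_summary(pts, complete = ti$complete))
}))
utils::write.csv(summ, "results/trip_summaries.csv", row.names = FALSE)

rt <- rayleigh_test(summ$azimuth_deg)
cat("Trips summarized:", nrow(summ), "(", sum(summ$complete), "complete )\n")
cat(sprintf("Mean trip azimuth %.0f deg; Rayleigh R-bar = %.2f, p = %.3g -> %s\n",
            (atan2(mean(summ$sin_azimuth), mean(summ$cos_azimuth)) * 180 / pi) %% 360,
            rt$r_bar, rt$p_value,
            if (rt$p_value < 0.05) "directed migration" else "no preferred direction"))

cmp <- list()
for (pair in list(c("pup", "female"), c("pup", "male"), c("female", "male"))) {
  a <- dives$max_depth[dives$class == pair[1]]
  b <- dives$max_depth[dives$class == pair[2]]
  if (!length(a) || !length(b)) next
  g <- group_compare(a, b)
  cmp[[length(cmp) + 1]] <- data.frame(group_a = pair[1], group_b = pair[2],
                                       parameter = "max_depth",
                                       U = g$statistic, p_value = g$p_value,
                                       method = g$method)
  cat(sprintf("Max depth, %s vs %s: U = %.0f, p = %.3g\n",
              pair[1], pair[2], g$statistic, g$p_value))
}
utils::write.csv(do.call(rbind, cmp), "results/class_comparisons.csv",
                 row.names = FALSE)
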