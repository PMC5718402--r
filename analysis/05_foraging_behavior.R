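#!/usr/bin/env Rscript
# Diving behaviour inside important foraging areas: flag days above the 75%
# FPT quantile and report the daily mean maximum depth and its ratio to
# bathymetry per class (benthic vs pelagic foraging).

suppressMessages(library(sealforage))

daily <- read_srdl_csv("results/daily.csv")
fl <- foraging_days(data.frame(animal_id = daily$animal_id, day = daily$day,
                               mean_fpt_hr = daily$mean_fpt_hr))
cat(sprintf("75%% daily-FPT quantile: %.2f hr (%.2f days); %d of %d days flagged\n",
            attr(fl, "threshold"), attr(fl, "threshold") / 24,
            sum(fl$foraging), nrow(fl)))

dd <- data.frame(animal_id = daily$animal_id, day = daily$day,
                 mean_max_depth = daily$mean_max_depth)
de <- data.frame(animal_id = daily$animal_id, day = daily$day,
                 bathymetry_m = daily$bathymetry_m)
fb <- foraging_dive_behavior(dd, de, fl)
fb$class <- daily$class[match(paste(fb$animal_id, fb$day),
                              paste(daily$animal_id, daily$day))]
utils::write.csv(fb, "results/foraging_dive_behavior.csv", row.names = FALSE)

for (cl in unique(fb$class))
  cat(sprintf("%-7s foraging days: mean max depth %.0f m, depth/bathymetry %.2f\n",
              cl, mean(fb$mean_max_depth[fb$class == cl]),
              mean(fb$depth_over_bathymetry[fb$class == cl])))
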