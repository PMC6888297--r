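#!/usr/bin/env Rscript
## Bistability of the AMPK-mTOR toggle: a one-parameter steady-state
## scan over the stress input S, the forward/backward hysteresis sweep,
## and the reduced AMPK-mTOR phase plane with nullclines inside and
## outside the bistable window.

library(ampkswitch)

dir.create("results", showWarnings = FALSE)

defaults <- default_parameters()

sc <- scan_parameter("S", c(0.5, 3), n_points = 26, params = defaults,
                     n_starts = 20, seed = 1)
bifurcation_table(sc, "results/bifurcation_S.csv")
cat("bistable interval brackets (grid resolution):\n")
print(sc$bistable_intervals)

hy <- hysteresis_scan("S", c(0.5, 3), n_points = 21, params = defaults)
utils::write.csv(hy, "results/hysteresis_S.csv", row.names = FALSE)
fw <- hy[hy$direction == "forward", ]
bw <- hy[hy$direction == "backward", ]
dis <- fw$value[abs(fw$M - bw$M) > 0.2]
cat(sprintf("forward/backward branch disagreement for S in [%.2f, %.2f]\n",
            min(dis), max(dis)))

for (s in c(1.0, 1.8)) {
  p <- defaults
  p$S <- s
  nc <- nullclines(p, n_grid = 80)
  tag <- gsub("\\.", "p", sprintf("S%.1f", s))
  utils::write.csv(nc$A_nullcline,
                   sprintf("results/nullcline_A_%s.csv", tag),
                   row.names = FALSE)
  utils::write.csv(nc$M_nullcline,
                   sprintf("results/nullcline_M_%s.csv", tag),
                   row.names = FALSE)
  cat(sprintf("S = %.1f: %d intersection(s), %d stable; QSS time-scale ratio %.2f\n",
              s, nrow(nc$intersections), sum(nc$intersections$stable),
              nc$qss_timescale_ratio))
}

grDevices::pdf("results/bifurcation_S.pdf", width = 6, height = 4)
plot_bifurcation(sc, species = "M")
grDevices::dev.off()
cat("wrote results/bifurcation_S.csv, hysteresis_S.csv, nullcline_*.csv\n")
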