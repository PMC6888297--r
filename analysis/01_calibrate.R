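#!/usr/bin/env Rscript
## Verify the shipped calibrated parameter set against the qualitative
## constraint battery: the 16-scenario phenotype matrix, physiological
## monostability (mTOR on, AMPK/ULK1/ATG off at S = 1), the variant
## contrasts that motivate the mTOR -| AMPK edge, and the existence of a
## bistable window in the stress input. Re-running the calibration
## operation from the shipped set with a small refinement budget must
## terminate immediately at zero violations.

library(ampkswitch)

dir.create("results", showWarnings = FALSE)

defaults <- default_parameters()
score <- calibration_score(defaults)
cat(sprintf("constraint battery at shipped defaults: score = %g\n",
            score$score))
if (length(score$violations)) {
  cat("violations:\n"); print(score$violations)
} else {
  cat("no violations: the shipped defaults satisfy every constraint\n")
}

cal <- calibrate_parameters(start = defaults, free = character(), budget = 2)
cat(sprintf("calibrate_parameters from shipped set: score %g after %d evaluations\n",
            cal$score, cal$evaluations))

jsonlite::write_json(
  list(score = score$score,
       n_violations = length(score$violations),
       matrix_matched = score$matrix_report$n_matched,
       matrix_total = score$matrix_report$n_total),
  "results/calibration_check.json", auto_unbox = TRUE, digits = NA)

write_parameters(defaults, "results/default_parameters_echo.yaml",
                 provenance = attr(defaults, "provenance"))
cat("wrote results/calibration_check.json and the parameter echo\n")
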