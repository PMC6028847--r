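#!/usr/bin/env Rscript
# Sphere-phantom partial-volume study: simulate four repeat acquisitions of
# a six-sphere phantom (10-37 mm) under the clinical protocol (b = 50,
# 1000 s/mm^2), then quantify how VOI measurements degrade as targets
# shrink: the 80%-VOI scaling table, the concentric-VOI control in the
# largest sphere, and the same-size differential comparison that isolates
# partial-volume contamination.

suppressPackageStartupMessages(library(dwiqc))
dir.create("results", showWarnings = FALSE)
seed <- 20260928L

ex <- sphere_phantom_experiment(noise_sd = 5, n_repeats = 4L, seed = seed)

cat("== Scaling analysis: 80% VOIs centred on each sphere ==\n")
print(ex$scaling, digits = 4)
cat("\nThe relative error and the repeat CV grow as the sphere shrinks;\n")
cat("the smallest spheres are dominated by partial-volume contamination.\n")

cat("\n== Concentric VOIs inside the 37-mm reference sphere ==\n")
print(ex$concentric, digits = 4)
cat(sprintf("\nMax |deviation| across VOI sizes: %.3g%% -- shrinking the VOI\n",
            max(abs(ex$concentric$dev_vs_largest_pct))))
cat("inside a clean target adds no systematic error; size alone is benign.\n")

cat("\n== Differential same-size VOIs: largest sphere vs smaller spheres ==\n")
print(ex$differential, digits = 4)
cat("\nIdentical VOIs in the clean reference vs each target sphere:\n")
cat("residual |errors| are pure partial-volume effects, rising steeply\n")
cat("once the VOI is sampled by only tens of voxels.\n")

write.csv(ex$scaling, "results/sphere_scaling.csv", row.names = FALSE)
write.csv(ex$concentric, "results/sphere_concentric.csv", row.names = FALSE)
write.csv(ex$differential, "results/sphere_differential.csv", row.names = FALSE)
write_report_json(list(scaling = ex$scaling, concentric = ex$concentric,
                       differential = ex$differential),
                  "results/sphere_analysis.json", seed = seed)
cat("\nWrote results/sphere_scaling.csv, sphere_concentric.csv,",
    "sphere_differential.csv, sphere_analysis.json\n")
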