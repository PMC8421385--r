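#!/usr/bin/env Rscript
# Marker-based strain estimation for the scaffold-stretch protocol.
#
# Emulates the nine-dot surface-marker measurement: a 3 x 3 grid of fiducial
# markers is deformed by a known 10% equibiaxial stretch (plus translation
# and localization noise), the homogeneous deformation gradient F and
# translation p are fit by least squares, and the Green-Lagrange strain and
# engineering stretch percentages are recovered.

suppressMessages(library(fiberarch))
dir.create("results", showWarnings = FALSE)

F_true <- diag(c(1.10, 1.10))   # 10% equibiaxial stretch
rows <- lapply(1:20, function(i) {
  mp <- gen_marker_pair(F_true, p_true = c(4, -3), grid = c(3, 3, 10),
                        noise_sigma = 0.05, seed = 500L + i)
  fit <- fit_deformation(mp)
  st <- green_lagrange(fit)
  eb <- equibiaxial_strain_percent(fit)
  data.frame(replicate = i,
             F11 = fit$F[1, 1], F22 = fit$F[2, 2],
             E11 = st$E[1, 1], E22 = st$E[2, 2],
             stretch1_pct = eb$percent[1], stretch2_pct = eb$percent[2],
             anisotropy = eb$anisotropy, residual_rms = fit$residual_rms)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/strain_recovery.csv", row.names = FALSE)

cat(sprintf("20 noisy nine-marker replicates of a 10%% equibiaxial stretch\n"))
cat(sprintf("mean recovered stretch: %.2f%% / %.2f%% (target 10 / 10)\n",
            mean(tab$stretch1_pct), mean(tab$stretch2_pct)))
cat(sprintf("mean E diagonal: %.4f / %.4f (closed form 0.105)\n",
            mean(tab$E11), mean(tab$E22)))
cat(sprintf("mean residual RMS: %.4f (noise sd 0.05)\n", mean(tab$residual_rms)))
cat("wrote results/strain_recovery.csv\n")
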