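#!/usr/bin/env Rscript
# Stage 1: translocation landscapes and the Langevin engine.
#
# Builds the analytic free-energy archetypes (a transported substrate's
# downhill profile and the same profile with an elevated entry barrier,
# plus the symmetric double well used for calibration), checks that
# unbiased Langevin sampling reproduces the Boltzmann distribution, and
# writes the tabulated profiles.

library(abcgate)
dir.create("results", showWarnings = FALSE)
kB <- 0.0083144621

zg <- seq(-1.4, 2.2, by = 0.01)
profiles <- data.frame(
  z = zg,
  substrate = evaluate_landscape(make_landscape("substrate_downhill"), zg)$energy,
  nonsubstrate = evaluate_landscape(make_landscape("nonsubstrate_entry_barrier"), zg)$energy,
  double_well = evaluate_landscape(make_landscape("double_well"), zg)$energy)
write.table(profiles, "results/01_landscapes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
bump <- profiles$nonsubstrate - profiles$substrate
cat(sprintf("entry barrier adds %.1f kJ/mol, peaking at z = %.2f nm\n",
            max(bump), zg[which.max(bump)]))

# Boltzmann consistency of the engine on a bounded double well
dw <- make_landscape("double_well", list(barrier = 8, minima = 0.8))
walls <- wall_spec(-1.3, 1.3, 1000)
tr <- run_langevin(dw, langevin_params(), walls, NULL, 4e7, 0.8,
                   seed = 11, stride = 10)
breaks <- seq(-1.4, 1.4, length.out = 51)
hs <- hist(pmin(pmax(tr$z, -1.4), 1.4), breaks = breaks, plot = FALSE)
E <- evaluate_landscape(dw, hs$mids)$energy + wall_energy(walls, hs$mids)$energy
p <- exp(-E / (kB * 303.15)); p <- p / sum(p)
tv <- 0.5 * sum(abs(p - hs$counts / sum(hs$counts)))
cat(sprintf("Boltzmann total-variation distance over 50 bins: %.4f\n", tv))
write.table(data.frame(z = hs$mids, expected = p,
                       observed = hs$counts / sum(hs$counts)),
            "results/01_boltzmann_histogram.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
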