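#!/usr/bin/env Rscript
# Protonation-state arithmetic across the buffer systems.
#
# The fragment's carboxyl group (pKa ~4.1-4.2) is almost fully deprotonated
# in the ITC buffer (pH 6.9) but the organic-solvent-rich soaking buffer
# drops the pH to 5.3, raising the protonated (neutral) fraction to ~6% --
# enough, the analysis argues, to soak the neutral form into the crystal.
# A binding-induced pKa shift of +1.2 units corresponds to a ~6.9 kJ/mol
# free-energy preference for binding the protonated form. A triplicate
# synthetic titration at the measured pKa checks the fitting machinery.

library(protonbind)

dir.create("results", showWarnings = FALSE)

conds <- data.frame(
  condition = c("ITC buffer", "soaking buffer", "physiological"),
  pka = c(4.2, 4.1, 4.2),
  ph = c(6.9, 5.3, 7.4))
conds$protonated_fraction <- mapply(function(pka, ph)
  protonated_fraction(pka, ph = ph), conds$pka, conds$ph)
write.csv(conds, "results/protonation_conditions.csv", row.names = FALSE)
for (i in seq_len(nrow(conds))) {
  cat(sprintf("%-15s pH %.1f, pKa %.1f -> %5.2f%% protonated\n",
              conds$condition[i], conds$ph[i], conds$pka[i],
              100 * conds$protonated_fraction[i]))
}

# linkage free energy of the bound-state pKa shift (4.2 -> 5.4)
sh <- pka_shift(4.2, 5.4)
cat(sprintf("pKa shift on binding: %+0.1f units -> %.2f kJ/mol in favour of the protonated form\n",
            sh$delta, ddg_from_dpka(sh)))

# triplicate titration fit at the soaking-buffer pKa
reps <- lapply(1:3, function(i)
  gen_ph_titration(4.1, c(2, 7), n_points = 21, noise_sd = 0.02,
                   seed = 300 + i, replicate_id = paste0("r", i)))
fit <- fit_pka(reps)
cat(sprintf("Triplicate titration fit: pKa = %.3f +- %.3f (replicates: %s)\n",
            fit$pka, fit$se, paste(sprintf("%.3f", fit$replicates),
                                   collapse = ", ")))
write.csv(data.frame(replicate = paste0("r", 1:3), pka = fit$replicates),
          "results/pka_fit_replicates.csv", row.names = FALSE)
cat("Wrote results/protonation_conditions.csv and results/pka_fit_replicates.csv\n")
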