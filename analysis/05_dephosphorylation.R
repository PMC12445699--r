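#!/usr/bin/env Rscript
# Real-time dephosphorylation of H3.3S31ph nucleosomes at constant force.
#
# A phosphorylated nucleosome is held at 8.6 pN - between the wild-type
# outer-wrap rupture regime (~6.6 pN) and the phosphorylated disruption
# regime (~11.3 pN) - while phosphatase acts. Dephosphorylation restores
# wild-type outer-wrap kinetics, so the wrap releases and the tether
# lengthens by ~20 nm; the change-point detector recovers the jump from
# each trace.

suppressMessages(library(nucpull))
dir.create("results", showWarnings = FALSE)

cfg <- analysis_config()
rows <- lapply(1:60, function(s) {
  dp <- simulate_dephos(seed = 5000 + s, hold_time = 180)
  ev <- detect_constant_force_event(dp$trace, cfg)
  data.frame(
    seed = 5000 + s,
    true_time = if (nrow(dp$truth)) dp$truth$time else NA_real_,
    det_time = if (is.null(ev)) NA_real_ else ev$time,
    jump_nm = if (is.null(ev)) NA_real_ else ev$jump)
})
tab <- do.call(rbind, rows)
write.table(format(tab, digits = 6), "results/dephosphorylation.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

det <- tab[!is.na(tab$jump_nm) & !is.na(tab$true_time), ]
cat(sprintf("detected %d/%d dephosphorylation events\n",
            sum(!is.na(tab$jump_nm)), nrow(tab)))
cat(sprintf("median jump %.2f nm (expected ~20 nm for the 62 bp outer wrap\n",
            median(tab$jump_nm, na.rm = TRUE)))
cat(sprintf("at 8.6 pN); timing error median %.2f s\n",
            median(abs(det$det_time - det$true_time))))
cat("Wrote results/dephosphorylation.tsv\n")
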