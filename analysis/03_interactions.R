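#!/usr/bin/env Rscript
# Stage 3: interchain contacts and stand-in energies.
#
# For each construct, compares the start conformation against the medoid
# representative: hydrogen bonds, salt bridges, and stand-in pair energies
# for the canonical group pairs, with percent changes on energy magnitudes
# (positive = attraction strengthened).  The energies come from the
# package's transparent stand-in potential, so only their relative changes
# between conformations are meaningful.

suppressPackageStartupMessages(library(scfvfcdyn))

start <- read_structure("scratch/sim/start.pdb")
map <- parse_domain_map("scratch/sim/domains.yaml")

rows <- list()
for (v in c("WT", "SM", "DM")) {
  tr <- align_frames(read_trajectory(sprintf("scratch/sim/%s_traj.pdb", v)),
                     start, selection = c("Fc1:CA", "Fc2:CA"), map = map)
  rep_idx <- centroid_frame(tr)
  ir <- interaction_summary(frame_structure(tr, 1),
                            frame_structure(tr, rep_idx), map)
  for (p in ir$pairs)
    rows[[length(rows) + 1]] <- data.frame(
      construct = v, pair = p$pair,
      e_start_kcal_mol = p$e_start, e_rep_kcal_mol = p$e_end,
      percent_change = p$percent_change,
      hbonds_start = nrow(p$hbonds_start), hbonds_rep = nrow(p$hbonds_end),
      salt_bridges_rep = nrow(p$salt_end))
  rows[[length(rows) + 1]] <- data.frame(
    construct = v, pair = "interchain-total",
    e_start_kcal_mol = ir$interchain$e_start,
    e_rep_kcal_mol = ir$interchain$e_end,
    percent_change = ir$interchain$percent_change,
    hbonds_start = ir$linker_hbond_count$start,
    hbonds_rep = ir$linker_hbond_count$representative,
    salt_bridges_rep = NA_integer_)
  pc <- if (abs(ir$interchain$e_start) > 0.01)
    sprintf("%+.0f%%", ir$interchain$percent_change) else "n/a, near-zero start"
  cat(sprintf("%s: interchain stand-in energy %.3f -> %.3f kcal/mol (%s)\n",
              v, ir$interchain$e_start, ir$interchain$e_end, pc))
}

out <- do.call(rbind, rows)
write.csv(out, "results/interactions.csv", row.names = FALSE)
cat("\nPer-pair stand-in energies written to results/interactions.csv\n")
cat("Note: the rigid toy arms keep inter-arm atoms mostly beyond the 12 A\n",
    "cutoff, so interchain totals stay near zero; the intra-arm VH-VL pairs\n",
    "carry the non-trivial energies and percent changes.\n", sep = "")
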