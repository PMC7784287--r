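#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study and record its planted ground truth.
#
# Two cohorts are simulated at seed 1: wild-type and 5xFAD. Each cohort has
# widefield fura-2 movies (7 odorants x 10 trials of 20 s at 25 Hz), an
# angle-resolved A11 histology profile, nose-poke trajectory sessions, and
# per-animal marker count tables.

library(olfactomap)

seed <- 1L
dir.create("results", showWarnings = FALSE)

gt_all <- list()
for (g in c("WT", "5xFAD")) {
  cfg <- sim_config(seed = seed, genotype = g)
  geom <- ellipse_contour(cfg$fov_px)
  for (od in odorant_panel()) {
    gt <- generate_odorant_trialset(cfg, od, geom)$ground_truth
    gt$genotype <- g
    gt_all[[paste(g, od)]] <- gt
  }
}
gt_img <- do.call(rbind, gt_all)
write.csv(gt_img, "results/ground_truth_imaging.csv", row.names = FALSE)

cat("Planted imaging ground truth (seed", seed, "):\n")
cat(sprintf("  %d foci over %d odorant x genotype conditions\n",
            nrow(gt_img), nrow(unique(gt_img[c("odorant", "genotype")]))))
cat(sprintf("  group-A foci at %.0f-%.0f deg (dorsal), group-B at %.0f-%.0f deg (ventral)\n",
            min(gt_img$focus_angle_deg[gt_img$group == "A"]),
            max(gt_img$focus_angle_deg[gt_img$group == "A"]),
            min(gt_img$focus_angle_deg[gt_img$group == "B"]),
            max(gt_img$focus_angle_deg[gt_img$group == "B"])))
supp <- with(gt_img, tapply(peak_dff, list(genotype, group), max))
cat(sprintf("  peak dF/F0 dips: WT A/B = %.2f/%.2f, 5xFAD A/B = %.2f/%.2f (ventral suppression planted)\n",
            supp["WT", "A"], supp["WT", "B"],
            supp["5xFAD", "A"], supp["5xFAD", "B"]))

# histology ground truth: per-degree planted A11 intensity
hist_gt <- do.call(rbind, lapply(c("WT", "5xFAD"), function(g) {
  hp <- generate_histology_profile(sim_config(seed = seed, genotype = g),
                                   plane = "sagittal")
  data.frame(genotype = g, bin_start_deg = 0:179,
             planted = hp$ground_truth, observed = hp$profile$values)
}))
write.csv(hist_gt, "results/ground_truth_histology.csv", row.names = FALSE)
cat(sprintf("\nPlanted A11 ventral/dorsal intensity ratio: WT %.2f, 5xFAD %.2f\n",
            1.0, sim_config(seed = seed, genotype = "5xFAD")$ab_ventral_gain))

# marker count tables (6 animals per genotype)
counts <- generate_count_tables(n_per_group = 6, seed = seed)
write.csv(counts, "results/counts.csv", row.names = FALSE)
cat(sprintf("\nCount table: %d rows (%d animals x 8 marker-region cells)\n",
            nrow(counts), 12))

# behavior: one detecting and one chance session as examples
det <- generate_trajectory(TRUE, duration_s = 120, seed = seed + 100)
chc <- generate_trajectory(FALSE, duration_s = 120, seed = seed + 101)
cat(sprintf("\nExample sessions: detecting occupancy %.2f (planted 0.60), chance %.2f (planted 0.33)\n",
            zone_occupancy(det)$odor_fraction,
            zone_occupancy(chc)$odor_fraction))
cat("\nWrote results/ground_truth_imaging.csv, ground_truth_histology.csv, counts.csv\n")
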