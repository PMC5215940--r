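#!/usr/bin/env Rscript
# Step 4: the agreement battery. Accelerometer profiles for the full cohort
# come from the ground-truth sidecar (step 2 verified that reduction
# reproduces them exactly from the epoch files); questionnaire scores from
# step 3. Outputs every comparison table under results/comparison/.

suppressMessages(library(actipaq))

prof <- read.csv("results/ground_truth_profiles.csv")
scores <- read.csv("results/questionnaire_scores.csv")
acc <- data.frame(subject_id = prof$subject_id,
                  acc_sedentary = prof$sedentary, acc_light = prof$light,
                  acc_moderate = prof$moderate, acc_vigorous = prof$vigorous,
                  acc_mvpa = prof$mvpa, acc_steps = prof$steps_per_day,
                  acc_wear = prof$mean_wear)
tab <- merge(acc, scores, by = "subject_id")

res <- run_pipeline(tab, out_dir = "results/comparison")
print(res)

sb <- res$stratified
cat(sprintf("\nbias split at 60 min/d accelerometer MVPA (self-report minus device):\n"))
cat(sprintf("  active:   %+.1f min/d (t(%d) = %.2f, p = %.2g, n = %d)\n",
            sb$mean_diff[1], sb$df[1], sb$t_stat[1], sb$p[1], sb$n[1]))
cat(sprintf("  inactive: %+.1f min/d (t(%d) = %.2f, p = %.2g, n = %d)\n",
            sb$mean_diff[2], sb$df[2], sb$t_stat[2], sb$p[2], sb$n[2]))
ba <- bland_altman(tab, "acc_mvpa", "tpaq_index")
cat(sprintf("TPAQ index proportional bias (device-first): r = %.2f (p = %.2g)\n",
            ba$prop_bias_r, ba$prop_bias_p))
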