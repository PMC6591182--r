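#!/usr/bin/env Rscript
# Computes per-subject connectivity profiles (NOS, delta, volume-normalized
# delta_norm), the across-subject group summary with COV and the 1% retention
# threshold, and the compartment aggregation.

suppressPackageStartupMessages(library(tractdensity))

phantom_dir <- "results/phantom"
out <- "results/density"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

labels <- read_label_volume(file.path(phantom_dir, "labels.nii.gz"))
table <- read_region_table(file.path(phantom_dir, "regions.tsv"))
tcks <- sort(list.files(phantom_dir, pattern = "^subject.*\\.tck$",
                        full.names = TRUE))
tg <- table[table$role == "target", ]

profiles <- lapply(seq_along(tcks), function(k) {
  asg <- assign_streamlines(read_tck(tcks[k]), labels, table)
  p <- subject_profile(asg, labels, table)
  write.table(data.frame(label = tg$label, structure = tg$name,
                         nos = unname(p$nos), delta = unname(p$delta),
                         delta_norm = unname(p$delta_norm)),
              file.path(out, sprintf("profile_subject%03d.tsv", k)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  p
})

summ <- summarize_group(profiles, threshold = 1.0)
summ_named <- data.frame(structure = tg$name[match(as.integer(summ$target),
                                                   tg$label)],
                         mean = round_half_up(summ$mean_delta_norm),
                         sd = round_half_up(summ$sd),
                         cov = round_half_up(summ$cov),
                         retained = summ$retained)
summ_named <- summ_named[order(-summ_named$mean), ]
write.table(summ_named, file.path(out, "group_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

comp <- aggregate_compartments(
  stats::setNames(summ$mean_delta_norm, summ$target), table)
write.table(data.frame(compartment = names(comp),
                       mean_delta_norm = round_half_up(comp)),
            file.path(out, "compartments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("group summary (mean delta_norm %, across", length(profiles),
    "subjects):\n")
print(summ_named, row.names = FALSE)
cat("\ncompartment aggregation (%):\n")
print(round_half_up(comp))
cat("\nretained pathways (mean delta_norm > 1%):",
    sum(summ$retained), "of", nrow(summ), "\n")
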