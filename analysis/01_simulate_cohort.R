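#!/usr/bin/env Rscript
# Stage 1: simulate the demo cohort.
#
# 40 synthetic DSC-PWI subjects at 50% lesion prevalence on the default
# 16 x 32 x 32 x 50 grid. The cohort table (three binary endpoints per
# subject) goes to results/cohort.csv; the first two subjects are also
# written as NIfTI for inspection.

library(dynradiomics)

seed <- 1L
out <- "results"
dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)

co <- generate_cohort(40, prevalence = 0.5, seed = seed, keep_images = FALSE)
write.csv(co$table, file.path(out, "cohort.csv"), row.names = FALSE)

# two example subjects (one control, one stroke) as NIfTI
ids <- c(which(co$table$stroke == 0)[1], which(co$table$stroke == 1)[1])
full <- generate_cohort(40, prevalence = 0.5, seed = seed)
for (i in ids)
  write_subject(full$subjects[[i]],
                file.path(out, "images", co$table$subject_id[i]))

cat("cohort of", nrow(co$table), "subjects; endpoint prevalences:\n")
print(colMeans(co$table[, c("stroke", "impairment", "poor_outcome")]))
cat("wrote", file.path(out, "cohort.csv"), "and two example NIfTI subjects\n")
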