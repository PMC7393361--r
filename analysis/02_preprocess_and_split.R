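#!/usr/bin/env Rscript
# Preprocess the simulated cohort (truncation to 900-1800 cm^-1,
# Savitzky-Golay 7/2, AWLS baseline, Amide I normalization), then build the
# Kennard-Stone 70/15/15 split. Requires 01_simulate_cohort.R to have run.

suppressMessages(library(spectroscreen))

ds <- read_spectra("scratch/cohort_wide.csv", "wide")
avg <- average_replicates(ds)
pp <- preprocess(avg, preprocess_config())
split <- split_dataset(pp)

write_spectra(pp, "scratch/cohort_preprocessed.csv")
write_split_csv(split, "results/split_indices.csv")

cat("Preprocessed", nrow(pp$absorbance), "averaged spectra down to",
    length(pp$wavenumbers), "wavenumbers in the biofingerprint region\n")
cat("Kennard-Stone split sizes (train/val/test):",
    length(split$train_idx), "/", length(split$val_idx), "/",
    length(split$test_idx), "\n")
cat("Split indices written to results/split_indices.csv\n")
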