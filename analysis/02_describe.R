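#!/usr/bin/env Rscript
# Eligibility filtering and descriptive tables of the working sample:
# composition by education / cohort / country group, and poor-health
# prevalence per wave.
#
# Usage: Rscript analysis/02_describe.R [panel.csv]

suppressMessages(library(panelmsm))

args <- commandArgs(trailingOnly = TRUE)
panel_path <- if (length(args) >= 1) args[1] else "results/panel.csv"
dir.create("results", showWarnings = FALSE)

panel <- read_panel(panel_path)
filt <- apply_eligibility_filters(panel)
message("exclusions by reason and gender:")
print(filt$report)

write_panel(filt$panel, "results/panel_filtered.csv")

tab1 <- sample_characteristics(filt$panel)
print(tab1)
utils::write.csv(tab1$composition, "results/table1_composition.csv",
                 row.names = FALSE)
utils::write.csv(tab1$participation, "results/table1_participation.csv",
                 row.names = FALSE)

tab2 <- prevalence_table(filt$panel)
print(tab2)
utils::write.csv(as.data.frame(tab2), "results/table2_prevalence.csv",
                 row.names = FALSE)
message("wrote results/table1_*.csv and results/table2_prevalence.csv")
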