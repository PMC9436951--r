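#!/usr/bin/env Rscript
# Screen the raw plot table: formation classification from growth-form
# cover shares, plot-size windows per formation, anthropogenic/aquatic
# exclusion; label size classes for stratification.

source(file.path("analysis", "_common.R"))

plots <- read_plot_table(file.path("results", "plots_raw.tsv"))
res <- filter_plots(plots)
print(res$report)

write_plot_table(res$plots, file.path(results_dir(), "plots_screened.tsv"))
rep <- data.frame(rule = names(res$report$dropped_by_rule),
                  dropped = as.integer(res$report$dropped_by_rule))
rep <- rbind(rep, data.frame(rule = "retained",
                             dropped = res$report$n_retained))
write.table(rep, file.path(results_dir(), "ingest_report.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/plots_screened.tsv and results/ingest_report.tsv\n")
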