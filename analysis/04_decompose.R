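#!/usr/bin/env Rscript
# Stage 4: four-test Venn decomposition of the significant sets.
#
# The total-response, fetal-response, adult-response and
# response-difference sets are partitioned into the 15 regions of the
# four-set Venn diagram; per test we report the implicated total and the
# count newly identified beyond the total-response screen.

suppressMessages(library(lfqnest))

res <- read_results("results/contrast_results.tsv")
sig <- split(res$protein_id[res$significant], res$contrast[res$significant])
get <- function(ct) if (is.null(sig[[ct]])) character(0) else sig[[ct]]

partition <- venn_partition(
  total = get("total_response"), fetal = get("fetal_response"),
  adult = get("adult_response"), difference = get("response_difference")
)
write_partition(partition, "results/venn_partition.tsv")

s <- summarize_partition(partition)
cat("implicated totals:  ",
    paste(sprintf("%s=%d", names(s$implicated), s$implicated), collapse = "  "), "\n")
cat("newly identified:   ",
    paste(sprintf("%s=%s", names(s$newly_identified),
                  ifelse(is.na(s$newly_identified), "-", s$newly_identified)),
          collapse = "  "), "\n")
cat("difference breakdown by prior implication:\n")
print(s$difference_breakdown)
cat(sprintf("baseline_difference (reported alongside, outside the partition): %d\n",
            length(get("baseline_difference"))))
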