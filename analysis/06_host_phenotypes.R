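#!/usr/bin/env Rscript
# Host phenotype statistics: Mann-Whitney on the weeks 80-120 weight AUC,
# Mann-Whitney on the ipGTT glucose AUC (minutes 0-120), and the log-rank
# test on survival.

suppressPackageStartupMessages(library(rejuvenome))
inp <- "results/inputs"
out <- "results"

weights <- utils::read.delim(file.path(inp, "weights.tsv"))
gtt <- utils::read.delim(file.path(inp, "gtt.tsv"))
surv <- utils::read.delim(file.path(inp, "survival.tsv"))

wa <- compare_auc(weights, 80, 120)
cat(sprintf("weight AUC (weeks 80-120): U = %g, p = %.4g\n", wa$U, wa$p))
ga <- compare_auc(gtt, 0, 120)
cat(sprintf("ipGTT AUC (0-120 min):     U = %g, p = %.4g\n", ga$U, ga$p))
lr <- logrank_test(surv$time, surv$event, surv$group)
cat(sprintf("log-rank survival:          chisq = %.3f, p = %.4g\n",
            lr$chisq, lr$p))

stats <- data.frame(
  test = c("weight_auc_mw", "gtt_auc_mw", "survival_logrank"),
  statistic = c(wa$U, ga$U, lr$chisq),
  p = c(wa$p, ga$p, lr$p))
utils::write.table(stats, file.path(out, "phenotype_tests.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
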