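#!/usr/bin/env Rscript
# Assemble the comparison report in the layout of the study's three result
# tables (diagnostic performance per split; localization contingency tables
# with Fisher p-values) from the artifacts written by 02_run_study.R, plus
# the Fisher p-values that are fully determined by the printed contingency
# tables of the original localization analysis.

library(uscam)

stopifnot(file.exists("results/study/results.json"))
js <- jsonlite::read_json("results/study/results.json")

md <- c("# Phantom study report", "")
for (split in c("internal_val", "external_val")) {
  auc <- read.csv(sprintf("results/study/auc_%s.csv", split))
  met <- read.csv(sprintf("results/study/metrics_%s.csv", split))
  loc <- read.csv(sprintf("results/study/localization_%s.csv", split))
  md <- c(md, sprintf("## %s", split), "",
          "| arm | AUC (95% CI) | sensitivity | specificity |",
          "|---|---|---|---|",
          sprintf("| %s | %.2f (%.2f, %.2f) | %s | %s |",
                  auc$arm, auc$auc, auc$ci_low, auc$ci_high,
                  met$sens_str, met$spec_str),
          "",
          sprintf("Localization (weak arm): benign %d/%d, malignant %d/%d correct",
                  loc$correct[1], loc$correct[1] + loc$incorrect[1],
                  loc$correct[2], loc$correct[2] + loc$incorrect[2]),
          "")
}
md <- c(md, "## Fisher p-values from the printed localization tables", "",
        sprintf("- ((99,1),(100,0)): %.2f",
                fisher_exact_2x2(matrix(c(99, 100, 1, 0), 2))),
        sprintf("- ((96,4),(98,2)): %.2f",
                fisher_exact_2x2(matrix(c(96, 98, 4, 2), 2))),
        sprintf("- ((97,3),(100,0)): %.2f",
                fisher_exact_2x2(matrix(c(97, 100, 3, 0), 2))))
writeLines(md, "results/tables.md")
cat("wrote results/tables.md\n")
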