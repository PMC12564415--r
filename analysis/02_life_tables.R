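#!/usr/bin/env Rscript
# Step 2: age-stage two-sex life tables of the study-sized cohorts:
# s_xj / f_xj schedules, l_x, m_x, the population parameters, and the
# life-expectancy and reproductive-value surfaces. Tables are exported
# under results/lifetables/.

suppressPackageStartupMessages(library(agestage))

cohdir <- "results/cohorts"
out <- "results/lifetables"
sch <- butterfly_schema()

for (stem in c("cg_n30", "st_n90")) {
  coh <- read_cohort(file.path(cohdir, paste0(stem, "_individuals.csv")),
                     file.path(cohdir, paste0(stem, "_fecundity.csv")), sch,
                     label = stem)
  rep <- run_lifetable_report(coh, dir = out)
  cat("==", stem, "==\n")
  print(rep$parameters)
  e <- rep$life_expectancy
  cat(sprintf("newborn life expectancy e_0,egg = %.1f d\n", e[1, "egg"]))
  v <- rep$reproductive_value
  cat(sprintf("newborn reproductive value v_0,egg = %.4f (= lambda)\n\n", v[1, "egg"]))
  utils::write.csv(
    data.frame(x = as.integer(rownames(e)), e[, , drop = FALSE], check.names = FALSE),
    file.path(out, paste0(stem, "_life_expectancy.csv")), row.names = FALSE, na = "")
  utils::write.csv(
    data.frame(x = as.integer(rownames(v)), v[, , drop = FALSE], check.names = FALSE),
    file.path(out, paste0(stem, "_reproductive_value.csv")), row.names = FALSE, na = "")
}
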