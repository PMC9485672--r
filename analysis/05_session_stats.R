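#!/usr/bin/env Rscript
# Stage 5 -- session-level statistics.
#
# The inferential layer over the per-dyad synchrony table (stage 3):
# descriptives with normality diagnostics, paired pre/post Wilcoxon
# signed-rank and Student t contrasts with effect sizes, and simple
# regressions of each synchrony measure on VAS therapy readiness.
# Also summarizes the bundled example session-duration table.

library(dyadsync)

out_dir <- "results"
tab <- read.csv(file.path(out_dir, "synchrony_by_dyad.csv"))
vas <- read.csv(file.path(out_dir, "data", "vas.csv"))$vas

pre <- tab[tab$phase == "pretalk", ]
post <- tab[tab$phase == "posttalk", ]
measures <- list(
  "all lags" = c("zccf_all_lags"), "lag zero" = c("zccf_lag_zero"),
  "therapist leading" = c("therapist_lead"),
  "patient leading" = c("patient_lead"), "Tlead-Plead" = c("tlead_minus_plead"))

paired <- do.call(rbind, lapply(names(measures), function(nm) {
  col <- measures[[nm]]
  w <- paired_wilcoxon(pre[[col]], post[[col]])
  t <- paired_ttest(pre[[col]], post[[col]])
  data.frame(measure = nm, wilcoxon_w = w$wilcoxon_w, p_wilcoxon = w$p_wilcoxon,
             rank_biserial = w$rank_biserial_r,
             mean_difference = w$mean_difference, se = w$se_difference,
             ci_low = w$ci_low, ci_high = w$ci_high,
             student_t = t$student_t, df = t$df, p_t = t$p_t)
}))
write.csv(paired, file.path(out_dir, "paired_contrasts.csv"), row.names = FALSE)
w1 <- paired[paired$measure == "all lags", ]
cat(sprintf("Pre vs post (all lags): W = %g, p = %.4g, rank-biserial r = %.2f, t(%d) = %.2f\n",
            w1$wilcoxon_w, w1$p_wilcoxon, w1$rank_biserial, w1$df, w1$student_t))

regs <- do.call(rbind, lapply(names(measures), function(nm) {
  col <- measures[[nm]]
  rows <- lapply(c(pretalk = "pretalk", posttalk = "posttalk"), function(ph) {
    y <- tab[tab$phase == ph, col]
    r <- regress_on_readiness(y, vas)
    data.frame(measure = nm, phase = ph, F = r$f_stat, df1 = r$df1,
               df2 = r$df2, p = r$p, R2 = r$r_squared, t = r$t_slope)
  })
  do.call(rbind, rows)
}))
write.csv(regs, file.path(out_dir, "vas_regressions.csv"), row.names = FALSE)
sig <- regs[regs$p < 0.1, ]
cat(sprintf("VAS regressions (n = %d complete): %d of %d below p = 0.1\n",
            sum(!is.na(vas)), nrow(sig), nrow(regs)))

durations <- session_table()
d <- describe_values(durations$session_min)
cat(sprintf("Bundled session durations: mean %.2f min (SD %.2f, range %.2f-%.2f)\n",
            d$mean, d$sd, d$min, d$max))
write.csv(data.frame(statistic = c("n", "mean", "median", "sd", "min", "max"),
                     session_min = c(d$n, d$mean, d$median, d$sd, d$min, d$max)),
          file.path(out_dir, "session_durations.csv"), row.names = FALSE)
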