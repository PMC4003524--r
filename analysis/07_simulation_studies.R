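#!/usr/bin/env Rscript
# The package's calibration, power, correctness and recovery studies, at
# the same settings the acceptance script uses, summarized in one table.

suppressPackageStartupMessages(library(arealclust))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

rows <- list()
note <- function(study, quantity, value, n) {
  rows[[length(rows) + 1L]] <<- data.frame(study = study,
                                           quantity = quantity,
                                           value = value, n = n)
  cat(sprintf("%-28s %-28s %8.4f  (n = %d)\n", study, quantity, value, n))
}

cal <- experiment_scan_calibration(seed = 1)
note("scan_null_calibration", "reject_rate_at_0.05", cal$reject_rate,
     cal$n_datasets)
pw <- experiment_scan_power(seed = 2)
note("scan_power_rr3", "css_power", pw$power_css, length(pw$hit_css))
note("scan_power_rr3", "fss_power", pw$power_fss, length(pw$hit_fss))
fo <- experiment_fss_oracle(seed = 3)
note("fss_enumeration_oracle", "agreement_rate",
     fo$n_agree / fo$n_maps, fo$n_maps)
lr <- experiment_lr_check(seed = 4)
note("loglr_arithmetic", "max_rel_err", lr$max_rel_err, lr$n)
pd <- experiment_car_pd(seed = 5)
note("car_positive_definiteness", "inside_pd_rate",
     pd$n_inside_pd / pd$n_checks, pd$n_checks)
rec <- experiment_bym_recovery(seed = 6)
note("bym_recovery", "mu_ci_coverage", rec$coverage_mu,
     length(rec$covered))
note("bym_recovery", "sigma2_rel_bias", rec$sigma2_rel_bias,
     length(rec$sigma2_mean))
dg <- experiment_dc_degeneracy(seed = 7)
note("dc_degeneracy", "loglog_variance_slope", dg$slope,
     nrow(dg$convergence))
oc <- experiment_dc_oracle(seed = 8)
note("dc_quadrature_oracle", "mu_z", oc$z_mu, 4)
note("dc_quadrature_oracle", "sigma2_z", oc$z_sigma2, 4)
cc <- experiment_concordance(seed = 9)
note("bym_mle_concordance", "spearman_mean", cc$spearman_mean,
     length(cc$spearman))
note("bym_mle_concordance", "threshold_monotone_fraction",
     cc$monotone_fraction, 2L * length(cc$spearman))

utils::write.csv(do.call(rbind, rows),
                 "results/tables/simulation_studies.csv",
                 row.names = FALSE, quote = FALSE)
cat("wrote results/tables/simulation_studies.csv\n")
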