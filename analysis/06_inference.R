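#!/usr/bin/env Rscript
# Stage 6: depth and travel rate conditional on association state.
# Gaussian mixed models (exact maximum likelihood) with a per-seal random
# intercept and AR(1) residual correlation along each seal's hourly
# sequence. Depth model: Random (availability sample, one pseudo-group)
# vs No Association vs Association. Rate model: No Association vs
# Association. Plus the Williams-corrected G test of sex-pair
# composition.

source("analysis/00_common.R")

steps <- utils::read.csv(file.path(results_dir,
                                   "steps_with_states.csv"))
steps <- steps[!is.na(steps$lon), ]
rand <- utils::read.csv(file.path(results_dir, "random_depths.csv"))

depth_data <- rbind(
  data.frame(response = rand$depth_m, category = "Random",
             group = "random_sample"),
  data.frame(response = steps$depth_m,
             category = ifelse(steps$associated, "Association",
                               "No Association"),
             group = steps$seal_id))
lmm_depth <- fit_lmm_ar1(depth_data, "response", "category", "group",
                         levels = c("Random", "No Association",
                                    "Association"))
message("Depth model (m):")
print(lmm_depth)

rate_data <- data.frame(response = steps$rate_ms,
                        category = ifelse(steps$associated,
                                          "Association",
                                          "No Association"),
                        group = steps$seal_id)
lmm_rate <- fit_lmm_ar1(rate_data, "response", "category", "group",
                        levels = c("No Association", "Association"))
message("Travel-rate model (m/s):")
print(lmm_rate)

assoc <- utils::read.csv(file.path(results_dir, "associations.csv"))
summ <- summarize_associations(assoc, study_sexes())
message("Sex-pair composition of associations:")
print(summ$sex_pairs)
print(summ$sex_g_test)

mean_rate <- tapply(rate_data$response, rate_data$category,
                    function(v) mean(v, na.rm = TRUE))
message("mean rate (m/s): ",
        paste(names(mean_rate), sprintf("%.2f", mean_rate),
              collapse = ", "))

write_table(cbind(model = "depth", lmm_depth$coefficients),
            "lmm_depth.csv")
write_table(cbind(model = "rate", lmm_rate$coefficients),
            "lmm_rate.csv")
variance <- data.frame(
  model = c("depth", "rate"),
  sigma_b = c(lmm_depth$sigma_b, lmm_rate$sigma_b),
  sigma_e = c(lmm_depth$sigma_e, lmm_rate$sigma_e),
  phi = c(lmm_depth$phi, lmm_rate$phi),
  loglik = c(lmm_depth$loglik, lmm_rate$loglik))
write_table(variance, "lmm_variance_components.csv")
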