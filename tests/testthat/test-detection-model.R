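# shared simulated survey for model-table and fitting checks
sim_glm_survey <- function(seed, n_per_class = 33, theta = 1,
                           offsets = c(clearfell = 0, coniferous_plantation = 1,
                                       grassland = 2, heathland_shrubland = 0.5,
                                       wetland = -0.5, woodland = 1.5),
                           base_rate = 0.3, human_rate = 0.3) {
  cfg <- sim_config(
    n_stations = setNames(rep(n_per_class, 6), land_cover_classes),
    species = list(test_sp = list(base_log_rate = log(base_rate),
                                  landcover_offsets = offsets,
                                  theta = theta, diel = diel_profile())),
    human = list(rate = human_rate, theta = 1, diel = diel_profile(13, 2)),
    bursts = FALSE, seed = seed)
  sim <- simulate_survey(cfg)
  list(ds = sim$dataset, ct = filter_independent(sim$dataset, window_minutes = 0))
}

test_that("the model table conserves counts and encodes land cover and effort", {
  s <- sim_glm_survey(101, n_per_class = 5)
  tab <- build_model_table(s$ct, s$ds, "test_sp")
  expect_equal(nrow(tab), 30)
  expect_equal(sum(tab$count), sum(s$ct$species == "test_sp"))
  expect_equal(levels(tab$land_cover)[1], "clearfell")
  expect_equal(tab$log_duration, rep(log(28), 30))
  hr <- human_detection_rates(s$ct, s$ds)
  expect_error(build_model_table(s$ct, s$ds, "test_sp", hr[-1, ]),
               "missing from human_rates")
})

test_that("Pearson dispersion diagnostic separates Poisson from NB data", {
  # equidispersed data: ratio near 1, verdict negative
  s <- sim_glm_survey(202, n_per_class = 50, theta = 1e7)
  pois <- fit_detection_model(s$ct, s$ds, "test_sp", family = "poisson")
  d <- check_overdispersion(pois)
  expect_lt(abs(d$ratio - 1), 0.35)
  expect_false(d$overdispersed)

  # strongly overdispersed data (theta = 0.5): ratio well above threshold
  s2 <- sim_glm_survey(203, n_per_class = 50, theta = 0.5)
  pois2 <- fit_detection_model(s2$ct, s2$ds, "test_sp", family = "poisson")
  d2 <- check_overdispersion(pois2)
  expect_gt(d2$ratio, 3)
  expect_true(d2$overdispersed)
})

test_that("all-zero counts deflate the dispersion ratio below 1", {
  fit <- suppressWarnings(glm(count ~ 1, family = poisson(),
                              data = data.frame(count = rep(0L, 10))))
  d <- check_overdispersion(fit)
  expect_lt(d$ratio, 1)
  # and with no residual degrees of freedom the diagnostic refuses to answer
  fit1 <- suppressWarnings(glm(count ~ 1, family = poisson(),
                               data = data.frame(count = 3L)))
  expect_error(check_overdispersion(fit1), "degrees of freedom")
})

test_that("NB fit recovers known coefficients within 3 SE at n = 198 stations", {
  s <- sim_glm_survey(301)
  fit <- fit_detection_model(s$ct, s$ds, "test_sp")
  co <- fit$coefficients
  truth <- c("(Intercept)" = log(0.3),
             land_coverconiferous_plantation = 1, land_covergrassland = 2,
             land_coverheathland_shrubland = 0.5, land_coverwetland = -0.5,
             land_coverwoodland = 1.5, human_rate = 0)
  for (nm in names(truth)) {
    row <- co[co$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 3 * row$std_error,
              label = nm)
  }
  expect_true(fit$pseudo_r2 >= 0 && fit$pseudo_r2 <= 1)
})

test_that("intercept-only fit equals the closed-form rate MLE, with zero pseudo-R2", {
  # single land cover, no human contacts: rate model collapses to
  # total contacts / total trap-days
  ev <- data.frame(station_id = sprintf("st%02d", c(1, 1, 2, 3, 3, 3)),
                   species = "sika_deer",
                   minutes = c(0, 2000, 500, 100, 3000, 9000))
  ds <- ds_from_minutes(ev, n_stations = 4, days = c(28, 28, 14, 14),
                        land_cover = rep("woodland", 4))
  ct <- filter_independent(ds)
  fit <- fit_detection_model(ct, ds, "sika_deer")
  expect_equal(unname(coef(fit)[["(Intercept)"]]),
               log(nrow(ct) / trap_days(ds)), tolerance = 1e-6)
  expect_equal(fit$pseudo_r2, 0)
})

test_that("a land-cover level with zero contacts is separation-flagged, not hidden", {
  s <- sim_glm_survey(404, n_per_class = 8,
                      offsets = c(clearfell = 0, coniferous_plantation = 1,
                                  grassland = 1, heathland_shrubland = 0,
                                  wetland = -30, woodland = 1))
  tab <- build_model_table(s$ct, s$ds, "test_sp")
  expect_equal(sum(tab$count[tab$land_cover == "wetland"]), 0)
  fit <- fit_detection_model(s$ct, s$ds, "test_sp")
  expect_true(fit$separation[["land_coverwetland"]])
  expect_false(fit$separation[["land_covergrassland"]])
  em <- emm_contrasts(fit)
  flg <- em$contrasts$flagged
  involved <- em$contrasts$level_a == "wetland" | em$contrasts$level_b == "wetland"
  expect_equal(flg, involved)
})

test_that("rate ratios exponentiate log-scale coefficients", {
  expect_equal(rate_ratio(0), 1)
  expect_equal(rate_ratio(log(2)), 2)
  expect_equal(round(rate_ratio(2.48), 2), 11.94)
})

test_that("offset handling: doubling effort and counts leaves rate coefficients unchanged", {
  s <- sim_glm_survey(505, n_per_class = 10)
  tab <- build_model_table(s$ct, s$ds, "test_sp")
  fit1 <- glm(count ~ land_cover + human_rate + offset(log_duration),
              family = poisson(), data = tab)
  tab2 <- tab
  tab2$count <- tab$count * 2L
  tab2$log_duration <- tab$log_duration + log(2)
  fit2 <- glm(count ~ land_cover + human_rate + offset(log_duration),
              family = poisson(), data = tab2)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-8)
})

test_that("with theta large, NB and Poisson fits agree on coefficients to < 1e-3", {
  s <- sim_glm_survey(606, n_per_class = 40, theta = 1e7)
  nb <- fit_detection_model(s$ct, s$ds, "test_sp")
  po <- fit_detection_model(s$ct, s$ds, "test_sp", family = "poisson")
  expect_lt(max(abs(coef(nb) - coef(po))), 1e-3)
})

test_that("EMM contrasts reduce to coefficient differences and have 15 pairs", {
  s <- sim_glm_survey(707, n_per_class = 12)
  fit <- fit_detection_model(s$ct, s$ds, "test_sp")
  em <- emm_contrasts(fit)
  expect_equal(nrow(em$contrasts), 15)
  expect_equal(nrow(em$emmeans), 6)
  # the human-rate covariate conditions every EMM identically, so the
  # clearfell-grassland contrast is exactly minus the grassland coefficient
  cg <- em$contrasts[em$contrasts$level_a == "clearfell" &
                     em$contrasts$level_b == "grassland", ]
  expect_equal(cg$estimate, -unname(coef(fit)[["land_covergrassland"]]))
  # response-scale EMMs are exp(log EMMs)
  expect_equal(em$emmeans$response, exp(em$emmeans$emmean))
})

test_that("EMMs and contrasts match the emmeans package", {
  s <- sim_glm_survey(808, n_per_class = 12)
  fit <- fit_detection_model(s$ct, s$ds, "test_sp")
  em <- emm_contrasts(fit)
  rg <- emmeans::emmeans(fit$fit, "land_cover",
                         at = list(log_duration = 0),
                         data = fit$table)
  ref <- as.data.frame(rg)
  expect_equal(em$emmeans$emmean, ref$emmean, tolerance = 1e-6)
  expect_equal(em$emmeans$se, ref$SE, tolerance = 1e-6)
  prs <- as.data.frame(emmeans::contrast(rg, "pairwise", adjust = "none"))
  expect_equal(em$contrasts$estimate, prs$estimate, tolerance = 1e-6)
  expect_equal(em$contrasts$se, prs$SE, tolerance = 1e-6)
  expect_equal(em$contrasts$p_value, prs$p.value, tolerance = 1e-6)
  prs_t <- as.data.frame(emmeans::contrast(rg, "pairwise", adjust = "tukey"))
  em_t <- emm_contrasts(fit, adjust = "tukey")
  expect_equal(em_t$contrasts$p_value, prs_t$p.value, tolerance = 1e-5)
})

test_that("on balanced data with no covariate, EMMs approach group log mean rates", {
  s <- sim_glm_survey(909, n_per_class = 25, human_rate = 0)
  fit <- fit_detection_model(s$ct, s$ds, "test_sp")
  em <- emm_contrasts(fit)
  tab <- fit$table
  grp <- tapply(tab$count / exp(tab$log_duration), tab$land_cover, mean)
  expect_equal(em$emmeans$emmean, as.numeric(log(grp[em$emmeans$land_cover])),
               tolerance = 1e-6)
})
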