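# Shared fitted model for the conformal / attribution / prediction tests.
# Built once per test run: 10 synthetic sites, 4000 footprints, regularized
# shallow boosted trees trained on 8 sites with 2 sites held out for
# conformal calibration.
demo_env <- new.env(parent = emptyenv())

demo_params <- function() {
  wsci::wsci_grid(n_estimators = 100, subsample = 0.7, feature_fraction = 0.7,
                  max_depth = 2, learning_rate = 0.05)
}

demo_fit <- function() {
  if (is.null(demo_env$fit)) {
    sites <- wsci::simulate_rh_sites(10, seed = 42)
    tab <- wsci::simulate_rh_table(4000, sites, seed = 43)
    cal_sites <- c("S09", "S10")
    train <- tab[!(tab$site_id %in% cal_sites), ]
    cal <- tab[tab$site_id %in% cal_sites, ]
    fit <- wsci::wsci_fit(train, params = demo_params(), seed = 7)
    demo_env$sites <- sites
    demo_env$train <- train
    demo_env$cal <- cal
    demo_env$cal_sites <- cal_sites
    demo_env$fit <- fit
    demo_env$fit_cal <- wsci::calibrate_mondrian(fit, cal, alpha = 0.05)
  }
  demo_env
}
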