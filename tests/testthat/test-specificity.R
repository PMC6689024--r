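test_that("the highest conversion picks the maximum covered C", {
  site <- fixture_site()
  tab <- simulate_site_counts(site, editor_profile("p", c(`6` = 0.5, `4` = 0.1),
                                                   seq_error = 0),
                              5000, seed = 3)
  hc <- highest_conversion(tab)
  expect_identical(hc$cp, 6L)
  expect_gt(hc$value, 0.45)
  # no covered C is undefined
  empty <- tabulate_reads(data.frame(id = character(0), seq = character(0),
                                     offset = integer(0)), site)
  expect_true(is.na(highest_conversion(empty)$value))
})

test_that("specificity scores follow (onCh - offCh) / onCh with labels", {
  expect_equal(specificity_score(0.5, 0.1)$value, 0.8)
  expect_equal(specificity_score(0.3, 0.3)$value, 0)
  expect_equal(specificity_score(0.4, 0)$value, 1)
  expect_identical(specificity_score(0.5, 0.1)$label, "numeric")
  # off-target activity above on-target: N.Sp., negative value recorded
  s <- specificity_score(0.2, 0.4)
  expect_identical(s$label, "N.Sp.")
  expect_equal(s$value, -1)
  # no obvious on-target activity
  expect_identical(specificity_score(0.01, 0.4)$label, "no-activity")
  expect_identical(specificity_score(NA, 0.4)$label, "no-activity")
})

test_that("specificity is scale-free and monotone where defined", {
  set.seed(31)
  for (i in 1:20) {
    on <- stats::runif(1, 0.06, 1); off <- stats::runif(1, 0, on)
    v <- specificity_score(on, off)$value
    k <- stats::runif(1, 0.1, 1 / on)
    expect_equal(specificity_score(on * k, off * k)$value, v)     # scale-free
    off2 <- min(off + 0.05, on)
    expect_lte(specificity_score(on, off2)$value, v + 1e-12)      # in offCh
    expect_gte(specificity_score(min(on + 0.05, 1), off)$value + 1e-12, v)
    expect_true(specificity_score(on, off)$value <= 1)
  }
})

test_that("exactly one label applies per result", {
  grid <- expand.grid(on = c(NA, 0.01, 0.2, 0.6), off = c(0, 0.3, 0.9))
  for (i in seq_len(nrow(grid))) {
    s <- specificity_score(grid$on[i], grid$off[i])
    expect_length(s$label, 1L)
    if (identical(s$label, "N.Sp.")) {
      expect_true(grid$off[i] > grid$on[i] && grid$on[i] >= 0.05)
    }
    if (!is.na(grid$on[i]) && grid$on[i] >= 0.05 && grid$off[i] <= grid$on[i]) {
      expect_identical(s$label, "numeric")
      expect_true(s$value >= 0 && s$value <= 1)
    }
  }
})

test_that("a specificity panel scores each pair and summarizes per target", {
  panel <- bescope:::specificity_panel_sites(seed = 55, n_off = 2L)
  mk <- function(q) editor_profile("e", stats::setNames(rep(q, 14), 1:14),
                                   seq_error = 0)
  tabs <- list(
    on_target = simulate_site_counts(panel$sites$on_target, mk(0.5), 20000, seed = 1),
    off_target01 = simulate_site_counts(panel$sites$off_target01, mk(0.1), 20000, seed = 2),
    off_target02 = simulate_site_counts(panel$sites$off_target02, mk(0.25), 20000, seed = 3))
  res <- specificity_panel(tabs, panel$pairs, editor_id = "e")
  expect_identical(nrow(res$pairs), 2L)
  expect_identical(nrow(res$summary), 1L)
  expect_lt(abs(res$pairs$specificity[1] - 0.8), 0.05)
  expect_lt(abs(res$pairs$specificity[2] - 0.5), 0.05)
  # the summary reports the worst per-pair score and the pooled (max offCh) one
  expect_equal(res$summary$worst_specificity, min(res$pairs$specificity))
  expect_lt(abs(res$summary$pooled_specificity - 0.5), 0.05)
  # simulated off > on triggers N.Sp.
  tabs2 <- tabs; tabs2$off_target01 <- simulate_site_counts(
    panel$sites$off_target01, mk(0.9), 20000, seed = 4)
  res2 <- specificity_panel(tabs2, panel$pairs, editor_id = "e")
  expect_identical(res2$pairs$label[1], "N.Sp.")
  expect_identical(res2$summary$worst_label, "N.Sp.")
  # pairing a site with no table is a configuration error
  expect_error(specificity_panel(tabs[1:2], panel$pairs), "no conversion table")
})
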