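test_that("site selection keeps every C at a qualifying position", {
  sites_df <- data.frame(
    site_id = c("a", "b", "a"), cp = c(6, 6, 12),
    upstream_di = c("AC", "GC", "TC"),
    downstream_di = c("CA", "CG", "CT"),
    norm = c(0.85, 0.40, 0.50), stringsAsFactors = FALSE)
  sel <- select_sites(sites_df)
  # position 6 qualifies through the 0.85 site; both its sites are returned
  expect_identical(sort(sel$norm), c(0.40, 0.85))
  expect_true(all(sel$cp == 6))
  # the boundary is inclusive
  sel2 <- select_sites(transform(sites_df, norm = c(0.8, 0.4, 0.5)))
  expect_identical(nrow(sel2), 2L)
  # nothing qualifies below the threshold
  sel3 <- select_sites(transform(sites_df, norm = c(0.7, 0.4, 0.5)))
  expect_identical(nrow(sel3), 0L)
  expect_true(attr(sel3, "no_qualifying"))
})

test_that("context grouping partitions by direction", {
  sites_df <- data.frame(
    site_id = "a", cp = c(4, 5, 9, 12),
    upstream_di = c("AC", "AC", "GC", "TC"),
    downstream_di = c("CA", "CC", "CG", "CT"),
    norm = c(0.9, 0.8, 0.7, 0.6), stringsAsFactors = FALSE)
  up <- group_by_context(sites_df, "upstream")
  expect_identical(lengths(up), c(AC = 2L, CC = 0L, GC = 1L, TC = 1L))
  dn <- group_by_context(sites_df, "downstream")
  expect_identical(lengths(dn), c(CA = 1L, CC = 1L, CG = 1L, CT = 1L))
})

test_that("one-way ANOVA matches hand computation and handles edge cases", {
  # groups [1,2] vs [3,4]: SSB = 4, SSW = 1, F = (4/1)/(1/2) = 8 on (1, 2) df
  av <- one_way_anova(list(c(1, 2), c(3, 4)))
  expect_equal(av$F, 8)
  expect_identical(c(av$df1, av$df2), c(1L, 2L))
  expect_equal(av$p, stats::pf(8, 1, 2, lower.tail = FALSE))
  # identical groups: no between-group signal
  av0 <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(av0$F, 0, tolerance = 1e-12)
  expect_equal(av0$p, 1)
  # zero within-group variance with unequal means
  avd <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_identical(avd$F, Inf)
  expect_identical(avd$p, 0)
  expect_true(avd$degenerate)
  expect_error(one_way_anova(list(c(1, 2))), "analysis undefined")
  expect_error(one_way_anova(list(1, 2)), "analysis undefined")
})

test_that("ANOVA agrees with the brute-force oracle on random instances", {
  set.seed(2024)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    groups <- replicate(k, stats::runif(sample(1:6, 1)), simplify = FALSE)
    if (sum(lengths(groups)) - k < 1) next
    a <- one_way_anova(groups)
    b <- anova_bruteforce(groups)
    expect_equal(a$F, b$F, tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-10)
  }
})

test_that("two-group F equals the squared pooled-variance t statistic", {
  set.seed(11)
  for (i in 1:20) {
    g1 <- stats::rnorm(sample(2:8, 1)); g2 <- stats::rnorm(sample(2:8, 1))
    a <- one_way_anova(list(g1, g2))
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("preference ordering formats tiers and significance", {
  groups <- list(TC = c(0.9), AC = c(0.88), CC = c(0.5), GC = c(0.1))
  expect_identical(preference_ordering(groups, p = 0.001), "TC/AC>CC>GC")
  # all means within tolerance collapse to one tier
  flat <- list(TC = c(0.80), AC = c(0.79), CC = c(0.78), GC = c(0.77))
  expect_identical(preference_ordering(flat, p = 0.01), "TC/AC/CC/GC")
  # non-significant ANOVA reports N.S.
  expect_identical(preference_ordering(groups, p = 0.2), "N.S.")
})

test_that("the GC-averse archetype is detected with GC ranked last", {
  res <- preference_recovery_study(n_runs = 3, seed = 404)
  expect_identical(res$successes, 3L)
  expect_true(all(res$details$last_context == "GC"))
})

test_that("the preference panel is balanced across upstream contexts", {
  sites <- preference_panel_sites()
  ctx <- unlist(lapply(sites, function(s) {
    proto_cps <- 1:14
    bases <- vapply(proto_cps, function(p) bescope:::protospacer_base(s, p),
                    character(1))
    vapply(proto_cps[bases == "C"],
           function(p) context_at(s, p)$upstream_di, character(1))
  }))
  counts <- table(factor(ctx, levels = c("AC", "CC", "GC", "TC")))
  expect_true(all(counts == 5L))
})
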