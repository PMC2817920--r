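test_that("average bond length is the plain arithmetic mean", {
  expect_equal(average_bond_length(c(1.957, 2.485, 1.964, 2.456, 2.184, 2.253)),
               2.2165, tolerance = 1e-12)
  expect_equal(average_bond_length(rep(2, 6)), 2)
  expect_equal(average_bond_length(c(2.499, 2.117, 2.519, 2.015, 2.237, 2.037)),
               2.2373, tolerance = 1e-4)
  expect_error(average_bond_length(numeric()), class = "asfscreen_domain_error")
  expect_error(average_bond_length(c(2, -1)), class = "asfscreen_domain_error")
})

test_that("the stability factor reproduces printed reference values", {
  # discodermolide O1-O6 complex
  expect_equal(compute_asf(1073380.93, 2.2165, 11.17, 1), 2.1299e-5,
               tolerance = 1e-4)
  # negative energy (aqua halichondrin complex): sign carries through
  expect_equal(signif(compute_asf(-1780.230, 2.307, 17.89, 1), 2), -2.3e-8)
  expect_equal(compute_asf(0, 2.2, 10, 1), 0)
})

test_that("the stability factor scales linearly in energy and inversely in dipole and charge", {
  base <- compute_asf(1.2e6, 2.2, 11, 1)
  expect_equal(compute_asf(3 * 1.2e6, 2.2, 11, 1), 3 * base)
  expect_equal(compute_asf(1.2e6, 2.2, 5.5, 1), 2 * base)
  expect_equal(compute_asf(1.2e6, 2.2, 11, 2), base / 2)
  expect_error(compute_asf(1e6, 2.2, 0, 1, complex_id = "cx-bad"),
               class = "asfscreen_division_error")
  expect_error(compute_asf(1e6, 2.2, 0, 1, complex_id = "cx-bad"), "cx-bad")
  expect_error(compute_asf(1e6, 2.2, 10, 0), class = "asfscreen_domain_error")
})

test_that("dipole-to-volume ratios reproduce the printed reference values", {
  expect_equal(compute_dv(1.74, 19.24), 0.090, tolerance = 5e-3)
  expect_equal(compute_dv(0, 124.80), 0)
  expect_equal(signif(compute_dv(11.17, 647.87), 3), 0.0172)
  expect_error(compute_dv(1.5, 0), class = "asfscreen_domain_error")
})

test_that("covalency filters flag long average and single bonds independently", {
  # printed halichondrin distances averaging just over the 2.7 threshold
  x <- make_descriptors(list(c(2.729, 2.769, 2.750, 2.782, 2.592, 2.729)))
  filtered <- apply_filters(x)
  expect_false(filtered$passed)
  expect_equal(filtered$filter_reasons, "abl_gt_max")

  expect_true(apply_filters(make_descriptors(list(rep(2, 6))))$passed)

  one_long <- apply_filters(make_descriptors(list(c(rep(2, 5), 2.95))))
  expect_equal(one_long$filter_reasons, "bond_gt_max")

  both <- apply_filters(make_descriptors(list(rep(2.95, 6))))
  expect_equal(both$filter_reasons, "abl_gt_max;bond_gt_max")

  # thresholds are configurable and strict inequalities
  at_threshold <- make_descriptors(list(rep(2.7, 6)))
  expect_true(apply_filters(at_threshold)$passed)
  loose <- asf_filter_config(max_average_bond_length = 3.0,
                             max_single_bond_length = 3.0)
  expect_true(apply_filters(both, loose)$passed)
})

test_that("raising the average-bond threshold never fails a passing complex", {
  set.seed(42)
  distances <- replicate(25, runif(6, 1.9, 3.0), simplify = FALSE)
  x <- make_descriptors(distances)
  thresholds <- seq(2.0, 3.2, by = 0.1)
  verdicts <- vapply(thresholds, function(th) {
    apply_filters(x, asf_filter_config(max_average_bond_length = th))$passed
  }, logical(nrow(x)))
  for (i in seq_len(ncol(verdicts) - 1)) {
    expect_true(all(verdicts[, i] <= verdicts[, i + 1]))
  }
})

test_that("scoring a table computes ASF even for rule-violating rows", {
  t2 <- score_complexes(load_fixture("table2"))
  expect_s3_class(t2, "asf_results")
  expect_equal(nrow(t2), 10)
  expect_true(all(abs(t2$asf - t2$printed_asf) / t2$printed_asf <= 0.01))

  t5 <- score_complexes(load_fixture("table5"))
  expect_equal(t5$asf[t5$complex_id == "DisW-01"], 1.1878e-5,
               tolerance = 1e-4)

  # the filtered-out halichondrin rows still carry scores
  t4 <- score_complexes(load_fixture("table4"))
  expect_true(any(!t4$passed))
  expect_true(all(is.finite(t4$asf)))

  empty <- score_complexes(load_fixture("table2")[0, ])
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "asf_results")
})

test_that("ranking is ascending, tie-broken by id, and a permutation", {
  res <- tibble::tibble(
    complex_id = c("a", "b", "c"),
    asf = c(3e-5, 1e-5, 2e-5),
    passed = TRUE
  )
  top2 <- rank_complexes(res, k = 2)
  expect_equal(top2$complex_id, c("b", "c"))
  expect_equal(top2$rank, 1:2)

  signed <- tibble::tibble(
    complex_id = c("p", "q", "r"),
    asf = c(-6.3e-5, 2.5e-7, 6.9e-5),
    passed = TRUE
  )
  expect_equal(rank_complexes(signed)$complex_id[1], "p")
  expect_equal(rank_complexes(signed, policy = "magnitude")$complex_id[1], "q")

  ties <- tibble::tibble(complex_id = c("z", "a", "m"), asf = 1e-5,
                         passed = TRUE)
  expect_equal(rank_complexes(ties)$complex_id, c("a", "m", "z"))

  # permutation property over a scored fixture
  scored <- score_complexes(load_fixture("table3"))
  ranked <- rank_complexes(scored, include_filtered = TRUE)
  expect_setequal(ranked$complex_id, scored$complex_id)
  expect_equal(ranked$rank, seq_len(nrow(scored)))

  expect_error(rank_complexes(res, policy = "best"),
               class = "asfscreen_config_error")

  # failing complexes are excluded unless asked for
  t4 <- score_complexes(load_fixture("table4"))
  expect_lt(nrow(rank_complexes(t4)), nrow(t4))
  expect_equal(nrow(rank_complexes(t4, include_filtered = TRUE)), nrow(t4))
})

test_that("group summaries are plain means plus best and mean ASF", {
  s <- summarize_group(load_fixture("table2"), "Fe-Disco-top10")
  expect_equal(s$dipole_debye, 11.856, tolerance = 1e-12)
  expect_equal(s$n, 10)

  t5 <- load_fixture("table5")
  s5 <- summarize_group(t5, "Fe-Disco-H2O-top10")
  expect_equal(s5$abl_A, mean(t5$printed_abl), tolerance = 1e-3)

  one <- summarize_group(load_fixture("table2")[1, ], "single")
  expect_equal(one$dipole_debye, 11.17)
  expect_equal(one$asf_best, one$asf_mean)

  scored <- score_complexes(load_fixture("table4"))
  s4 <- summarize_group(scored, "Fe-Hali-top10")
  expect_equal(s4$asf_best, min(scored$asf))

  expect_error(summarize_group(load_fixture("table2")[0, ], "empty"),
               class = "asfscreen_domain_error")
})

test_that("replication flags exactly the documented inconsistent rows", {
  for (tn in c("table2", "table3", "table5", "table6")) {
    rep <- replicate_table(tn)
    expect_true(all(rep$abl_consistent), label = paste(tn, "abl"))
    expect_true(all(rep$dv_consistent), label = paste(tn, "dv"))
    expect_true(all(rep$asf_consistent), label = paste(tn, "asf"))
  }
  t4 <- replicate_table("table4")
  expect_equal(t4$complex_id[!t4$dv_consistent], "Hali-03")
  expect_setequal(t4$complex_id[!t4$asf_consistent], c("Hali-02", "Hali-06"))
  expect_equal(t4$complex_id[t4$incomplete], "Hali-06")
  t7 <- replicate_table("table7")
  expect_true(all(t7$dv_consistent))
  expect_true(all(t7$asf_consistent))
})
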