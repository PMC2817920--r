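test_that("donor identification labels O and N atoms in file order", {
  donors <- identify_donors(asf_fixture_path("toy9donors_synthetic.sdf"))
  expect_equal(nrow(donors), 9)
  expect_equal(donors$label, c(paste0("O", 1:8), "N1"))
  expect_equal(donors$element, c(rep("O", 8), "N"))
  expect_equal(donors$atom_index, 0:8)
  # deterministic for a fixed file
  expect_identical(donors,
                   identify_donors(asf_fixture_path("toy9donors_synthetic.sdf")))

  water <- identify_donors(write_water_sdf())
  expect_equal(water$label, "O1")

  expect_error(identify_donors(tempfile("nope", fileext = ".sdf")),
               class = "asfscreen_format_error")
})

test_that("a user label map overrides file-order numbering", {
  path <- asf_fixture_path("toy9donors_synthetic.sdf")
  relabeled <- identify_donors(path, label_map = c("0" = "O12", "8" = "N3"))
  expect_equal(relabeled$label[1], "O12")
  expect_equal(relabeled$label[9], "N3")
  expect_equal(relabeled$label[2], "O2")

  json <- withr::local_tempfile(fileext = ".json")
  writeLines('{"0": "O12", "8": "N3"}', json)
  expect_identical(identify_donors(path, label_map = json), relabeled)
})

test_that("shell enumeration matches a brute-force subset oracle", {
  for (n in c(6, 8, 9, 11)) {
    labels <- paste0("O", 1:n)
    shells <- enumerate_shells(labels)
    expect_equal(nrow(shells), length(brute_subsets(labels, 6)))
    aqua <- enumerate_shells(labels, include_aqua = TRUE)
    expect_equal(sum(aqua$has_aqua), length(brute_subsets(labels, 5)))
    expect_equal(sum(!aqua$has_aqua), length(brute_subsets(labels, 6)))
  }
  # 8 donors -> C(8,6) = 28; 9 donors with aqua -> 84 + 126 = 210
  expect_equal(nrow(enumerate_shells(paste0("O", 1:8))), 28)
  expect_equal(nrow(enumerate_shells(paste0("O", 1:9), include_aqua = TRUE)),
               210)
  expect_equal(nrow(enumerate_shells(paste0("O", 1:6))), 1)
})

test_that("every shell satisfies its size invariant and none repeats", {
  donors <- identify_donors(asf_fixture_path("toy9donors_synthetic.sdf"))
  shells <- enumerate_shells(donors, include_aqua = TRUE)
  expect_equal(anyDuplicated(paste(shells$donors, shells$has_aqua)), 0)
  sizes <- lengths(strsplit(shells$donors, ";"))
  expect_true(all(sizes + shells$has_aqua == 6))
  expect_true(all(shells$n_donors[shells$has_aqua] == 5))
  # deterministic lexicographic order
  expect_identical(shells, enumerate_shells(donors, include_aqua = TRUE))
  six <- shells$donors[!shells$has_aqua]
  expect_equal(six, sort(six, method = "radix"))
})

test_that("the geometry prefilter drops shells with distant donor pairs", {
  donors <- identify_donors(asf_fixture_path("toy9donors_synthetic.sdf"))
  all_shells <- enumerate_shells(donors)
  tight <- enumerate_shells(donors, max_span = 5.0)
  expect_lt(nrow(tight), nrow(all_shells))
  # every surviving shell respects the span bound
  coords <- as.matrix(donors[, c("x", "y", "z")])
  rownames(coords) <- donors$label
  spans <- vapply(strsplit(tight$donors, ";"), function(lbl) {
    max(dist(coords[lbl, , drop = FALSE]))
  }, numeric(1))
  expect_true(all(spans <= 5.0))
  expect_error(enumerate_shells(paste0("O", 1:7), max_span = 5.0),
               class = "asfscreen_geometry_error")
})

test_that("too few donors is a capacity error", {
  expect_error(enumerate_shells(paste0("O", 1:5)),
               class = "asfscreen_capacity_error")
  expect_error(enumerate_shells(paste0("O", 1:4), include_aqua = TRUE),
               class = "asfscreen_capacity_error")
  # 5 donors suffice in aqua mode
  aqua <- enumerate_shells(paste0("O", 1:5), include_aqua = TRUE)
  expect_equal(nrow(aqua), 1)
  expect_true(aqua$has_aqua)
})

test_that("capping keeps at most max_count shells per coordination mode", {
  shells <- enumerate_shells(paste0("O", 1:9), include_aqua = TRUE)
  capped <- cap_shells(shells, 50)
  expect_equal(sum(!capped$has_aqua), 50)
  expect_equal(sum(capped$has_aqua), 50)
  # non-binding cap returns everything
  expect_equal(nrow(cap_shells(enumerate_shells(paste0("O", 1:8)), 50)), 28)
  # seeded random selection is reproducible and distinct from "first"
  r1 <- cap_shells(shells, 50, rule = "random", seed = 17)
  r2 <- cap_shells(shells, 50, rule = "random", seed = 17)
  expect_identical(r1, r2)
  expect_error(cap_shells(shells, 50, rule = "random"),
               class = "asfscreen_config_error")
  expect_error(cap_shells(shells, 0), class = "asfscreen_config_error")
})

test_that("rotamer counting is exact powers of three", {
  expect_equal(count_conformers(15), 14348907)
  expect_equal(count_conformers(0), 1)
  expect_equal(count_conformers(3), 27)
  for (n in c(1, 7, 20, 32)) {
    expect_equal(count_conformers(n + 1), 3 * count_conformers(n))
  }
  # beyond double precision the exact decimal digits are preserved
  expect_equal(count_conformers(40), "12157665459056928801")
  expect_error(count_conformers(-1), class = "asfscreen_domain_error")
  expect_error(count_conformers(2.5), class = "asfscreen_domain_error")
})
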