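test_that("pooled t-test matches the closed form and t.test", {
  res <- two_group_test(c(10, 11, 12), c(13, 14, 15))
  expect_equal(res$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(res$p_value, 0.0213116, tolerance = 1e-5)
  expect_equal(res$df, 4)
  # agrees with stats::t.test on non-degenerate data
  withr::with_seed(5, {
    x <- rnorm(4); y <- rnorm(5, 1)
  })
  ref <- stats::t.test(x, y, var.equal = TRUE)
  mine <- two_group_test(x, y)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
  # identical groups: t = 0, p = 1
  same <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # both constant but unequal: variance floor keeps p finite and tiny
  degen <- two_group_test(c(5, 5, 5), c(7, 7, 7))
  expect_true(is.finite(degen$statistic))
  expect_lt(degen$p_value, 1e-10)
  expect_error(two_group_test(1, c(1, 2)), class = "photocolony_input_error")
})

test_that("BH adjustment matches hand computations and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "photocolony_input_error")
  # NA (untestable) entries pass through without affecting the correction
  expect_equal(bh_adjust(c(0.001, NA, 0.5)), c(0.002, NA, 0.5))

  # all permutations of up to 6 p-values agree with the brute-force oracle
  base_sets <- list(
    c(0.001, 0.01, 0.04, 0.04, 0.2, 0.9),
    c(0.5, 0.01, 0.22, 0.013, 0.94),
    c(0, 0.5, 1)
  )
  for (ps in base_sets) {
    perms <- pracma::perms(seq_along(ps))
    for (r in seq_len(nrow(perms))) {
      p <- ps[perms[r, ]]
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  }
})

test_that("regulation classification applies the p and fold-change gates", {
  expect_equal(classify_regulation(-1.32, 0.001, "both"), "down")
  expect_equal(classify_regulation(1.8, 0.003, "both"), "up")
  expect_equal(classify_regulation(0.5, 0.001, "both"), "unchanged")
  expect_equal(classify_regulation(-2.5, 0.02, "both"), "unchanged")
  # boundary values do not pass strict gates
  expect_equal(classify_regulation(-1, 0.001, "both"), "unchanged")
  expect_equal(classify_regulation(-1.5, 0.01, "both"), "unchanged")
  # detection-pattern calls override the quantitative rule
  expect_equal(classify_regulation(NA, NA, "ref_only"), "repressed_complete")
  expect_equal(classify_regulation(NA, NA, "mut_only"), "induced_complete")
  expect_equal(classify_regulation(NA, NA, "untestable"), "untestable")
})

test_that("the pipeline is symmetric under group relabeling", {
  cfg <- scenario_config("WT", seed = 17, n_proteins = 120,
                         effect_fraction = 0.2, complete_fraction = 0.05)
  ab <- make_abundance_table(cfg)$abundance
  fwd <- proteome_de(ab, ref_group = "WT", mut_group = "dmoeA")
  rev <- proteome_de(ab, ref_group = "dmoeA", mut_group = "WT")
  swap <- c(up = "down", down = "up", unchanged = "unchanged",
            repressed_complete = "induced_complete",
            induced_complete = "repressed_complete",
            untestable = "untestable")
  expect_equal(unname(swap[fwd$call]), rev$call)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
})

test_that("calls partition the protein list and handle missingness", {
  cfg <- scenario_config("WT", seed = 23, n_proteins = 200,
                         effect_fraction = 0.1, complete_fraction = 0.04)
  ab <- make_abundance_table(cfg)
  calls <- proteome_de(ab$abundance)
  # counts conservation: every protein gets exactly one call
  expect_equal(nrow(calls), 200)
  expect_equal(sum(table(calls$call)), 200)
  expect_true(all(calls$call %in% c("up", "down", "unchanged",
                                    "repressed_complete", "induced_complete",
                                    "untestable")))
  # complete-pattern calls match the detection pattern exactly
  expect_equal(calls$call == "repressed_complete",
               calls$detection == "ref_only")
  expect_equal(calls$call == "induced_complete",
               calls$detection == "mut_only")
  # a protein with a single detected replicate in one group is untestable
  ab1 <- tibble::tibble(
    accession = "P1",
    group = rep(c("WT", "dmoeA"), each = 3),
    replicate = rep(1:3, 2),
    abundance = c(10, NA, NA, 9, 10, 11)
  )
  expect_equal(proteome_de(ab1)$call, "untestable")
})

test_that("null tables stay near the nominal type-I level and planted effects are recovered", {
  # nulls: fraction of testable proteins with p < 0.01 stays below 0.03
  for (seed in 1:10) {
    cfg <- scenario_config("WT", seed = seed, n_proteins = 300,
                           effect_fraction = 0, complete_fraction = 0)
    calls <- proteome_de(make_abundance_table(cfg)$abundance)
    expect_lte(mean(calls$p_value < 0.01, na.rm = TRUE), 0.03)
  }
  # planted +/-2 log2 effects in 10% of 1000 proteins: >= 70% recovered
  cfg <- scenario_config("WT", seed = 42, n_proteins = 1000)
  ab <- make_abundance_table(cfg)
  calls <- proteome_de(ab$abundance)
  joined <- dplyr::inner_join(calls, ab$truth, by = "accession")
  planted <- joined[joined$true_class %in% c("up", "down"), ]
  expect_gte(mean(planted$call == planted$true_class), 0.70)
})

test_that("secretion filter unions the two flags and reports sub-counts", {
  calls <- tibble::tibble(accession = sprintf("PAM9%04d", 1:80),
                          call = "down")
  ann <- tibble::tibble(
    accession = calls$accession,
    has_signal_peptide = c(rep(TRUE, 59), rep(FALSE, 21)),
    nonclassical_secreted = c(rep(FALSE, 59), rep(TRUE, 10), rep(FALSE, 11))
  )
  kept <- secretion_filter(calls, ann)
  counts <- attr(kept, "secretion_counts")
  expect_equal(counts$signal_peptide, 59)
  expect_equal(counts$nonclassical, 10)
  expect_equal(counts$union, 69)
  # a doubly flagged protein counts once; unflagged proteins are excluded
  ann2 <- ann
  ann2$nonclassical_secreted[1] <- TRUE
  expect_equal(attr(secretion_filter(calls, ann2), "secretion_counts")$union, 69)
  # missing annotations warn and drop
  expect_warning(out <- secretion_filter(calls, ann[-1, ]), "lack annotation")
  expect_equal(nrow(out), 68)
})

test_that("percentage bookkeeping reproduces one-decimal rounding", {
  expect_equal(summarize_counts(3181, 5471), 58.1)
  expect_equal(summarize_counts(909, 1504), 60.4)
  expect_equal(summarize_counts(324, 3181), 10.2)
  expect_equal(summarize_counts(0, 10), 0)
  expect_equal(summarize_counts(1, 1), 100)
  expect_true(is.na(summarize_counts(0, 0)))
  expect_error(summarize_counts(5, 3), class = "photocolony_input_error")
  # half-away-from-zero at the first decimal
  expect_equal(summarize_counts(125, 1000), 12.5)
  expect_equal(summarize_counts(1, 16), 6.3)   # 6.25 -> 6.3
})

test_that("cluster overlay reports dominant direction with tie handling", {
  clusters <- tibble::tibble(
    contig = "c1", start = c(1, 1100, 2200, 3300), end = c(1000, 2100, 3200, 4300),
    strand = "+", name = c("PAM95095", "PAM95094", "PAM95093", "PAM95092")
  ) |> cluster_loci()
  calls <- tibble::tibble(
    accession = c("PAM95095", "PAM95094", "PAM95093"),
    call = c("up", "up", "up")
  )
  ov <- overlay_clusters(calls, clusters)
  expect_equal(ov$dominant, "up")
  expect_equal(ov$n_members, 4)
  expect_equal(ov$fraction_detected, 0.75)
  # all unchanged: no dominant direction
  calls2 <- tibble::tibble(accession = clusters$name, call = "unchanged")
  expect_equal(overlay_clusters(calls2, clusters)$dominant, "none")
  # an up/down tie is mixed
  calls3 <- tibble::tibble(accession = clusters$name,
                           call = c("up", "down", "unchanged", "unchanged"))
  expect_equal(overlay_clusters(calls3, clusters)$dominant, "mixed")
  # complete-pattern calls count toward their direction
  calls4 <- tibble::tibble(accession = clusters$name,
                           call = c("repressed_complete", "down", "unchanged",
                                    "unchanged"))
  expect_equal(overlay_clusters(calls4, clusters)$dominant, "down")
})
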