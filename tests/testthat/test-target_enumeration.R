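test_that("stop-gain counting matches hand-derived examples and bounds", {
  expect_equal(count_stop_gain_sites("ATGTGGAAATAA"), 3L)  # TGG: 2, AAA: 1
  expect_equal(count_stop_gain_sites("ATGGGGGGGTAA"), 0L)
  br <- count_stop_gain_sites("ATGTGGAAATAA", per_codon = TRUE)
  expect_equal(br$breakdown$stop_gain, c(2L, 1L))
  for (seed in 1:5) {
    cds <- random_cds(50, seed)
    expect_lte(count_stop_gain_sites(cds), 3L * (50 - 2))
  }
})

test_that("frameshift site weighting follows the homopolymer rule", {
  cds <- random_cds(100, 3)  # 300 nt
  expect_equal(count_frameshift_sites(cds, list(h = 1, min_run = 4)), 300)
  # content-invariance at h = 1
  expect_equal(count_frameshift_sites(random_cds(100, 4)), 300)
  # planted 6-nt run with h = 4: L + 6 * (4 - 1)
  base <- "ATGCGTCGATGCCGTTGA"
  planted <- plant_codon(plant_codon(base, 3, "AAA"), 4, "AAA")
  expect_equal(substr(planted, 7, 12), "AAAAAA")
  expect_equal(count_frameshift_sites(planted, list(h = 4, min_run = 4)),
               nchar(planted) + 6 * 3)
  expect_error(count_frameshift_sites(base, list(h = -1)), "negative")
})

test_that("direct-repeat scanner finds the documented example", {
  hits <- scan_direct_repeats("ATGGCCGATTACGATTACTAA", min_repeat_len = 6)
  expect_equal(nrow(hits), 1L)
  expect_match(hits$repeat_seq, "GATTAC")
  expect_equal(hits$deletion_len, 6L)
  expect_true(hits$frame_preserving)
  # 5-bp repeat at separation 5 is frame-breaking
  h5 <- scan_direct_repeats("ATGAAGCATGCCATGCCTGCACGTTAA",
                            min_repeat_len = 5, max_deletion_len = 50)
  h5 <- h5[h5$repeat_len == 5 & h5$deletion_len == 5, ]
  expect_true(all(!h5$frame_preserving))
  expect_equal(nrow(scan_direct_repeats("ATGTAA")), 0L)
  expect_error(scan_direct_repeats("ATGTAA", min_repeat_len = 3), ">= 4")
})

test_that("scanner output is sound, complete and suffix-stable", {
  for (seed in 1:6) {
    n <- sample(60:180, 1)
    seq <- substr(random_cds(ceiling(n / 3) + 2, seed), 1, n)
    hits <- scan_direct_repeats(seq, min_repeat_len = 4, max_deletion_len = 60)
    oracle_check_repeats(seq, hits, 4, 60)
    # appending sequence never removes a repeat: every hit persists (possibly
    # extended) after a suffix is appended
    ext <- scan_direct_repeats(paste0(seq, "ACG"), 4, 60)
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      match_row <- ext[ext$deletion_len == h$deletion_len &
                         ext$left_start <= h$left_start &
                         ext$left_start + ext$repeat_len >=
                           h$left_start + h$repeat_len, , drop = FALSE]
      expect_gte(nrow(match_row), 1L)
    }
  }
})

test_that("restricted missense counts equal brute force", {
  skip_if_not_installed("Biostrings")
  # single TGG codon region: 9 mutants - 2 nonsense - 0 synonymous = 7
  cds <- "ATGTGGAAATAA"
  expect_equal(restricted_missense_target(
    cds, data.frame(start = 2, end = 2)), 7L)
  expect_equal(restricted_missense_target(cds, NULL), 0L)
  expect_equal(restricted_missense_target(cds, data.frame(start = integer(),
                                                          end = integer())),
               0L)
  for (seed in 1:3) {
    cds <- random_cds(40, seed)
    whole <- data.frame(start = 1, end = 39)
    # initiator codon is excluded by design (loss of initiation, not missense)
    expect_equal(restricted_missense_target(cds, whole),
                 oracle_missense(cds, 2:39))
  }
  expect_error(restricted_missense_target(cds, data.frame(start = 1, end = 99)),
               "outside protein")
})

test_that("constraint sets shape per-gene targets correctly", {
  fx <- fixture_cache()
  gm <- fx$gene_models
  awsx <- lof_target(gm$awsX, "inframe_only", fx$regions)
  expect_equal(awsx[["frameshift_indel"]], 0)
  expect_equal(awsx[["nonsense"]], 0)
  expect_gt(awsx[["inframe_indel"]], 0)
  wspf <- lof_target(gm$wspF, "any_lof", fx$regions)
  expect_gte(sum(wspf), count_stop_gain_sites(gm$wspF$cds_seq))
  none <- lof_target(gm$wspF, "none", fx$regions)
  expect_true(all(none == 0))
  expect_error(lof_target(gm$wspF, "sometimes"), "arg")
})

test_that("targets are monotone under region enlargement and constraint relaxation", {
  fx <- fixture_cache()
  g <- fx$gene_models$awsR
  small <- data.frame(gene_name = "awsR", kind = "aa_range", start = 25,
                      end = 60, allowed_classes = "missense")
  big <- small; big$end <- 100
  t_small <- lof_target(g, "regions_only", small)
  t_big <- lof_target(g, "regions_only", big)
  expect_gte(t_big[["missense"]], t_small[["missense"]])
  # relaxing regions_only -> any_lof never decreases the total
  t_relax <- lof_target(g, "any_lof", big)
  expect_gte(sum(t_relax), sum(t_big))
})

test_that("full target table has valid structure and zero rows for disabled classes", {
  fx <- fixture_cache()
  targets <- target_size_table(fx$gene_models, pf5_constraints(), fx$regions)
  expect_true(all(targets$count >= 0))
  expect_equal(targets$count[targets$gene_name == "awsX" &
                               targets$mclass == "frameshift_indel"], 0)
  expect_equal(sum(targets$count[targets$gene_name == "wspB"]), 0)
})
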