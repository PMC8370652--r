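test_that("network logic handles the canonical cases", {
  specs <- pathway_specs()
  expect_identical(ws_output(specs$Wsp), "basal")
  expect_identical(ws_output(specs$Wsp, c(wspF = "lof")), "high")
  expect_identical(ws_output(specs$Wsp, c(wspR = "lof", wspF = "lof")), "none")
  expect_identical(ws_output(specs$Aws, c(awsX = "lof")), "high")
  # AwsX polarity: frame-breaking lesion silences downstream AwsR
  expect_identical(ws_output(specs$Aws, c(awsX = "lof_frame_breaking")),
                   "none")
  expect_identical(ws_output(specs$Mws, c(mwsR = "activating")), "high")
  expect_identical(ws_output(specs$Mws, c(mwsR = "lof")), "none")
  del <- pathway_specs(deleted = c("Wsp"))
  expect_identical(ws_output(del$Wsp, c(wspF = "lof")), "none")
  expect_error(ws_output(specs$Wsp, c(wspF = "broken")), "unknown component state")
  expect_error(ws_output(specs$Wsp, c(wspZ = "lof")), "unknown component")
})

test_that("network logic matches the exhaustive truth-table oracle", {
  specs <- pathway_specs()
  states <- c("wildtype", "lof", "lof_frame_breaking", "activating", "absent")
  # full enumeration for the small pathways
  for (pname in c("Aws", "Mws", "DgcH")) {
    spec <- specs[[pname]]
    comps <- names(spec$components)
    grid <- expand.grid(rep(list(states), length(comps)),
                        stringsAsFactors = FALSE)
    names(grid) <- comps
    for (i in seq_len(nrow(grid))) {
      st <- unlist(grid[i, , drop = FALSE])
      expect_identical(ws_output(spec, st), oracle_ws_output(spec, st),
                       info = paste(pname, paste(st, collapse = ",")))
    }
  }
  # Wsp: full enumeration over the four signalling-relevant components
  spec <- specs$Wsp
  grid <- expand.grid(wspA = states, wspE = states, wspF = states,
                      wspR = states, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    st <- unlist(grid[i, , drop = FALSE])
    expect_identical(ws_output(spec, st), oracle_ws_output(spec, st))
  }
  # plus every single perturbation of the scaffold components
  for (comp in c("wspB", "wspC", "wspD")) {
    for (s in states) {
      st <- setNames(s, comp)
      expect_identical(ws_output(spec, st), oracle_ws_output(spec, st))
    }
  }
})

toy_targets <- function(counts) {
  out <- data.frame(gene_name = c("wspF", "awsX", "mwsR"),
                    pathway = c("Wsp", "Aws", "Mws"),
                    mclass = "missense", count = counts,
                    stringsAsFactors = FALSE)
  class(out) <- c("ws_target_table", class(out))
  out
}

test_that("spectrum prediction normalizes, scales and renormalizes on knockout", {
  p <- null_model_params(rates = c(substitution = 1, indel = 0,
                                   promoter_point = 0))
  eq <- predict_spectrum(toy_targets(c(5, 5, 5)), p)
  expect_equal(unname(eq$pathway_probs), rep(1 / 3, 3), tolerance = 1e-12)
  w <- predict_spectrum(toy_targets(c(10, 5, 5)), p)
  expect_equal(unname(w$pathway_probs[c("Wsp", "Aws", "Mws")]),
               c(0.5, 0.25, 0.25))
  expect_equal(sum(w$gene_probs), 1)
  # scaling invariance of the rate vector
  p10 <- null_model_params(rates = c(substitution = 10, indel = 0,
                                     promoter_point = 0))
  w10 <- predict_spectrum(toy_targets(c(10, 5, 5)), p10)
  expect_equal(w10$gene_probs, w$gene_probs)
  expect_equal(w10$mu_relative, 10 * w$mu_relative)
  # knockout renormalizes the remainder proportionally
  kn <- predict_spectrum(toy_targets(c(10, 5, 5)), p,
                         specs = pathway_specs(deleted = "Wsp"))
  expect_equal(unname(kn$pathway_probs[c("Aws", "Mws")]), c(0.5, 0.5))
  expect_error(predict_spectrum(toy_targets(c(0, 0, 0)), p),
               "undefined spectrum")
})

test_that("gene ranking is stable with alphabetical tie-break", {
  p <- null_model_params(rates = c(substitution = 1, indel = 0,
                                   promoter_point = 0))
  eq <- predict_spectrum(toy_targets(c(5, 5, 5)), p)
  expect_identical(rank_genes(eq), sort(c("wspF", "awsX", "mwsR")))
  single <- toy_targets(c(3, 0, 0))
  expect_identical(rank_genes(predict_spectrum(single, p))[1], "wspF")
})

test_that("the frozen configuration reproduces the published pathway hierarchy", {
  fx <- fixture_cache()
  targets <- target_size_table(fx$gene_models, pf5_constraints(), fx$regions)
  params <- load_null_model_config(fx$config_path)
  pred <- predict_spectrum(targets, params)
  pw <- pred$pathway_probs
  expect_equal(unname(pw["Wsp"]), 0.54, tolerance = 0.02 / 0.54)
  expect_identical(names(pw), c("Wsp", "Aws", "Mws"))
  expect_setequal(utils::head(rank_genes(pred), 6),
                  c("wspA", "wspE", "wspF", "awsR", "awsX", "mwsR"))
})

test_that("params validation rejects degenerate rate vectors", {
  expect_error(null_model_params(rates = c(substitution = -1, indel = 1)),
               ">= 0")
  expect_error(null_model_params(rates = c(substitution = 0, indel = 0)),
               "positive rate")
})
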