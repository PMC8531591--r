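test_that("feature expressions parse to the declared kinds", {
  r <- parse_feature_expr("HSP90AB1/HSP90AA1")
  expect_equal(r$kind, "ratio")
  expect_equal(r$operands, list("HSP90AB1", "HSP90AA1"))
  p <- parse_feature_expr("HSPB1*HSPA9")
  expect_equal(p$kind, "product")
  s <- parse_feature_expr("(CCT1+CCT2+CCT5)/HSP90AA1")
  expect_equal(s$kind, "ratio")
  expect_equal(s$operands[[1]], c("CCT1", "CCT2", "CCT5"))
  raw <- parse_feature_expr("TRAP1")
  expect_equal(raw$kind, "raw")
  fam <- parse_feature_expr("HSPA2+HSPA6+HSPA8")
  expect_equal(fam$kind, "sum")
  expect_equal(length(fam$operands[[1]]), 3)
  # aliases canonicalize inside expressions
  expect_equal(parse_feature_expr("TCP1/HSP90AA1")$operands[[1]], "CCT1")
})

test_that("malformed expressions fail with a positioned parse error", {
  expect_error(parse_feature_expr("HSP90AA1/"), "missing operand")
  expect_error(parse_feature_expr("/TRAP1"), "missing operand")
  expect_error(parse_feature_expr("A/B/C"), "top-level")
  expect_error(parse_feature_expr("A~B"), "position 2")
  expect_error(parse_feature_expr("(A+B"), "unbalanced")
  expect_error(parse_feature_expr(""), "empty")
})

test_that("render is the inverse of parse on canonical strings", {
  canon <- c("TRAP1", "HSP90AA1/TRAP1", "HSPB1*HSPA9",
             "(CCT1+CCT2+CCT5)/HSP90AA1", "HSPA2+HSPA6+HSPA8",
             "(HSPA2+HSPA6)*(DNAJA1+DNAJA2)")
  for (s in canon)
    expect_identical(render_feature_expr(parse_feature_expr(s)), s)
})

test_that("feature evaluation computes ratio / product / sum arithmetic", {
  m <- matrix(c(4, 2, 3, 2, 6, 1), nrow = 1,
              dimnames = list("s1", c("HSP90AB1", "HSP90AA1", "HSPB1",
                                      "HSPA9", "CCT1", "CCT2")))
  fx <- evaluate_feature_set(m, list("HSP90AB1/HSP90AA1", "HSPB1*HSPA9",
                                     "(CCT1+CCT2)/HSP90AA1",
                                     "CCT1+CCT2"))
  expect_equal(unname(fx[1, ]), c(2, 6, 3.5, 7))
  expect_identical(colnames(fx),
                   c("HSP90AB1/HSP90AA1", "HSPB1*HSPA9",
                     "(CCT1+CCT2)/HSP90AA1", "CCT1+CCT2"))
  expect_error(evaluate_feature_set(m, list("HSPA4/CCT1")), "HSPA4")
})

test_that("sentinel-over-sentinel ratios evaluate to one", {
  m <- matrix(c(0.0099, 0.0099), nrow = 1,
              dimnames = list("s1", c("ST13", "TRAP1")))
  fx <- evaluate_feature_set(m, list("ST13/TRAP1"))
  expect_equal(unname(fx[1, 1]), 1)
  # denominator floored at the sentinel: a zero denominator stays finite
  m0 <- matrix(c(3, 0), nrow = 1, dimnames = list("s1", c("ST13", "TRAP1")))
  fx0 <- evaluate_feature_set(m0, list("ST13/TRAP1"))
  expect_equal(unname(fx0[1, 1]), 3 / 0.0099)
})

test_that("ratios are scale-invariant and products scale quadratically", {
  co <- generate_cohort(default_cohort_config(seed = 14))
  m <- co$matrix[1:20, ]
  feats <- list("HSP90AA1/TRAP1", "HSPB1*HSPA9",
                "(CCT1+CCT2+CCT5)/HSP90AA1")
  a <- evaluate_feature_set(m, feats, epsilon = 0)
  b <- evaluate_feature_set(3 * m, feats, epsilon = 0)
  expect_equal(b[, 1], a[, 1])
  expect_equal(b[, 3], a[, 3])
  expect_equal(b[, 2], 9 * a[, 2])
})

test_that("default feature set contains the named network features", {
  feats <- default_feature_set()
  names <- vapply(feats, `[[`, "", "name")
  expect_true(all(c(
    "HSP90AA1/TRAP1", "HSP90AB1/TRAP1", "HSP90AB1/HSP90AA1",
    "FKBP4/HSP90AA1", "HSPA6/TRAP1", "CCT2/HSP90AB1", "HSPB1*HSPA9",
    "HSPA9*TRAP1", "(CCT1+CCT2+CCT5)/HSP90AA1") %in% names))
  # HSP70-family sum uses exactly the five HSPA members
  hsp70 <- grep("^\\(HSPA", names, value = TRUE)
  expect_equal(length(hsp70), 1)
  expect_equal(parse_feature_expr(hsp70)$operands[[1]],
               c("HSPA2", "HSPA6", "HSPA8", "HSPA12", "HSPA5"))
  # every raw panel protein appears
  expect_true(all(default_panel()$symbols %in% names))
  # evaluation of the default set is finite on a generated cohort
  co <- generate_cohort(default_cohort_config(seed = 15))
  fx <- evaluate_feature_set(co$matrix, feats)
  expect_true(all(is.finite(fx)))
  expect_identical(rownames(fx), rownames(co$matrix))
})

test_that("features with symbols outside the panel are dropped loudly", {
  panel <- default_panel()
  fam <- lapply(panel$families, setdiff, "TRAP1")
  smaller <- panel_definition(setdiff(panel$symbols, "TRAP1"), fam)
  expect_warning(feats <- default_feature_set(smaller), "TRAP1")
  names <- vapply(feats, `[[`, "", "name")
  expect_false(any(grepl("TRAP1", names)))
})

test_that("feature definition files read with comments and blanks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# chaperone ratios", "HSP90AA1/TRAP1", "",
               "HSPB1*HSPA9   # stress pair"), path)
  feats <- read_feature_file(path)
  expect_equal(vapply(feats, `[[`, "", "name"),
               c("HSP90AA1/TRAP1", "HSPB1*HSPA9"))
})
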