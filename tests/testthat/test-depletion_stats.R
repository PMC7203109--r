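test_that("run-sum normalization makes each run sum to 1, preserving ratios", {
  d <- make_design(2)
  df <- data.frame(peptide = c("AAAK", "CCCK", "DDDK"), protein = "P1",
                   plus_r1 = c(2, 3, 5), plus_r2 = c(1, 1, 2),
                   minus_r1 = c(4, 4, 2), minus_r2 = c(1, 0, 3))
  x <- make_peptides(df, d$run_id)
  norm <- normalize_run_intensities(x, d)
  expect_equal(norm$plus_r1, c(0.2, 0.3, 0.5))
  for (r in d$run_id) expect_equal(sum(norm[[r]]), 1, tolerance = 1e-9)

  # random table: each column sums to 1, within-run ratios preserved
  set.seed(42)
  df2 <- data.frame(peptide = replicate(20, paste0(
    paste(sample(c("A", "C", "D", "E", "F", "G"), 7, TRUE), collapse = ""), "K")),
    protein = "P1")
  df2 <- df2[!duplicated(df2$peptide), ]
  mat <- matrix(rlnorm(nrow(df2) * 4, 10, 1), nrow(df2), 4,
                dimnames = list(NULL, d$run_id))
  x2 <- make_peptides(cbind(df2, as.data.frame(mat)), d$run_id)
  n2 <- normalize_run_intensities(x2, d)
  for (r in d$run_id) {
    expect_equal(sum(n2[[r]]), 1, tolerance = 1e-9)
    expect_equal(n2[[r]] / n2[[r]][1], mat[, r] / mat[1, r], tolerance = 1e-9)
  }

  # a dead run cannot be normalized
  df$plus_r1 <- 0
  expect_error(normalize_run_intensities(make_peptides(df, d$run_id), d),
               "plus_r1")
})

test_that("condition means follow the all-zero imputation rule", {
  d <- make_design(2)
  mat <- rbind(
    c(0.1, 0.3, 0.2, 0.2),   # plain means
    c(0.0, 0.0, 0.02, 0.02), # +4SU all zero -> imputed
    c(0.0, 0.4, 0.1, 0.1)    # mixed zeros count toward the mean
  )
  colnames(mat) <- d$run_id
  cm <- condition_means(mat, d)
  expect_equal(cm$mean_plus[1], 0.2)
  expect_false(cm$imputed_plus[1])
  # smallest positive condition mean anywhere is 0.02 -> floor 0.01
  expect_equal(cm$mean_plus[2], 0.01)
  expect_true(cm$imputed_plus[2])
  expect_equal(cm$mean_plus[3], 0.2)
  expect_false(cm$imputed_plus[3])

  expect_error(condition_means(mat * 0, d), "imputation floor")
})

test_that("log2 depletion ratio is antisymmetric and guarded", {
  expect_equal(depletion_ratio(0.3, 0.3), 0)
  expect_equal(depletion_ratio(1, 2), -1)
  set.seed(1)
  a <- runif(50, 0.01, 1); b <- runif(50, 0.01, 1)
  expect_equal(depletion_ratio(a, b), -depletion_ratio(b, a))
  expect_error(depletion_ratio(0, 1), "positive")
})

test_that("pooled t test matches the closed form and t.test, with degenerate rules", {
  # frozen closed-form oracle: pooled t on (1,2,3) vs (4,5,6), 4 df
  expect_equal(peptide_pvalue(c(1, 2, 3), c(4, 5, 6)), 0.0213116411,
               tolerance = 1e-8)
  # identical groups: t = 0, p = 1
  expect_equal(peptide_pvalue(c(0.2, 0.3), c(0.2, 0.3)), 1)
  # two-sidedness: symmetric in the group order
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(6, 0.5)
    expect_equal(peptide_pvalue(a, b), peptide_pvalue(b, a))
    expect_equal(peptide_pvalue(a, b),
                 t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
  # degenerate zero-variance groups
  expect_equal(peptide_pvalue(c(1, 1), c(1, 1)), 1)
  expect_equal(peptide_pvalue(c(1, 1), c(2, 2)), 1e-15)
  expect_error(peptide_pvalue(1, c(1, 2)), "at least 2")
})

test_that("RBR-ID score follows the formula with a clamped p", {
  expect_equal(rbr_score(-1, 0.01), 4)          # 2-fold depletion, p 0.01
  expect_equal(rbr_score(2.7, 1), 0)            # p = 1 kills the score
  expect_equal(rbr_score(0, 0.001), 0)          # no depletion, no score
  # sign(score) = -sign(log2_ratio)
  set.seed(3)
  lr <- rnorm(100); p <- runif(100, 1e-20, 1)
  expect_equal(sign(rbr_score(lr, pmax(p, 1e-15))), -sign(lr))
  # p below the floor is clamped, not amplified
  expect_equal(rbr_score(-1, 1e-30, p_floor = 1e-15), rbr_score(-1, 1e-15))
  expect_error(rbr_score(-1, 0), "\\(0, 1\\]")
  expect_error(rbr_score(-1, 1.2), "\\(0, 1\\]")
})

test_that("significance call is strict and directional", {
  st <- data.frame(peptide = c("A", "B", "C"), protein = "P1",
                   log2_ratio = c(-0.5, 0.5, -0.5),
                   p_value = c(0.05, 0.05, 0.1))
  kept <- significant_peptides(st, alpha = 0.1)
  expect_equal(kept$peptide, "A")  # B enriched, C at the strict boundary
})

test_that("peptide_stats equals an independent brute-force recomputation", {
  d <- make_design(3)
  df <- data.frame(
    peptide = c("AAAK", "CCCK", "DDDK", "EEEK", "FFFK"),
    protein = "P1",
    plus_r1 = c(5, 0, 9, 2.0, 0), plus_r2 = c(6, 0, 8, 2.2, 0),
    plus_r3 = c(4, 0, 10, 1.8, 0),
    minus_r1 = c(5, 3, 4, 2.1, 0), minus_r2 = c(7, 4, 5, 1.9, 0),
    minus_r3 = c(6, 2, 3, 2.0, 0)
  )
  x <- make_peptides(df, d$run_id)
  norm <- normalize_run_intensities(x, d)
  expect_warning(peptide_stats(norm, d), "no run")
  st <- suppressWarnings(peptide_stats(norm, d))
  expect_equal(nrow(st), 4L)  # FFFK detected nowhere, dropped

  # brute force with separate code: loops and t.test only
  raw <- as.matrix(df[1:4, d$run_id])
  nm <- raw
  for (j in seq_len(ncol(raw))) nm[, j] <- raw[, j] / sum(df[, d$run_id][, j])
  plus <- d$run_id[d$condition == "+4SU"]; minus <- d$run_id[d$condition == "-4SU"]
  mp <- apply(nm[, plus], 1, mean); mm <- apply(nm[, minus], 1, mean)
  floor_val <- 0.5 * min(c(mp[mp > 0], mm[mm > 0]))
  mp_i <- ifelse(mp == 0, floor_val, mp); mm_i <- ifelse(mm == 0, floor_val, mm)
  lr <- log2(mp_i / mm_i)
  pv <- sapply(1:4, function(i)
    t.test(nm[i, plus], nm[i, minus], var.equal = TRUE)$p.value)
  sc <- -lr * log10(pmax(pv, 1e-15))^2

  expect_equal(st$mean_plus, unname(mp_i), tolerance = 1e-12)
  expect_equal(st$mean_minus, unname(mm_i), tolerance = 1e-12)
  expect_equal(st$log2_ratio, unname(lr), tolerance = 1e-12)
  expect_equal(st$p_value, unname(pv), tolerance = 1e-12)
  expect_equal(st$score, unname(sc), tolerance = 1e-12)
  expect_true(st$imputed_plus[2])
  expect_false(any(st$imputed_minus))
})

test_that("scores are invariant to rescaling any single run", {
  d <- make_design(3)
  set.seed(11)
  df <- data.frame(peptide = c("AAAK", "CCCK", "DDDK", "EEEK"), protein = "P1")
  mat <- matrix(rlnorm(4 * 6, 10, 1), 4, 6, dimnames = list(NULL, d$run_id))
  x1 <- make_peptides(cbind(df, as.data.frame(mat)), d$run_id)
  mat2 <- mat; mat2[, "plus_r2"] <- mat2[, "plus_r2"] * 37.5
  x2 <- make_peptides(cbind(df, as.data.frame(mat2)), d$run_id)
  s1 <- peptide_stats(normalize_run_intensities(x1, d), d)
  s2 <- peptide_stats(normalize_run_intensities(x2, d), d)
  expect_equal(s2$score, s1$score, tolerance = 1e-9)
  expect_equal(s2$p_value, s1$p_value, tolerance = 1e-9)
})

test_that("score is monotone in effect size and confidence", {
  # p fixed: score increases as log2_ratio decreases
  lr <- seq(0.5, -3, by = -0.25)
  expect_true(all(diff(rbr_score(lr, 0.01)) > 0))
  # depleted ratio fixed: score increases as p decreases
  p <- 10^seq(-1, -10, by = -0.5)
  expect_true(all(diff(rbr_score(-1, p)) > 0))
})
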