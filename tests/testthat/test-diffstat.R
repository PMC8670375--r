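test_that("log2 transform behaves as the exact inverse of 2^x", {
  tbl <- tibble::tibble(protein = c("a", "b"), strain = "s1",
                        condition = "control", fraction = "cytosolic",
                        replicate = 1L, intensity = c(8, 1),
                        unique_peptides = 2L)
  got <- log2_transform(tbl)
  expect_equal(got$log2_intensity, c(3, 0))
  x <- stats::runif(50, -10, 30)
  tbl2 <- dplyr::mutate(tbl[rep(1, 50), ], intensity = 2^x,
                        replicate = 1:50)
  expect_equal(log2_transform(tbl2)$log2_intensity, x)
  expect_error(log2_transform(dplyr::mutate(tbl, intensity = -1)),
               "non-positive")
})

test_that("s0 statistic degenerates to the classical pooled t at s0 = 0", {
  set.seed(101)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1), mean = runif(1, -2, 2))
    b <- rnorm(sample(2:6, 1))
    classical <- unname(stats::t.test(a, b, var.equal = TRUE)$statistic)
    expect_equal(s0_tstat(a, b, s0 = 0), classical, tolerance = 1e-12)
  }
})

test_that("the statistic shrinks monotonically to zero as s0 grows", {
  set.seed(5)
  a <- rnorm(4, 2); b <- rnorm(4)
  grid <- c(0, 0.05, 0.1, 0.5, 1, 5, 50)
  vals <- vapply(grid, function(s) abs(s0_tstat(a, b, s0 = s)), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 0.05)
})

test_that("the statistic is antisymmetric and guards degenerate input", {
  a <- c(1, 2, 3); b <- c(4, 5, 7)
  expect_equal(s0_tstat(a, b), -s0_tstat(b, a))
  expect_equal(s0_tstat(a, a), 0)
  expect_error(s0_tstat(1, a), "at least 2")
})

test_that("mean differences are computed over detected replicates", {
  quant <- dplyr::bind_rows(
    quant_from_log2(list(flat = list(control = c(4, 4, 4),
                                     induced = c(4, 4, 4)))),
    quant_from_log2(list(shift = list(control = c(3, 4, 5),
                                      induced = c(5, 6)))))
  pres <- presence_all_both(c("flat", "shift"))
  d <- diff_abundance(quant, pres, seed = 1)
  expect_equal(d$difference[d$protein == "flat"], 0)
  expect_equal(d$difference[d$protein == "shift"], 1.5)
  expect_equal(d$n_induced[d$protein == "shift"], 2)
})

test_that("label swap negates differences and t while preserving p, q", {
  set.seed(77)
  vals <- lapply(1:12, function(i) {
    list(control = rnorm(3, 20), induced = rnorm(3, 20 + (i <= 3) * 2))
  })
  names(vals) <- sprintf("p%02d", 1:12)
  quant <- quant_from_log2(vals)
  swapped <- dplyr::mutate(quant, condition = ifelse(condition == "control",
                                                     "induced", "control"))
  pres <- presence_all_both(names(vals))
  d1 <- diff_abundance(quant, pres, seed = 2)
  d2 <- diff_abundance(swapped, pres, seed = 2)
  expect_equal(d2$difference, -d1$difference)
  expect_equal(d2$t_s0, -d1$t_s0)
  expect_equal(d2$p, d1$p)
  expect_equal(d2$q, d1$q)
  expect_equal(d2$significant, d1$significant)
})

test_that("extreme separation is flagged significant", {
  set.seed(33)
  vals <- lapply(1:40, function(i) {
    eff <- if (i <= 2) 5 else 0
    list(control = rnorm(3, 20, 0.2), induced = rnorm(3, 20 + eff, 0.2))
  })
  names(vals) <- sprintf("p%02d", 1:40)
  quant <- quant_from_log2(vals)
  d <- diff_abundance(quant, presence_all_both(names(vals)), seed = 3)
  expect_true(all(d$significant[d$protein %in% c("p01", "p02")]))
  expect_lt(sum(d$significant), 6)
  # BH mode agrees on such strong effects
  dbh <- diff_abundance(quant, presence_all_both(names(vals)),
                        method = "bh", seed = 3)
  expect_true(all(dbh$significant[dbh$protein %in% c("p01", "p02")]))
})

test_that("significance is monotone in the FDR threshold", {
  set.seed(55)
  vals <- lapply(1:30, function(i) {
    eff <- if (i <= 6) 3 else 0
    list(control = rnorm(3, 20, 0.5), induced = rnorm(3, 20 + eff, 0.5))
  })
  names(vals) <- sprintf("p%02d", 1:30)
  quant <- quant_from_log2(vals)
  d01 <- diff_abundance(quant, presence_all_both(names(vals)),
                        fdr = 0.01, seed = 4)
  d05 <- diff_abundance(quant, presence_all_both(names(vals)),
                        fdr = 0.05, seed = 4)
  expect_true(all(d05$significant[d01$significant]))
})

test_that("sampled randomizations converge to the exhaustive null", {
  set.seed(99)
  vals <- lapply(1:12, function(i) {
    eff <- if (i <= 2) 3 else 0
    list(control = rnorm(4, 20, 0.5), induced = rnorm(4, 20 + eff, 0.5))
  })
  names(vals) <- sprintf("p%02d", 1:12)
  quant <- quant_from_log2(vals)          # 4v4: 70 distinct assignments
  pres <- presence_all_both(names(vals))
  exact <- diff_abundance(quant, pres, n_randomizations = 100, seed = 1)
  sampled <- diff_abundance(quant, pres, n_randomizations = 60, seed = 1)
  expect_equal(sampled$t_s0, exact$t_s0)  # statistic itself is not random
  expect_lt(max(abs(sampled$q - exact$q)), 0.2)
  expect_gt(stats::cor(sampled$p, exact$p), 0.95)
})

test_that("regulation classes merge significance, sign and presence", {
  # statistics-level fixture mirroring published secretion-machinery rows
  diff <- tibble::tibble(
    strain = "midi", fraction = "cytosolic",
    protein = c("Rnc", "Ffh"),
    n_control = 3L, n_induced = 3L,
    difference = c(0.82, 0.206), t_s0 = c(5, 1),
    p = c(0.000284, 0.18), neglog10_p = c(3.547, 0.746),
    q = c(0.01, 0.4), significant = c(TRUE, FALSE))
  class(diff) <- c("diff_abund", class(diff))
  pres <- tibble::tibble(
    strain = "midi", fraction = "cytosolic",
    protein = c("Rnc", "Ffh", "HtrB"),
    call = c("both", "both", "OFF"))
  cl <- classify_regulation(diff, pres)
  expect_equal(cl$class[cl$protein == "Rnc"], "up")
  expect_equal(cl$class[cl$protein == "Ffh"], "unchanged")
  expect_equal(cl$class[cl$protein == "HtrB"], "OFF")
  # a significant negative difference is a downregulation
  diff2 <- dplyr::mutate(diff, difference = -difference)
  class(diff2) <- c("diff_abund", class(diff2))
  cl2 <- classify_regulation(diff2, pres)
  expect_equal(cl2$class[cl2$protein == "Rnc"], "down")
  # ON/OFF from presence wins regardless of any statistics row
  expect_error(classify_regulation(
    diff, dplyr::mutate(pres, call = c("ON", "both", "OFF"))),
    "both")
})

test_that("constant-intensity blocks warn and yield no significance", {
  quant <- quant_from_log2(list(a = list(control = c(4, 4, 4),
                                         induced = c(4, 4, 4)),
                                b = list(control = c(4, 4, 4),
                                         induced = c(4, 4, 4))))
  expect_warning(
    d <- diff_abundance(quant, presence_all_both(c("a", "b")), seed = 1),
    "constant")
  expect_false(any(d$significant))
})
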