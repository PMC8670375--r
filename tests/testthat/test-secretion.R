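mk_sec_fixture <- function(intensities, sp_flags, strain = "s1",
                           replicates = 1) {
  prots <- names(intensities)
  quant <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
    tibble::tibble(protein = prots, strain = strain, condition = "induced",
                   fraction = "extracellular", replicate = r,
                   intensity = unlist(intensities, use.names = FALSE),
                   unique_peptides = 5L)
  }))
  qs <- tibble::tibble(strain = strain, fraction = "extracellular",
                       protein = prots, condition = "induced",
                       n_detected = replicates, unique_peptides = 5L,
                       localization = "Extracellular",
                       loc_compatible = TRUE, qualified = TRUE)
  maps <- annotation_maps(
    localization = tibble::tibble(protein = prots,
                                  localization = "Extracellular"),
    sec_sp = tibble::tibble(protein = prots, sec_sp = sp_flags))
  list(quant = quant, qs = qs, maps = maps)
}

test_that("the Sec proportion reproduces hand-computed toy values", {
  fx <- mk_sec_fixture(list(A = 70, B = 2, C = 28),
                       c(TRUE, TRUE, FALSE))
  res <- sec_proportion(fx$quant, fx$qs, fx$maps)
  expect_equal(res$summary$mean_p_sec, 72.0)
  expect_equal(res$summary$n_sec_quantified, 2)
  expect_equal(res$summary$n_quantified, 3)

  none <- mk_sec_fixture(list(A = 70, B = 30), c(FALSE, FALSE))
  expect_equal(sec_proportion(none$quant, none$qs, none$maps)$summary$mean_p_sec, 0)
  all_sp <- mk_sec_fixture(list(A = 70, B = 30), c(TRUE, TRUE))
  expect_equal(sec_proportion(all_sp$quant, all_sp$qs, all_sp$maps)$summary$mean_p_sec, 100)
})

test_that("the Sec proportion is scale invariant and bounded", {
  fx <- mk_sec_fixture(list(A = 12.5, B = 3.1, C = 44, D = 0.7),
                       c(TRUE, FALSE, TRUE, FALSE), replicates = 3)
  res1 <- sec_proportion(fx$quant, fx$qs, fx$maps)
  scaled <- dplyr::mutate(fx$quant, intensity = intensity * 1e6)
  res2 <- sec_proportion(scaled, fx$qs, fx$maps)
  expect_equal(res1$per_replicate$p_sec, res2$per_replicate$p_sec)
  expect_true(all(res1$per_replicate$p_sec >= 0 &
                    res1$per_replicate$p_sec <= 100))
})

test_that("adding SP- proteins cannot raise, SP+ cannot lower, the proportion", {
  base <- mk_sec_fixture(list(A = 50, B = 50), c(TRUE, FALSE))
  p0 <- sec_proportion(base$quant, base$qs, base$maps)$summary$mean_p_sec
  plus_neg <- mk_sec_fixture(list(A = 50, B = 50, C = 30),
                             c(TRUE, FALSE, FALSE))
  p1 <- sec_proportion(plus_neg$quant, plus_neg$qs, plus_neg$maps)$summary$mean_p_sec
  plus_pos <- mk_sec_fixture(list(A = 50, B = 50, C = 30),
                             c(TRUE, FALSE, TRUE))
  p2 <- sec_proportion(plus_pos$quant, plus_pos$qs, plus_pos$maps)$summary$mean_p_sec
  expect_lte(p1, p0)
  expect_gte(p2, p0)
})

test_that("per-replicate averaging reports an SD and a between-strain test", {
  set.seed(71)
  mk_strain <- function(strain, shift) {
    quant <- dplyr::bind_rows(lapply(1:3, function(r) {
      tibble::tibble(protein = c("sp1", "sp2", "other"), strain = strain,
                     condition = "induced", fraction = "extracellular",
                     replicate = r,
                     intensity = c(60, 20, 20) + rnorm(3, 0, 1) + shift,
                     unique_peptides = 5L)
    }))
    qs <- tibble::tibble(strain = strain, fraction = "extracellular",
                         protein = c("sp1", "sp2", "other"),
                         condition = "induced", n_detected = 3L,
                         unique_peptides = 5L,
                         localization = "Extracellular",
                         loc_compatible = TRUE, qualified = TRUE)
    list(quant = quant, qs = qs)
  }
  a <- mk_strain("168", 0); b <- mk_strain("midi", c(-10, 0, 10))
  maps <- annotation_maps(sec_sp = tibble::tibble(
    protein = c("sp1", "sp2"), sec_sp = TRUE))
  res <- sec_proportion(dplyr::bind_rows(a$quant, b$quant),
                        dplyr::bind_rows(a$qs, b$qs), maps)
  expect_equal(nrow(res$per_replicate), 6)
  expect_true(all(res$summary$sd_p_sec >= 0))
  expect_s3_class(res$t_test, "htest")
  pooled <- sec_proportion(dplyr::bind_rows(a$quant, b$quant),
                           dplyr::bind_rows(a$qs, b$qs), maps,
                           pooled = TRUE)
  expect_true(all(is.na(pooled$summary$sd_p_sec)))
})

test_that("ON + upregulated secreted-protein counts yield the strain ratio", {
  classed <- tibble::tibble(
    strain = rep(c("168", "midi"), c(4, 2)),
    fraction = "extracellular",
    protein = c("e1", "e2", "e3", "e4", "e1", "e5"),
    class = c("ON", "up", "up", "unchanged", "up", "down"))
  maps <- annotation_maps(categories = tibble::tibble(
    protein = c("e1", "e2", "e3", "e4", "e5"),
    path = "Lifestyles/Exponential growth/Secreted proteins"))
  res <- secreted_regulation_ratio(classed, maps)
  expect_equal(res$counts$n_on_up[res$counts$strain == "168"], 3)
  expect_equal(res$counts$n_on_up[res$counts$strain == "midi"], 1)
  expect_equal(res$ratio, 3)
  # zero denominator is reported as undefined, not an error
  res0 <- secreted_regulation_ratio(
    dplyr::filter(classed, strain == "168" | class == "down"), maps)
  expect_true(is.na(res0$ratio))
  expect_error(secreted_regulation_ratio(classed, maps, category = "Nope"),
               "absent")
})

test_that("mislocalized SP+ proteins are exactly those missing extracellularly", {
  mk_qs <- function(protein, fraction, qualified = TRUE) {
    tibble::tibble(strain = "s1", fraction = fraction, protein = protein,
                   condition = "induced", n_detected = 3L,
                   unique_peptides = 5L, localization = "Cytoplasmic",
                   loc_compatible = TRUE, qualified = qualified)
  }
  qs <- dplyr::bind_rows(
    mk_qs("stuck", "membrane"),           # SP+, no extracellular: listed
    mk_qs("fine", "membrane"), mk_qs("fine", "extracellular"),
    mk_qs("nosp", "cytosolic"))
  maps <- annotation_maps(sec_sp = tibble::tibble(
    protein = c("stuck", "fine"), sec_sp = TRUE))
  got <- mislocalization_check(qs, maps)
  expect_equal(got$protein, "stuck")
  expect_equal(got$fractions, "membrane")
})

test_that("mislocalization matches a set-algebra oracle on simulated data", {
  sim <- simulate_quant_experiment(sim_config(n_proteins = 400, seed = 83))
  qs <- qualify_proteins(sim$quant, sim$annotations)
  got <- mislocalization_check(qs, sim$annotations)
  # oracle via plain set operations
  q <- qs[qs$qualified & qs$condition == "induced", ]
  sp <- sim$annotations$sec_sp$protein[sim$annotations$sec_sp$sec_sp]
  for (s in unique(q$strain)) {
    cellular <- unique(q$protein[q$strain == s &
                                   q$fraction %in% c("cytosolic", "membrane")])
    extra <- unique(q$protein[q$strain == s &
                                q$fraction == "extracellular"])
    oracle <- setdiff(intersect(cellular, sp), extra)
    expect_setequal(got$protein[got$strain == s], oracle)
  }
  # no listed protein is extracellularly qualified
  extra_all <- unique(q[q$fraction == "extracellular",
                        c("strain", "protein")])
  overlap <- dplyr::inner_join(got, extra_all, by = c("strain", "protein"))
  expect_equal(nrow(overlap), 0)
})
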