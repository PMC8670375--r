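test_that("category paths are backfilled to four levels", {
  got <- backfill_categories(tibble::tibble(
    protein = c("a", "b", "c"),
    path = c("Metabolism/Carbon", "L1/L2/L3/L4", "Solo")))
  a <- got[got$protein == "a", ]
  expect_equal(unlist(a[paste0("level", 1:4)], use.names = FALSE),
               c("Metabolism", "Carbon", "Carbon", "Carbon"))
  b <- got[got$protein == "b", ]
  expect_equal(unlist(b[paste0("level", 1:4)], use.names = FALSE),
               c("L1", "L2", "L3", "L4"))
  expect_equal(got$level4[got$protein == "c"], "Solo")
  expect_error(backfill_categories(tibble::tibble(
    protein = "x", path = "1/2/3/4/5")), "4 levels")
})

test_that("backfilled paths always have four levels (property)", {
  set.seed(17)
  labels <- c("A", "B", "C", "D", "E")
  paths <- replicate(200, paste(sample(labels, sample(1:4, 1)),
                                collapse = "/"))
  got <- backfill_categories(tibble::tibble(protein = sprintf("p%03d", 1:200),
                                            path = paths))
  expect_true(all(!is.na(got$level1) & !is.na(got$level4)))
  # backfill only ever repeats the deepest original label
  deepest <- vapply(strsplit(paths, "/"), function(p) p[length(p)], "")
  expect_equal(got$level4, deepest)
})

test_that("tallies match hand counts and honour multiple memberships", {
  classed <- tibble::tibble(
    strain = "s1", fraction = "cytosolic",
    protein = sprintf("p%02d", 1:10),
    class = c("up", "up", "down", "ON", "OFF",
              rep("unchanged", 5)))
  class(classed) <- c("regulation_classes", class(classed))
  maps <- annotation_maps(
    regulons = tibble::tibble(
      protein = c("p01", "p01", "p02", "p03", "p04", "p05", "p06"),
      regulon = c("R1", "R2", "R1", "R1", "R2", "R1", "R1"),
      mode = "activation"))
  tal <- tally_regulation(classed, maps, by = "regulon")
  r1 <- tal[tal$group == "R1", ]
  expect_equal(r1$n_up, 2)          # p01 (also in R2) and p02
  expect_equal(r1$n_down, 1)
  expect_equal(r1$n_off, 1)
  expect_equal(r1$n_total, 5)
  r2 <- tal[tal$group == "R2", ]
  expect_equal(r2$n_up, 1)          # p01 counted again in R2
  expect_equal(r2$n_on, 1)
  un <- tal[tal$group == "unannotated", ]
  expect_equal(un$n_total, 4)       # p07..p10
  # per-group class counts sum to the number of (protein, group) incidences
  expect_equal(sum(tal$n_total), 7 + 4)
})

test_that("an empty classed table tallies to nothing", {
  classed <- tibble::tibble(strain = character(), fraction = character(),
                            protein = character(), class = character())
  tal <- tally_regulation(classed, annotation_maps(), by = "regulon")
  expect_equal(nrow(tal), 0)
})

test_that("Venn regions agree with direct set algebra", {
  mk_qs <- function(strain, condition, proteins) {
    tibble::tibble(strain = strain, fraction = "cytosolic",
                   protein = proteins, condition = condition,
                   n_detected = 3L, unique_peptides = 5L,
                   localization = "Cytoplasmic", loc_compatible = TRUE,
                   qualified = TRUE)
  }
  # identical sets: core = |set|, no exclusive regions
  base <- sprintf("p%02d", 1:8)
  qs_same <- dplyr::bind_rows(
    mk_qs("a", "control", base), mk_qs("a", "induced", base),
    mk_qs("b", "control", base), mk_qs("b", "induced", base))
  cp <- core_proteome(qs_same)
  expect_equal(cp$core, 8)
  expect_equal(nrow(cp$regions), 1)

  # disjoint sets: core 0
  qs_disj <- dplyr::bind_rows(
    mk_qs("a", "control", "x1"), mk_qs("a", "induced", "x2"),
    mk_qs("b", "control", "x3"), mk_qs("b", "induced", "x4"))
  expect_equal(core_proteome(qs_disj)$core, 0)

  # random sets versus brute-force membership patterns
  set.seed(23)
  univ <- sprintf("p%03d", 1:60)
  sets <- list(a.control = sample(univ, 30), a.induced = sample(univ, 35),
               b.control = sample(univ, 25), b.induced = sample(univ, 40))
  qs_rand <- dplyr::bind_rows(purrr::imap(sets, function(prots, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    mk_qs(parts[1], parts[2], prots)
  }))
  cp <- core_proteome(qs_rand)
  expect_equal(cp$core,
               length(Reduce(intersect, sets)))
  expect_equal(sum(cp$regions$count), length(Reduce(union, sets)))
  # one spot check of an exclusive region by brute force
  only_ac <- setdiff(sets$a.control,
                     Reduce(union, sets[c("a.induced", "b.control",
                                          "b.induced")]))
  got <- cp$regions$count[cp$regions$region == "a.control"]
  expect_equal(if (length(got) == 0) 0L else got, length(only_ac))
})

test_that("altered-protein totals deduplicate across fractions", {
  classed <- tibble::tibble(
    strain = "s1",
    fraction = c("cytosolic", "membrane", "cytosolic", "cytosolic",
                 "cytosolic", "cytosolic"),
    protein = c("dup", "dup", "d1", "o1", "u1", "u2"),
    class = c("up", "up", "down", "ON", "unchanged", "unchanged"))
  expect_equal(total_altered(classed)$n_altered, 3)
  per_frac <- total_altered(classed, per_fraction = TRUE)
  expect_equal(sum(per_frac$n_altered), 4)
  # row order never matters
  shuffled <- classed[sample(nrow(classed)), ]
  expect_equal(total_altered(shuffled), total_altered(classed))
})

test_that("PCA separates well-separated conditions and is order-invariant", {
  cfg <- sim_config(n_proteins = 150, strains = "s1", frac_up = 0.3,
                    effect_log2 = 3, frac_on = 0, frac_off = 0,
                    detect_midpoint = -Inf, seed = 61)
  sim <- simulate_quant_experiment(cfg)
  quant <- dplyr::filter(sim$quant, fraction == "cytosolic")
  pca <- pca_qc(quant)
  expect_true(pca$separated)
  expect_gt(pca$between_distance, pca$within_spread)
  shuffled <- quant[sample(nrow(quant)), ]
  pca2 <- pca_qc(shuffled)
  expect_equal(dplyr::arrange(pca2$scores, sample),
               dplyr::arrange(pca$scores, sample), tolerance = 1e-9)
})

test_that("identical replicates give a degenerate ellipse with a warning", {
  quant <- quant_from_log2(list(a = list(control = c(5, 5, 5),
                                         induced = c(5, 5, 5)),
                                b = list(control = c(7, 7, 7),
                                         induced = c(7, 7, 7))))
  w <- capture_warnings(pca_qc(quant))
  expect_true(any(grepl("egenerate|zero variance", w)))
})

test_that("treemap weights sum and colors encode differences and sentinels", {
  classed <- tibble::tibble(
    strain = "s1", fraction = "cytosolic",
    protein = c("a", "b", "c", "d"),
    difference = c(0, 0, NA, NA),
    class = c("unchanged", "unchanged", "ON", "OFF"))
  maps <- annotation_maps(categories = tibble::tibble(
    protein = c("a", "b", "c", "d"),
    path = c("M/C1", "M/C2", "M/C1", "S")))
  tree <- treemap_export(classed, maps)
  expect_equal(tree$weight, 4)
  kid_weights <- vapply(tree$children, `[[`, numeric(1), "weight")
  expect_equal(sum(kid_weights), tree$weight)
  # zero differences sit at the scale midpoint; ON/OFF carry sentinels
  leaves <- list()
  walk <- function(node) {
    if (is.null(node$children)) leaves[[length(leaves) + 1]] <<- node
    else for (ch in node$children) walk(ch)
  }
  walk(tree)
  by_name <- setNames(leaves, vapply(leaves, `[[`, "", "name"))
  expect_equal(by_name$a$color, 0)
  expect_equal(by_name$c$sentinel, "ON")
  expect_equal(by_name$d$sentinel, "OFF")

  tf <- withr::local_tempfile(fileext = ".json")
  treemap_export(classed, maps, path = tf)
  back <- read_treemap(tf)
  expect_equal(back$weight, tree$weight)
  expect_equal(length(back$children), length(tree$children))
})
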