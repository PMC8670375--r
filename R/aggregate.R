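#' Backfill hierarchical category paths to four levels
#'
#' Functional-category exports assign proteins at varying depths of a
#' four-level hierarchy. For aggregation and treemap export, every path
#' is completed to exactly four levels by repeating the deepest available
#' label downwards (e.g. `Metabolism/Carbon` becomes
#' `Metabolism/Carbon/Carbon/Carbon`). Proteins with an empty path are
#' treated as unannotated and dropped here.
#'
#' @param categories Tibble with columns `protein`, `path`
#'   (`/`-separated, at most 4 levels).
#' @return A tibble with columns `protein`, `path`, `level1` .. `level4`.
#' @export
#' @examples
#' backfill_categories(tibble::tibble(protein = "a", path = "Metabolism/Carbon"))
backfill_categories <- function(categories) {
  categories <- as_tibble(categories) %>%
    filter(!is.na(.data$path), trimws(.data$path) != "")
  if (nrow(categories) == 0) {
    return(tibble(protein = character(), path = character(),
                  level1 = character(), level2 = character(),
                  level3 = character(), level4 = character()))
  }
  parts <- strsplit(categories$path, "/", fixed = TRUE)
  if (any(lengths(parts) > 4)) {
    stop_secretomics("Category paths must have at most 4 levels.")
  }
  filled <- purrr::map(parts, function(p) {
    p <- trimws(p)
    c(p, rep(p[length(p)], 4 - length(p)))
  })
  categories %>%
    mutate(level1 = purrr::map_chr(filled, 1),
           level2 = purrr::map_chr(filled, 2),
           level3 = purrr::map_chr(filled, 3),
           level4 = purrr::map_chr(filled, 4))
}

#' Tally regulation classes per functional category or regulon
#'
#' Counts ON, OFF, up-, down- and unregulated proteins per group and
#' strain. A protein assigned to several groups contributes to every one
#' of them; unannotated proteins are collected in an `unannotated`
#' group. Proteins classed in more than one fraction are deduplicated
#' within a group and strain (up/down/ON/OFF take precedence over
#' unchanged; a protein is counted once).
#'
#' @param classed A `regulation_classes` tibble from
#'   [classify_regulation()].
#' @param maps An [annotation_maps()] object.
#' @param by Group by `"category"` (at `level`) or `"regulon"`.
#' @param level Category hierarchy level (1-4) used when
#'   `by = "category"`.
#' @return A tibble with columns group, strain, n_up, n_down,
#'   n_unchanged, n_on, n_off, n_total and frac_significant (the share of
#'   the group's proteins that are up, down, ON or OFF).
#' @export
tally_regulation <- function(classed, maps, by = c("category", "regulon"),
                             level = 2) {
  by <- match.arg(by)
  stopifnot(inherits(maps, "annotation_maps"))
  if (by == "category") {
    stopifnot(level %in% 1:4)
    filled <- backfill_categories(maps$categories)
    groups <- filled %>%
      select("protein", group = all_of(paste0("level", level))) %>%
      distinct()
  } else {
    groups <- maps$regulons %>%
      select("protein", group = "regulon") %>%
      distinct()
  }
  # one class per (strain, protein, group); regulation beats unchanged
  rank <- c(up = 1, down = 1, ON = 1, OFF = 1, unchanged = 2)
  per_protein <- as_tibble(classed) %>%
    select("strain", "protein", "class") %>%
    mutate(.rank = rank[.data$class]) %>%
    group_by(.data$strain, .data$protein) %>%
    arrange(.data$.rank, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    ungroup() %>%
    select(-".rank")
  joined <- per_protein %>%
    left_join(groups, by = "protein",
              relationship = "many-to-many") %>%
    mutate(group = dplyr::coalesce(.data$group, "unannotated"))
  joined %>%
    group_by(.data$group, .data$strain) %>%
    summarise(n_up = sum(.data$class == "up"),
              n_down = sum(.data$class == "down"),
              n_unchanged = sum(.data$class == "unchanged"),
              n_on = sum(.data$class == "ON"),
              n_off = sum(.data$class == "OFF"),
              n_total = n(),
              .groups = "drop") %>%
    mutate(frac_significant =
             (.data$n_up + .data$n_down + .data$n_on + .data$n_off) /
             .data$n_total) %>%
    arrange(.data$group, .data$strain)
}

#' Core proteome and Venn region counts over four qualified sets
#'
#' Builds, per strain and condition, the set of proteins qualified in at
#' least one fraction, and returns all 15 non-empty-region counts of the
#' 4-set Venn diagram together with the core (proteins quantified in both
#' strains under both conditions).
#'
#' @param qs A `qualified_set` from [qualify_proteins()] covering two
#'   strains and two conditions.
#' @return A list with `sets` (named list of protein-id vectors),
#'   `regions` (tibble: membership pattern and exclusive count) and
#'   `core` (the number of proteins present in all four sets).
#' @export
core_proteome <- function(qs) {
  sets <- qs %>%
    filter(.data$qualified) %>%
    distinct(.data$strain, .data$condition, .data$protein) %>%
    mutate(set = paste(.data$strain, .data$condition, sep = ".")) %>%
    (function(d) split(d$protein, d$set))
  set_names <- names(sets)
  all_prot <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_prot %in% s,
                       logical(length(all_prot)))
  membership <- matrix(membership, nrow = length(all_prot),
                       dimnames = list(all_prot, set_names))
  pattern <- apply(membership, 1L, function(m) {
    paste(set_names[m], collapse = "&")
  })
  regions <- tibble(region = pattern) %>%
    count(.data$region, name = "count") %>%
    arrange(.data$region)
  core <- if (length(sets) > 0) sum(rowSums(membership) == ncol(membership)) else 0L
  list(sets = sets, regions = regions, core = as.integer(core))
}

#' Total number of altered proteins per strain
#'
#' Counts, per strain, the proteins that are ON, OFF or significantly up-
#' or downregulated in at least one fraction. A protein altered in
#' several fractions counts once (set `per_fraction = TRUE` to count per
#' fraction instead).
#'
#' @param classed A `regulation_classes` tibble.
#' @param per_fraction Count per (strain, fraction) instead of
#'   deduplicating across fractions.
#' @return A tibble with `strain` (and `fraction` if requested) and
#'   `n_altered`.
#' @export
total_altered <- function(classed, per_fraction = FALSE) {
  altered <- as_tibble(classed) %>%
    filter(.data$class %in% c("up", "down", "ON", "OFF"))
  if (per_fraction) {
    altered %>%
      distinct(.data$strain, .data$fraction, .data$protein) %>%
      count(.data$strain, .data$fraction, name = "n_altered")
  } else {
    altered %>%
      distinct(.data$strain, .data$protein) %>%
      count(.data$strain, name = "n_altered")
  }
}

#' Replicate-level PCA for quality control
#'
#' Principal-component analysis of the complete-case log2 intensity
#' matrix (proteins observed in every replicate of the selected block),
#' with samples as (condition, replicate) columns. Reports the
#' coordinates of each replicate on the first two components, a 95%
#' confidence ellipse per condition, and whether the condition groups
#' separate (between-centroid distance on PC1/PC2 exceeding the mean
#' within-group spread).
#'
#' @param quant A validated quantification tibble, typically filtered to
#'   one strain (and optionally one fraction).
#' @return A list of class `lfq_pca`: `scores` (tibble with sample,
#'   condition, replicate, PC1, PC2), `ellipses` (per-condition centre,
#'   axes and angle), `var_explained`, `n_proteins` and `separated`.
#' @export
pca_qc <- function(quant) {
  lq <- log2_transform(quant)
  wide <- lq %>%
    mutate(sample = paste(.data$condition, .data$replicate, sep = "_")) %>%
    select("protein", "sample", "log2_intensity") %>%
    tidyr::pivot_wider(names_from = "sample",
                       values_from = "log2_intensity",
                       values_fn = mean)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$protein
  if (ncol(m) < 3) stop_secretomics("PCA needs at least 3 replicates in total.")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop_secretomics("Too few complete-case proteins for PCA.")

  x <- t(m)                               # samples in rows
  sds <- apply(x, 2L, sd)
  if (all(sds < 1e-12)) {
    warn("All proteins have zero variance across replicates; PCA is degenerate.")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- tibble(sample = rownames(pc$x),
                   PC1 = pc$x[, 1],
                   PC2 = if (k >= 2) pc$x[, 2] else 0) %>%
    tidyr::separate_wider_delim("sample", "_", names = c("condition", "replicate"),
                                cols_remove = FALSE) %>%
    mutate(replicate = as.integer(.data$replicate))
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  ellipses <- scores %>%
    group_by(.data$condition) %>%
    summarise(n = n(),
              cx = mean(.data$PC1), cy = mean(.data$PC2),
              vxx = var(.data$PC1), vyy = var(.data$PC2),
              vxy = cov(.data$PC1, .data$PC2),
              .groups = "drop") %>%
    mutate(purrr::pmap_dfr(list(.data$vxx, .data$vyy, .data$vxy),
                           function(vxx, vyy, vxy) {
      if (any(is.na(c(vxx, vyy, vxy))) || (vxx + vyy) < 1e-12) {
        return(tibble(a = 0, b = 0, angle = 0, degenerate = TRUE))
      }
      ev <- eigen(matrix(c(vxx, vxy, vxy, vyy), 2), symmetric = TRUE)
      r <- sqrt(pmax(ev$values, 0) * qchisq(0.95, df = 2))
      tibble(a = r[1], b = r[2],
             angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
             degenerate = r[1] < 1e-12)
    }))
  if (any(ellipses$degenerate)) {
    warn("Degenerate (zero-variance) confidence ellipse in at least one condition.")
  }

  centred <- scores %>%
    group_by(.data$condition) %>%
    mutate(d = sqrt((.data$PC1 - mean(.data$PC1))^2 +
                      (.data$PC2 - mean(.data$PC2))^2)) %>%
    ungroup()
  within_spread <- mean(centred$d)
  cents <- ellipses %>% select("condition", "cx", "cy")
  between <- if (nrow(cents) >= 2) {
    sqrt(diff(cents$cx[1:2])^2 + diff(cents$cy[1:2])^2)
  } else 0
  structure(list(scores = scores, ellipses = ellipses,
                 var_explained = ve, n_proteins = nrow(m),
                 between_distance = between, within_spread = within_spread,
                 separated = between > within_spread),
            class = "lfq_pca")
}

#' Export a weighted, colored category tree for treemap rendering
#'
#' Builds the hierarchical weight/color structure consumed by Voronoi
#' treemap renderers: every protein is a leaf of weight 1 under its
#' four-level (backfilled) category path; inner-node weights are the sum
#' of their children. The leaf color value is the protein's log2
#' difference on a scale symmetric around 0, with sentinel color codes
#' for ON (`dark orange`), OFF (`dark turquoise`), gene-deleted and
#' unidentified proteins. The layout itself (power-diagram computation)
#' is left to the renderer.
#'
#' @param classed A `regulation_classes` tibble for one strain.
#' @param maps An [annotation_maps()] object.
#' @param deleted Optional character vector of proteins whose genes are
#'   absent from the strain's genome.
#' @param path Optional file; when given the tree is written as JSON.
#' @return The tree as nested lists (`name`, `weight`, `color`,
#'   `children`; leaves carry `sentinel`), invisibly if written.
#' @export
treemap_export <- function(classed, maps, deleted = character(), path = NULL) {
  stopifnot(inherits(maps, "annotation_maps"))
  filled <- backfill_categories(maps$categories)
  per_protein <- as_tibble(classed) %>%
    group_by(.data$protein) %>%
    summarise(class = .data$class[which.max(.data$class %in%
                                              c("up", "down", "ON", "OFF"))],
              difference = mean(.data$difference, na.rm = TRUE),
              .groups = "drop")
  leaves <- per_protein %>%
    left_join(filled, by = "protein", relationship = "many-to-many") %>%
    mutate(across(all_of(paste0("level", 1:4)),
                  ~ dplyr::coalesce(.x, "unannotated"))) %>%
    mutate(
      sentinel = case_when(
        .data$protein %in% deleted ~ "deleted",
        .data$class == "ON" ~ "ON",
        .data$class == "OFF" ~ "OFF",
        is.na(.data$difference) | is.nan(.data$difference) ~ "unidentified",
        TRUE ~ NA_character_),
      color = dplyr::if_else(is.na(.data$sentinel), .data$difference,
                             NA_real_))

  build <- function(df, depth) {
    if (depth > 4) {
      return(purrr::pmap(df, function(protein, color, sentinel, ...) {
        leaf <- list(name = protein, weight = 1)
        leaf$color <- if (is.na(sentinel)) color else NULL
        leaf$sentinel <- if (is.na(sentinel)) NULL else sentinel
        leaf
      }))
    }
    lvl <- paste0("level", depth)
    split(df, df[[lvl]]) %>%
      purrr::imap(function(d, nm) {
        children <- build(d, depth + 1)
        list(name = nm,
             weight = sum(purrr::map_dbl(children, "weight")),
             children = unname(children))
      }) %>% unname()
  }
  children <- build(leaves, 1)
  tree <- list(name = "proteome",
               weight = sum(purrr::map_dbl(children, "weight")),
               children = children,
               color_scale = list(midpoint = 0,
                                  limit = max(abs(leaves$color), 0,
                                              na.rm = TRUE),
                                  on = "dark orange", off = "dark turquoise",
                                  deleted = "light gray",
                                  unidentified = "light gray"))
  if (!is.null(path)) {
    jsonlite::write_json(tree, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(tree))
  }
  tree
}

#' Read back a treemap export
#'
#' @param path JSON file written by [treemap_export()].
#' @return The tree as nested lists.
#' @export
read_treemap <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
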