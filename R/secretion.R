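#' Proportion of extracellular protein secreted via the Sec pathway
#'
#' For each strain, within the extracellular fraction under the induced
#' condition, the summed linear LFQ intensity of qualified proteins
#' carrying a predicted Sec-type signal peptide is divided by the summed
#' intensity of all qualified proteins. The proportion is computed per
#' replicate and then averaged (mean and SD across replicates); a pooled
#' variant summing intensities over all replicates first is available.
#' When exactly two strains are present, a two-sided two-sample t test on
#' the replicate-level proportions is reported.
#'
#' @param quant A validated quantification tibble (linear intensities).
#' @param qs A `qualified_set` from [qualify_proteins()].
#' @param maps An [annotation_maps()] object (its `sec_sp` table is
#'   used; unlisted proteins count as signal-peptide-free).
#' @param fraction,condition Block to evaluate (defaults: extracellular,
#'   induced).
#' @param pooled Sum intensities over replicates before forming the
#'   proportion instead of averaging per-replicate proportions.
#' @return A list of class `sec_proportion`: `per_replicate` (tibble
#'   strain, replicate, p_sec in percent), `summary` (strain, mean_p_sec,
#'   sd_p_sec, n_sec_quantified, n_quantified) and `t_test` (htest or
#'   NULL).
#' @export
sec_proportion <- function(quant, qs, maps,
                           fraction = "extracellular",
                           condition = "induced",
                           pooled = FALSE) {
  stopifnot(inherits(maps, "annotation_maps"))
  qualified <- qs %>%
    filter(.data$fraction == !!fraction, .data$condition == !!condition,
           .data$qualified) %>%
    distinct(.data$strain, .data$protein)
  sp <- maps$sec_sp %>% filter(.data$sec_sp)
  rows <- quant %>%
    filter(.data$fraction == !!fraction, .data$condition == !!condition) %>%
    semi_join(qualified, by = c("strain", "protein")) %>%
    mutate(is_sp = .data$protein %in% sp$protein)
  if (nrow(rows) == 0 || sum(rows$intensity) <= 0) {
    stop_secretomics("No qualified intensity in the requested block.")
  }

  per_rep <- rows %>%
    group_by(.data$strain, .data$replicate) %>%
    summarise(p_sec = 100 * sum(.data$intensity[.data$is_sp]) /
                sum(.data$intensity),
              .groups = "drop")
  counts <- qualified %>%
    group_by(.data$strain) %>%
    summarise(n_quantified = n(),
              n_sec_quantified = sum(.data$protein %in% sp$protein),
              .groups = "drop")
  if (pooled) {
    summary <- rows %>%
      group_by(.data$strain) %>%
      summarise(mean_p_sec = 100 * sum(.data$intensity[.data$is_sp]) /
                  sum(.data$intensity),
                sd_p_sec = NA_real_, .groups = "drop")
  } else {
    summary <- per_rep %>%
      group_by(.data$strain) %>%
      summarise(mean_p_sec = mean(.data$p_sec),
                sd_p_sec = sd(.data$p_sec), .groups = "drop")
  }
  summary <- left_join(summary, counts, by = "strain")

  strains <- unique(per_rep$strain)
  t_res <- NULL
  if (!pooled && length(strains) == 2) {
    g1 <- per_rep$p_sec[per_rep$strain == strains[1]]
    g2 <- per_rep$p_sec[per_rep$strain == strains[2]]
    if (length(g1) >= 2 && length(g2) >= 2 &&
        (sd(g1) > 0 || sd(g2) > 0)) {
      t_res <- t.test(g1, g2, alternative = "two.sided")
    }
  }
  structure(list(per_replicate = per_rep, summary = summary,
                 t_test = t_res),
            class = "sec_proportion")
}

#' Secreted-protein regulation counts and between-strain ratio
#'
#' Counts, per strain, the proteins of a named functional category
#' (matched at any hierarchy level, case-insensitively) that are ON or
#' significantly upregulated upon induction, and reports the ratio
#' between the two strains.
#'
#' @param classed A `regulation_classes` tibble covering both strains.
#' @param maps An [annotation_maps()] object.
#' @param category Category name, default `"Secreted proteins"`.
#' @param numerator,denominator Strain labels for the reported ratio;
#'   defaults to the first and second strain in the table.
#' @return A list: `counts` (tibble strain, n_on_up) and `ratio`
#'   (numerator / denominator count; `NA` when the denominator is zero).
#' @export
secreted_regulation_ratio <- function(classed, maps,
                                      category = "Secreted proteins",
                                      numerator = NULL, denominator = NULL) {
  stopifnot(inherits(maps, "annotation_maps"))
  filled <- backfill_categories(maps$categories)
  hit <- filled %>%
    filter(tolower(.data$level1) == tolower(category) |
             tolower(.data$level2) == tolower(category) |
             tolower(.data$level3) == tolower(category) |
             tolower(.data$level4) == tolower(category)) %>%
    distinct(.data$protein)
  if (nrow(hit) == 0) {
    stop_secretomics(sprintf("Category '%s' is absent from the annotation map.",
                             category))
  }
  strains <- sort(unique(classed$strain))
  counts <- as_tibble(classed) %>%
    filter(.data$class %in% c("ON", "up"),
           .data$protein %in% hit$protein) %>%
    distinct(.data$strain, .data$protein) %>%
    count(.data$strain, name = "n_on_up") %>%
    tidyr::complete(strain = strains, fill = list(n_on_up = 0L))
  if (is.null(numerator)) numerator <- strains[1]
  if (is.null(denominator)) denominator <- strains[min(2, length(strains))]
  num <- counts$n_on_up[counts$strain == numerator]
  den <- counts$n_on_up[counts$strain == denominator]
  ratio <- if (length(num) == 1 && length(den) == 1 && den > 0) num / den
           else NA_real_
  list(counts = counts, ratio = ratio,
       numerator = numerator, denominator = denominator)
}

#' Signal-peptide mislocalization check
#'
#' Lists proteins with a predicted Sec-type signal peptide that qualify
#' in the cytosolic or membrane fraction under the induced condition
#' while remaining unqualified in the extracellular fraction --
#' candidates for stalled or mistargeted secretion.
#'
#' @param qs A `qualified_set` from [qualify_proteins()].
#' @param maps An [annotation_maps()] object.
#' @param condition Condition to inspect (default induced).
#' @return A tibble with columns strain, protein, fractions (the
#'   cell-associated fractions where the protein qualified).
#' @export
mislocalization_check <- function(qs, maps, condition = "induced") {
  stopifnot(inherits(maps, "annotation_maps"))
  sp <- maps$sec_sp %>% filter(.data$sec_sp)
  q <- qs %>% filter(.data$condition == !!condition, .data$qualified)
  cellular <- q %>%
    filter(.data$fraction %in% c("cytosolic", "membrane"),
           .data$protein %in% sp$protein)
  extra <- q %>% filter(.data$fraction == "extracellular")
  cellular %>%
    anti_join(extra, by = c("strain", "protein")) %>%
    group_by(.data$strain, .data$protein) %>%
    summarise(fractions = paste(sort(unique(.data$fraction)), collapse = ","),
              .groups = "drop") %>%
    arrange(.data$strain, .data$protein)
}
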