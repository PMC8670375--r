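#' Qualify proteins for quantification
#'
#' Applies the evidence filters used for compartment-resolved LFQ data:
#' a protein qualifies for quantification in a given strain, fraction and
#' condition if it carries at least `min_unique_peptides` unique peptides,
#' was detected in at least `min_replicates` of the biological replicates
#' of that condition, and its predicted subcellular localization is
#' compatible with the fraction. By default cytoplasmic proteins qualify
#' only in the cytosolic fraction, membrane proteins in the membrane
#' fraction and extracellular proteins in the growth-medium fraction;
#' cell-wall-associated and unknown-localization proteins are excluded
#' everywhere (no cell-wall enrichment is performed). The compatibility
#' map can be overridden.
#'
#' @param quant A validated long-format quantification tibble.
#' @param maps An [annotation_maps()] object (its `localization` table is
#'   used); proteins absent from the map are treated as `Unknown`.
#' @param min_unique_peptides Minimum unique peptides per protein.
#' @param min_replicates Minimum replicates with a detection, per
#'   condition.
#' @param localization_rules Compatibility tibble with columns
#'   `localization`, `fraction`; see [default_localization_rules()].
#' @param apply_localization Set `FALSE` to skip the localization filter.
#' @return A tibble of class `qualified_set`: one row per (strain,
#'   fraction, protein, condition) observed at least once, with columns
#'   `n_detected`, `unique_peptides`, `loc_compatible` and the logical
#'   `qualified`.
#' @export
#' @examples
#' sim <- simulate_quant_experiment(sim_config(n_proteins = 100, seed = 1))
#' qs <- qualify_proteins(sim$quant, sim$annotations)
#' dplyr::count(qs, strain, fraction, condition, qualified)
qualify_proteins <- function(quant, maps,
                             min_unique_peptides = 2,
                             min_replicates = 2,
                             localization_rules = default_localization_rules(),
                             apply_localization = TRUE) {
  stopifnot(inherits(maps, "annotation_maps"))
  loc <- maps$localization
  counts <- quant %>%
    group_by(.data$strain, .data$fraction, .data$protein, .data$condition) %>%
    summarise(n_detected = n_distinct(.data$replicate),
              unique_peptides = first(.data$unique_peptides),
              .groups = "drop") %>%
    left_join(loc, by = "protein") %>%
    mutate(localization = dplyr::coalesce(.data$localization, "Unknown"))

  if (apply_localization) {
    counts <- counts %>%
      left_join(mutate(localization_rules, .compatible = TRUE),
                by = c("localization", "fraction")) %>%
      mutate(loc_compatible = dplyr::coalesce(.data$.compatible, FALSE)) %>%
      select(-".compatible")
  } else {
    counts <- mutate(counts, loc_compatible = TRUE)
  }

  out <- counts %>%
    mutate(qualified = .data$loc_compatible &
             .data$n_detected >= min_replicates &
             (is.na(.data$unique_peptides) |
                .data$unique_peptides >= min_unique_peptides)) %>%
    arrange(.data$strain, .data$fraction, .data$protein, .data$condition)

  empty_frac <- out %>%
    group_by(.data$strain, .data$fraction) %>%
    summarise(any_q = any(.data$qualified), .groups = "drop") %>%
    filter(!.data$any_q)
  if (nrow(empty_frac) > 0) {
    warn(sprintf("No proteins qualified in %d (strain, fraction) block(s).",
                 nrow(empty_frac)))
  }
  class(out) <- c("qualified_set", class(out))
  out
}

#' Call presence (ON/OFF) per protein, strain and fraction
#'
#' A protein that qualifies for quantification exclusively in the induced
#' condition is called `ON`; one qualifying exclusively in the control
#' condition is called `OFF`; one qualifying in both conditions is
#' `both` (and enters the differential-abundance test); anything else
#' observed at least once is `neither`. By default "exclusively" means
#' the protein failed the qualification rule (e.g. 2-of-3 replicates) in
#' the other condition; with `strict_absence = TRUE` it must additionally
#' have zero detections there.
#'
#' @param qs A `qualified_set` from [qualify_proteins()].
#' @param strict_absence Require zero detections (not merely failed
#'   qualification) in the other condition for ON/OFF calls.
#' @return A tibble of class `presence_call` with one row per (strain,
#'   fraction, protein) and a `call` column in
#'   `c("ON", "OFF", "both", "neither")`.
#' @export
call_presence <- function(qs, strict_absence = FALSE) {
  wide <- qs %>%
    tidyr::pivot_wider(id_cols = c("strain", "fraction", "protein"),
                       names_from = "condition",
                       values_from = c("qualified", "n_detected"),
                       values_fill = list(qualified = FALSE, n_detected = 0L))
  for (col in c("qualified_control", "qualified_induced",
                "n_detected_control", "n_detected_induced")) {
    if (!col %in% names(wide)) {
      wide[[col]] <- if (grepl("qualified", col)) FALSE else 0L
    }
  }
  out <- wide %>%
    mutate(
      absent_control = if (strict_absence) .data$n_detected_control == 0L
                       else !.data$qualified_control,
      absent_induced = if (strict_absence) .data$n_detected_induced == 0L
                       else !.data$qualified_induced,
      call = case_when(
        .data$qualified_induced & !.data$qualified_control &
          .data$absent_control ~ "ON",
        .data$qualified_control & !.data$qualified_induced &
          .data$absent_induced ~ "OFF",
        .data$qualified_control & .data$qualified_induced ~ "both",
        TRUE ~ "neither")) %>%
    select("strain", "fraction", "protein", "call",
           "qualified_control", "qualified_induced",
           "n_detected_control", "n_detected_induced") %>%
    arrange(.data$strain, .data$fraction, .data$protein)
  class(out) <- c("presence_call", class(out))
  out
}
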