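#' Subtract control-well background fluorescence
#'
#' Background GFP fluorescence is estimated, per time point, as the mean
#' GFP reading over the designated control wells (strains without the
#' reporter module) and subtracted from every reporter well. Background
#' grows with biomass, so a per-time-point estimate is used rather than a
#' single scalar.
#'
#' @param plate A plate-series tibble with columns well, role
#'   (`reporter`/`control`), strain, time_min, od600, gfp.
#' @return The reporter wells with `gfp` replaced by the
#'   background-corrected signal (original readings kept as `gfp_raw`).
#' @export
subtract_background <- function(plate) {
  plate <- as_tibble(plate)
  controls <- plate %>% filter(.data$role == "control")
  reporters <- plate %>% filter(.data$role == "reporter")
  if (nrow(controls) == 0) {
    stop_secretomics("No control wells designated; cannot estimate background.")
  }
  bg <- controls %>%
    group_by(.data$time_min) %>%
    summarise(background = mean(.data$gfp), .groups = "drop")
  rep_times <- sort(unique(reporters$time_min))
  if (!setequal(rep_times, bg$time_min)) {
    stop_secretomics("Control and reporter wells are on different time grids.")
  }
  reporters %>%
    left_join(bg, by = "time_min") %>%
    mutate(gfp_raw = .data$gfp,
           gfp = .data$gfp - .data$background) %>%
    arrange(.data$well, .data$time_min)
}

#' Compute transcriptional activity units (TAU)
#'
#' Promoter activity per time point from a background-corrected plate
#' series: `TAU_t = (GFP_t - GFP_(t-1)) / OD600_t` for every time point
#' after the first; TAU at the first time point is undefined and absent.
#' Adding a time-constant offset to GFP leaves TAU unchanged (the
#' difference telescopes), and negative values are legitimate (noise,
#' bleaching) and are not clipped.
#'
#' @param corrected A background-corrected reporter series from
#'   [subtract_background()] (or any tibble with well, strain, time_min,
#'   od600, gfp on a uniform time grid).
#' @return A tibble of class `tau_series`: well, strain, time_min, od600,
#'   gfp, tau.
#' @export
compute_tau <- function(corrected) {
  corrected <- as_tibble(corrected) %>%
    arrange(.data$well, .data$time_min)
  spacing <- corrected %>%
    group_by(.data$well) %>%
    summarise(u = length(unique(round(diff(.data$time_min), 9))),
              n = n(), .groups = "drop")
  if (any(spacing$n < 2)) {
    stop_secretomics("Each well needs at least two time points.")
  }
  if (any(spacing$u > 1)) {
    stop_secretomics("Time points must be uniformly spaced.")
  }
  out <- corrected %>%
    group_by(.data$well) %>%
    mutate(tau = (.data$gfp - dplyr::lag(.data$gfp)) / .data$od600) %>%
    ungroup() %>%
    filter(!is.na(.data$tau))
  bad_od <- out %>% filter(.data$od600 <= 0)
  if (nrow(bad_od) > 0) {
    stop_secretomics(sprintf(
      "OD600 <= 0 at %d time point(s) where TAU is needed.", nrow(bad_od)))
  }
  out <- out %>%
    select(any_of(c("well", "role", "strain")), "time_min", "od600",
           "gfp", "tau")
  class(out) <- c("tau_series", class(out))
  out
}

#' Summarize TAU profiles per strain
#'
#' Aggregates replicate wells into a time-resolved mean and SD TAU
#' profile per strain, an area-under-the-TAU-curve (trapezoidal, in
#' TAU x min) summary, and a ranking of strains by that summary.
#'
#' @param tau A `tau_series` from [compute_tau()].
#' @return A list of class `tau_summary`: `profile` (strain, time_min,
#'   mean_tau, sd_tau, n_wells), `auc` (strain, auc, rank) and
#'   `comparison` (pairwise differences in AUC).
#' @export
summarize_tau <- function(tau) {
  profile <- tau %>%
    group_by(.data$strain, .data$time_min) %>%
    summarise(mean_tau = mean(.data$tau), sd_tau = sd(.data$tau),
              n_wells = n(), .groups = "drop") %>%
    mutate(sd_tau = dplyr::coalesce(.data$sd_tau, 0))
  trapz <- function(t, y) sum(diff(t) * (head(y, -1) + y[-1]) / 2)
  auc <- tau %>%
    group_by(.data$strain, .data$well) %>%
    summarise(auc = trapz(.data$time_min, .data$tau), .groups = "drop") %>%
    group_by(.data$strain) %>%
    summarise(auc = mean(.data$auc), .groups = "drop") %>%
    arrange(dplyr::desc(.data$auc)) %>%
    mutate(rank = row_number())
  comparison <- if (nrow(auc) >= 2) {
    pairs <- combn(auc$strain, 2, simplify = FALSE)
    bind_rows(purrr::map(pairs, function(p) {
      tibble(strain_a = p[1], strain_b = p[2],
             auc_diff = auc$auc[auc$strain == p[1]] -
               auc$auc[auc$strain == p[2]])
    }))
  } else tibble(strain_a = character(), strain_b = character(),
                auc_diff = double())
  structure(list(profile = profile, auc = auc, comparison = comparison),
            class = "tau_summary")
}
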