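#' Configuration for the synthetic LFQ experiment generator
#'
#' Bundles all parameters of [simulate_quant_experiment()]. Defaults emulate
#' a two-strain subtilin-induction proteome experiment: two strains, two
#' conditions (control / induced), three subproteome fractions and three
#' biological replicates, with log-normal LFQ intensities and
#' intensity-dependent (missing-not-at-random) detection.
#'
#' @param n_proteins Number of simulated proteins.
#' @param strains Character vector of strain labels.
#' @param fractions Subproteome fraction names.
#' @param n_replicates Biological replicates per strain and condition
#'   (at least 2).
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of the per-protein
#'   baseline log2 LFQ intensity (arbitrary units; MaxQuant-style LFQ
#'   intensities typically sit around 22--32 on the log2 scale).
#' @param noise_log2_sd Replicate-to-replicate SD on the log2 scale.
#' @param effect_log2 Absolute log2 shift applied in the induced condition
#'   to truly up-/down-regulated proteins.
#' @param frac_up,frac_down,frac_on,frac_off Proportions of proteins that
#'   are truly upregulated, downregulated, switched ON (detectable only
#'   when induced) or switched OFF. Must sum to at most 1.
#' @param detect_midpoint,detect_slope Logistic detection model: a
#'   measurement with log2 intensity `x` is observed with probability
#'   `plogis(detect_slope * (x - detect_midpoint))`. `detect_slope` must be
#'   positive; set `detect_midpoint = -Inf` to force complete detection.
#' @param unique_peptide_range Integer range (length 2) from which the
#'   per-protein unique-peptide count is drawn once per protein.
#' @param loc_probs Named probabilities over the five localization classes
#'   `Cytoplasmic`, `CytoplasmicMembrane`, `Extracellular`, `Cellwall`,
#'   `Unknown`.
#' @param seed Integer RNG seed; the same seed reproduces the dataset
#'   exactly.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 50, seed = 1)
#' sim <- simulate_quant_experiment(cfg)
#' sim$quant
sim_config <- function(n_proteins = 1000,
                       strains = c("168", "midi"),
                       fractions = c("cytosolic", "membrane", "extracellular"),
                       n_replicates = 3,
                       baseline_log2_mean = 25,
                       baseline_log2_sd = 2,
                       noise_log2_sd = 0.5,
                       effect_log2 = 2,
                       frac_up = 0.05,
                       frac_down = 0.05,
                       frac_on = 0.03,
                       frac_off = 0.03,
                       detect_midpoint = 20,
                       detect_slope = 1,
                       unique_peptide_range = c(1L, 25L),
                       loc_probs = c(Cytoplasmic = 0.58,
                                     CytoplasmicMembrane = 0.24,
                                     Extracellular = 0.12,
                                     Cellwall = 0.03,
                                     Unknown = 0.03),
                       seed = NULL) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1 || n_proteins < 1) {
    stop_secretomics("`n_proteins` must be a positive count.",
                     class = "secretomics_config_error")
  }
  if (n_replicates < 2) {
    stop_secretomics("`n_replicates` must be at least 2.",
                     class = "secretomics_config_error")
  }
  fracs <- c(frac_up, frac_down, frac_on, frac_off)
  if (any(fracs < 0) || sum(fracs) > 1) {
    stop_secretomics(
      "Class proportions must be non-negative and sum to at most 1.",
      class = "secretomics_config_error")
  }
  if (detect_slope <= 0) {
    stop_secretomics("`detect_slope` must be positive.",
                     class = "secretomics_config_error")
  }
  if (length(unique_peptide_range) != 2 ||
      unique_peptide_range[1] > unique_peptide_range[2] ||
      unique_peptide_range[1] < 0) {
    stop_secretomics("`unique_peptide_range` must be a non-decreasing pair.",
                     class = "secretomics_config_error")
  }
  if (!setequal(names(loc_probs), .loc_classes) ||
      any(loc_probs < 0) || abs(sum(loc_probs) - 1) > 1e-8) {
    stop_secretomics(
      "`loc_probs` must be a probability vector over the five localization classes.",
      class = "secretomics_config_error")
  }
  structure(
    list(n_proteins = as.integer(n_proteins), strains = strains,
         fractions = fractions, n_replicates = as.integer(n_replicates),
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         noise_log2_sd = noise_log2_sd, effect_log2 = effect_log2,
         frac_up = frac_up, frac_down = frac_down,
         frac_on = frac_on, frac_off = frac_off,
         detect_midpoint = detect_midpoint, detect_slope = detect_slope,
         unique_peptide_range = as.integer(unique_peptide_range),
         loc_probs = loc_probs[.loc_classes], seed = seed),
    class = "sim_config")
}

# small invented four-level functional hierarchy, SubtiWiki-flavoured;
# the level-3 node "Secreted proteins" is reserved for extracellular proteins
.category_paths <- c(
  "Metabolism/Carbon metabolism/Glycolysis/Glycolytic enzymes",
  "Metabolism/Amino acid metabolism/Biosynthesis/Branched-chain amino acids",
  "Metabolism/Nucleotide metabolism/Purine biosynthesis/Pur operon",
  "Metabolism/Nucleotide metabolism/Pyrimidine biosynthesis/Pyr operon",
  "Protein synthesis and modification/Translation/Ribosomal proteins/Large subunit",
  "Protein synthesis and modification/Translation/Ribosomal proteins/Small subunit",
  "Protein synthesis and modification/Protein secretion/Sec machinery/Translocase",
  "Cellular processes/Cell envelope/Cell wall synthesis/Peptidoglycan synthesis",
  "Cellular processes/Transporters/ABC transporters/Importers",
  "Coping with stress/General stress response/SigB dependent/General stress proteins",
  "Coping with stress/Oxidative stress/Peroxide stress/PerR dependent",
  "Information processing/Regulation of gene expression/Transcription factors/Two-component systems"
)
.secreted_path <- "Lifestyles/Exponential growth/Secreted proteins/Degradative enzymes"

.regulon_pool <- tibble::tibble(
  regulon = c("SigB", "Spx", "Stringent response", "PyrR", "PurR",
              "SigW", "CssRS", "TnrA"),
  mode = c("activation", "activation", "other", "repression", "repression",
           "activation", "activation", "other")
)

#' Simulate a compartment-resolved LFQ proteome experiment
#'
#' Draws per-protein baseline log2 intensities from a normal distribution
#' (log-normal on the linear scale), applies condition effects as log2
#' shifts for regulated proteins, and observes each (strain, condition,
#' fraction, replicate) measurement independently with a logistic
#' detection probability in its log2 intensity. ON proteins have detection
#' probability forced to zero in the control condition, OFF proteins in the
#' induced condition, reproducing the presence/absence patterns seen in
#' real LFQ data. Undetected measurements are absent rows, not zeros.
#'
#' Each protein lives in the single fraction matching its localization
#' class (cell-wall and unknown-localization proteins are placed in a
#' random fraction, where the localization filter is expected to remove
#' them). Unique-peptide counts are drawn once per protein.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `lfq_sim` with elements
#'   \describe{
#'     \item{quant}{long-format measurement tibble (protein, strain,
#'       condition, fraction, replicate, intensity, unique_peptides)}
#'     \item{annotations}{an [annotation_maps()] list (localization,
#'       sec_sp, categories, regulons)}
#'     \item{truth}{per-protein ground truth: true class, localization,
#'       Sec signal-peptide flag, home fraction, baseline log2 intensity,
#'       unique peptides}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulate_quant_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_proteins

  protein <- sprintf("P%04d", seq_len(n))
  n_up  <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  n_on  <- round(config$frac_on * n)
  n_off <- round(config$frac_off * n)
  class <- rep("unchanged", n)
  idx <- sample.int(n)          # random positions for regulated proteins
  take <- function(k, used) idx[seq.int(used + 1, length.out = k)]
  class[take(n_up, 0)] <- "up"
  class[take(n_down, n_up)] <- "down"
  class[take(n_on, n_up + n_down)] <- "ON"
  class[take(n_off, n_up + n_down + n_on)] <- "OFF"

  localization <- sample(.loc_classes, n, replace = TRUE,
                         prob = config$loc_probs)
  sec_sp <- runif(n) < ifelse(localization == "Extracellular", 0.8, 0.05)
  home <- dplyr::case_match(localization,
    "Cytoplasmic" ~ "cytosolic",
    "CytoplasmicMembrane" ~ "membrane",
    "Extracellular" ~ "extracellular",
    .default = NA_character_)
  home[is.na(home)] <- sample(config$fractions, sum(is.na(home)),
                              replace = TRUE)

  upr <- config$unique_peptide_range
  unique_peptides <- sample(seq.int(upr[1], upr[2]), n, replace = TRUE)
  base_log2 <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  truth <- tibble(
    protein = protein, class = class, localization = localization,
    sec_sp = sec_sp, home_fraction = home,
    base_log2 = base_log2, unique_peptides = unique_peptides)

  # expand the full design for each protein's home fraction
  design <- tidyr::expand_grid(
    protein = protein,
    strain = config$strains,
    condition = .conditions,
    replicate = seq_len(config$n_replicates))
  cells <- design %>%
    left_join(truth, by = "protein") %>%
    mutate(
      fraction = .data$home_fraction,
      shift = dplyr::case_when(
        .data$class == "up"   & .data$condition == "induced" ~ config$effect_log2,
        .data$class == "down" & .data$condition == "induced" ~ -config$effect_log2,
        TRUE ~ 0),
      log2_value = .data$base_log2 + .data$shift +
        rnorm(dplyr::n(), 0, config$noise_log2_sd),
      p_detect = plogis(config$detect_slope *
                          (.data$log2_value - config$detect_midpoint)),
      p_detect = dplyr::case_when(
        .data$class == "ON"  & .data$condition == "control" ~ 0,
        .data$class == "OFF" & .data$condition == "induced" ~ 0,
        TRUE ~ .data$p_detect),
      detected = runif(dplyr::n()) < .data$p_detect)

  quant <- cells %>%
    filter(.data$detected) %>%
    mutate(intensity = 2^.data$log2_value) %>%
    select("protein", "strain", "condition", "fraction", "replicate",
           "intensity", "unique_peptides") %>%
    arrange(.data$protein, .data$strain, .data$condition,
            .data$fraction, .data$replicate)

  annotations <- annotation_maps(
    localization = truth %>% select("protein", "localization"),
    sec_sp = truth %>% select("protein", "sec_sp"),
    categories = .simulate_categories(truth),
    regulons = .simulate_regulons(truth))

  structure(list(quant = quant, annotations = annotations,
                 truth = truth, config = config),
            class = "lfq_sim")
}

# assign 1-2 category paths per protein; extracellular proteins carry the
# "Secreted proteins" branch; paths are randomly truncated to exercise
# level backfilling; ~5% of proteins stay unannotated
.simulate_categories <- function(truth) {
  n <- nrow(truth)
  annotated <- runif(n) > 0.05
  rows <- purrr::map(which(annotated), function(i) {
    paths <- sample(.category_paths, 1 + (runif(1) < 0.25))
    if (truth$localization[i] == "Extracellular") {
      paths <- unique(c(.secreted_path, paths[-1]))
    }
    depth <- sample.int(4, length(paths), replace = TRUE, prob = c(.05, .15, .2, .6))
    paths <- purrr::map2_chr(paths, depth, function(p, d) {
      paste(head(strsplit(p, "/", fixed = TRUE)[[1]], d), collapse = "/")
    })
    tibble(protein = truth$protein[i], path = paths)
  })
  bind_rows(rows)
}

# 0-2 regulons per protein with the pool's regulation mode
.simulate_regulons <- function(truth) {
  n <- nrow(truth)
  k <- sample(0:2, n, replace = TRUE, prob = c(0.35, 0.45, 0.2))
  rows <- purrr::map(which(k > 0), function(i) {
    picked <- .regulon_pool[sample.int(nrow(.regulon_pool), k[i]), ]
    tibble(protein = truth$protein[i],
           regulon = picked$regulon, mode = picked$mode)
  })
  bind_rows(rows)
}

#' Simulate a live-cell-array plate-reader run
#'
#' Generates OD600 and GFP time series for reporter wells (each strain at
#' a configurable promoter activity) and control wells that carry only
#' background fluorescence. Growth is logistic; the reporter GFP signal
#' accumulates by `activity * OD600(t)` per time step on top of a shared
#' background `background_base + background_per_od * OD600(t)`, so that
#' after background subtraction the TAU statistic
#' `(GFP_t - GFP_(t-1)) / OD600_t` recovers the injected activity exactly
#' in the noiseless case.
#'
#' @param strain_activities Named numeric vector: promoter activity
#'   (arbitrary TAU units) per reporter strain.
#' @param wells_per_strain Reporter wells per strain.
#' @param n_control_wells Background-only control wells.
#' @param duration_min,interval_min Run length and sampling interval in
#'   minutes (default 12 h at 10-min spacing, i.e. 73 time points).
#' @param od0,od_max,growth_rate,t_mid Logistic growth parameters:
#'   `OD600(t) = od0 + od_max / (1 + exp(-growth_rate * (t - t_mid)))`.
#' @param background_base,background_per_od Background fluorescence model.
#' @param gfp_noise_sd Additive Gaussian noise on each GFP reading.
#' @param seed Integer RNG seed.
#' @return A tibble of class `plate_series` with columns well, role
#'   (`reporter`/`control`), strain, time_min, od600, gfp.
#' @export
simulate_plate_series <- function(strain_activities = c("168" = 100, "midi" = 10),
                                  wells_per_strain = 3,
                                  n_control_wells = 3,
                                  duration_min = 720,
                                  interval_min = 10,
                                  od0 = 0.05, od_max = 1.2,
                                  growth_rate = 0.02, t_mid = 240,
                                  background_base = 50,
                                  background_per_od = 100,
                                  gfp_noise_sd = 0,
                                  seed = NULL) {
  times <- seq(0, duration_min, by = interval_min)
  if (length(times) < 2) {
    stop_secretomics("A plate series needs at least two time points.",
                     class = "secretomics_config_error")
  }
  if (n_control_wells < 1) {
    stop_secretomics("At least one control well is required.",
                     class = "secretomics_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  od <- od0 + od_max / (1 + exp(-growth_rate * (times - t_mid)))
  background <- background_base + background_per_od * od

  one_well <- function(well, role, strain, activity) {
    signal <- if (role == "reporter") cumsum(c(0, activity * od[-1])) else 0
    tibble(well = well, role = role, strain = strain, time_min = times,
           od600 = od,
           gfp = signal + background + rnorm(length(times), 0, gfp_noise_sd))
  }

  reporters <- purrr::imap(strain_activities, function(a, s) {
    purrr::map(seq_len(wells_per_strain), function(w) {
      one_well(sprintf("%s_R%d", s, w), "reporter", s, a)
    })
  })
  controls <- purrr::map(seq_len(n_control_wells), function(w) {
    one_well(sprintf("CTRL_%d", w), "control", "control", 0)
  })
  out <- bind_rows(c(unname(purrr::flatten(reporters)), controls))
  class(out) <- c("plate_series", class(out))
  out
}
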