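#' Log2-transform a quantification table
#'
#' Adds a `log2_intensity` column. Intensities must be linear and
#' positive; missing measurements remain absent rows.
#'
#' @param quant A validated quantification tibble.
#' @return The tibble with an added `log2_intensity` column.
#' @export
log2_transform <- function(quant) {
  if ("log2_intensity" %in% names(quant)) {
    inform("Table already carries `log2_intensity`; leaving it unchanged.")
    return(quant)
  }
  if (any(quant$intensity <= 0)) {
    stop_secretomics("Cannot log-transform non-positive intensities.")
  }
  mutate(quant, log2_intensity = log2(.data$intensity))
}

#' S0-moderated two-sample statistic
#'
#' The classical two-sample t statistic with a constant `s0` added to the
#' standard-error denominator, damping the significance of proteins with
#' tiny variance and tiny effect:
#' `t_s0 = (mean(a) - mean(b)) / (se + s0)`, where `se` is the pooled
#' (default) or Welch standard error of the mean difference. With
#' `s0 = 0` this is exactly the classical t statistic; it is
#' antisymmetric under swapping the groups and shrinks monotonically to 0
#' as `s0` grows.
#'
#' @param a,b Numeric vectors of log2 intensities (each of length >= 2).
#' @param s0 Non-negative moderation constant (default 0.1).
#' @param var_equal Use the pooled-variance standard error (default);
#'   `FALSE` uses the Welch form.
#' @return The moderated statistic (a single number).
#' @export
#' @examples
#' s0_tstat(c(5, 6, 7), c(3, 3.5, 4), s0 = 0.1)
s0_tstat <- function(a, b, s0 = 0.1, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_secretomics("Each group needs at least 2 values.")
  }
  if (s0 < 0) stop_secretomics("`s0` must be non-negative.")
  na <- length(a); nb <- length(b)
  if (var_equal) {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(var(a) / na + var(b) / nb)
  }
  (mean(a) - mean(b)) / (se + s0)
}

# vectorized moderated statistic over the rows of a matrix.
# `induced` flags the columns of the induced group; returns a list with
# difference (induced - control), t (with s0), se, and group sizes.
.row_tstats <- function(mat, induced, s0, var_equal = TRUE) {
  gi <- mat[, induced, drop = FALSE]
  gc <- mat[, !induced, drop = FALSE]
  ni <- rowSums(!is.na(gi)); nc <- rowSums(!is.na(gc))
  mi <- rowMeans(gi, na.rm = TRUE); mc <- rowMeans(gc, na.rm = TRUE)
  vi <- apply(gi, 1L, var, na.rm = TRUE)
  vc <- apply(gc, 1L, var, na.rm = TRUE)
  ok <- ni >= 2 & nc >= 2
  se <- rep(NA_real_, nrow(mat))
  if (var_equal) {
    sp2 <- ((ni - 1) * vi + (nc - 1) * vc) / (ni + nc - 2)
    se[ok] <- sqrt(sp2[ok] * (1 / ni[ok] + 1 / nc[ok]))
  } else {
    se[ok] <- sqrt(vi[ok] / ni[ok] + vc[ok] / nc[ok])
  }
  diff <- mi - mc
  diff[!ok] <- NA_real_
  list(difference = unname(diff), t = unname(diff / (se + s0)),
       se = unname(se), n_induced = unname(ni), n_control = unname(nc))
}

# counts #{sorted_vals >= x} for each x, robust to ties
.count_ge <- function(x, sorted_vals) {
  length(sorted_vals) - findInterval(x, sorted_vals, left.open = TRUE)
}

# SAM-style permutation FDR on one (strain, fraction) block.
# mat: proteins x columns of log2 values; induced: logical per column.
.permutation_fdr_block <- function(mat, induced, s0, n_randomizations,
                                   fdr, var_equal = TRUE) {
  obs <- .row_tstats(mat, induced, s0, var_equal)
  n_ind <- sum(induced)
  n_col <- length(induced)

  n_distinct_assign <- choose(n_col, n_ind)
  if (n_distinct_assign <= n_randomizations) {
    assignments <- combn(n_col, n_ind, simplify = FALSE)  # exhaustive
  } else {
    assignments <- replicate(n_randomizations,
                             sample.int(n_col, n_ind), simplify = FALSE)
  }
  # the observed labeling (and, by antisymmetry of the statistic, its
  # group-swap mirror) is not a draw from the null and is excluded from
  # the null ensemble
  observed_set <- sort(which(induced))
  mirror_set <- sort(which(!induced))
  is_null_draw <- vapply(assignments, function(cols) {
    s <- sort(cols)
    !identical(s, observed_set) &&
      !(length(s) == length(mirror_set) && identical(s, mirror_set))
  }, logical(1))
  assignments <- assignments[is_null_draw]
  if (length(assignments) == 0) {
    stop_secretomics("No non-identity label assignments available.")
  }
  n_perm <- length(assignments)
  perm_abs <- unlist(lapply(assignments, function(cols) {
    lab <- rep(FALSE, n_col); lab[cols] <- TRUE
    abs(.row_tstats(mat, lab, s0, var_equal)$t)
  }), use.names = FALSE)
  perm_abs <- perm_abs[!is.na(perm_abs)]

  abs_t <- abs(obs$t)
  tested <- !is.na(abs_t)
  sorted_perm <- sort(perm_abs)

  # pooled empirical p with add-one smoothing
  p <- rep(NA_real_, length(abs_t))
  p[tested] <- (1 + .count_ge(abs_t[tested], sorted_perm)) /
    (1 + length(sorted_perm))

  # estimated FDR at each candidate threshold c (the observed |t| values):
  # mean permuted exceedance count over observed exceedance count
  sorted_obs <- sort(abs_t[tested])
  cand <- sort(unique(abs_t[tested]))
  obs_count <- .count_ge(cand, sorted_obs)
  perm_mean <- .count_ge(cand, sorted_perm) / n_perm
  fdr_at <- pmin(1, perm_mean / obs_count)
  # q for a protein = smallest estimated FDR over the thresholds it
  # exceeds (ascending cummin makes q non-increasing in |t|)
  q_at <- cummin(fdr_at)
  q <- rep(NA_real_, length(abs_t))
  q[tested] <- q_at[match(abs_t[tested], cand)]

  list(difference = obs$difference, t = obs$t, p = p, q = q,
       significant = !is.na(q) & q <= fdr,
       n_induced = obs$n_induced, n_control = obs$n_control,
       n_randomizations_used = n_perm,
       exhaustive = n_distinct_assign <= n_randomizations)
}

#' Differential protein abundance with S0 moderation and permutation FDR
#'
#' For every protein qualifying in both conditions of a (strain,
#' fraction) block, computes the mean log2 difference (induced minus
#' control, over detected replicates), the S0-moderated statistic, a
#' nominal p-value and an FDR-adjusted q-value, and flags significance at
#' the requested FDR.
#'
#' The default method is the SAM-style permutation procedure: condition
#' labels of the replicate columns are permuted within each (strain,
#' fraction) block and all moderated statistics recomputed per
#' randomization; the estimated FDR at threshold `c` is the mean permuted
#' count of `|t| >= c` divided by the observed count, and a protein's q
#' is the smallest estimated FDR over thresholds it exceeds. When the
#' number of distinct label assignments does not exceed
#' `n_randomizations` (e.g. 20 for a 3-vs-3 design), all assignments are
#' enumerated exhaustively instead of sampled. Nominal p-values are
#' empirical, pooled over the block's permutation null with add-one
#' smoothing. With `method = "bh"` a classical two-sample t-test with a
#' Student-t reference is used per protein and q-values come from the
#' Benjamini-Hochberg adjustment.
#'
#' @param quant A validated quantification tibble (linear intensities).
#' @param presence A `presence_call` from [call_presence()]; only
#'   proteins called `both` are tested.
#' @param s0 Moderation constant (default 0.1).
#' @param n_randomizations Number of label randomizations (default 250).
#' @param fdr Target false-discovery rate (default 0.05).
#' @param seed Integer seed for the randomizations.
#' @param method `"permutation"` (default) or `"bh"`.
#' @param var_equal Pooled (default) vs Welch standard error.
#' @return A tibble of class `diff_abund` with columns strain, fraction,
#'   protein, n_control, n_induced, difference, t_s0, p, neglog10_p, q,
#'   significant, plus a `settings` attribute.
#' @export
diff_abundance <- function(quant, presence,
                           s0 = 0.1, n_randomizations = 250, fdr = 0.05,
                           seed = NULL,
                           method = c("permutation", "bh"),
                           var_equal = TRUE) {
  method <- match.arg(method)
  if (n_randomizations < 1) {
    stop_secretomics("`n_randomizations` must be at least 1.",
                     class = "secretomics_config_error")
  }
  if (!(fdr > 0 && fdr < 1)) {
    stop_secretomics("`fdr` must lie in (0, 1).",
                     class = "secretomics_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  lq <- log2_transform(quant)
  both <- presence %>% filter(.data$call == "both")

  blocks <- both %>% distinct(.data$strain, .data$fraction) %>%
    arrange(.data$strain, .data$fraction)
  res <- purrr::pmap(blocks, function(strain, fraction) {
    prots <- both$protein[both$strain == strain & both$fraction == fraction]
    sub <- lq %>%
      filter(.data$strain == !!strain, .data$fraction == !!fraction,
             .data$protein %in% prots)
    reps <- sort(unique(sub$replicate))
    cols <- tidyr::expand_grid(condition = .conditions, replicate = reps)
    mat <- matrix(NA_real_, nrow = length(prots), ncol = nrow(cols),
                  dimnames = list(prots, NULL))
    ridx <- match(sub$protein, prots)
    cidx <- match(paste(sub$condition, sub$replicate),
                  paste(cols$condition, cols$replicate))
    mat[cbind(ridx, cidx)] <- sub$log2_intensity
    induced <- cols$condition == "induced"

    if (length(prots) == 0) return(NULL)
    vals <- mat[!is.na(mat)]
    if (length(vals) > 0 && diff(range(vals)) < 1e-12) {
      warn(sprintf("All intensities constant in block (%s, %s); no significance assessed.",
                   strain, fraction))
    }
    if (method == "permutation") {
      bl <- .permutation_fdr_block(mat, induced, s0, n_randomizations,
                                   fdr, var_equal)
      tibble(strain = strain, fraction = fraction, protein = prots,
             n_control = bl$n_control, n_induced = bl$n_induced,
             difference = bl$difference, t_s0 = bl$t,
             p = bl$p, q = bl$q, significant = bl$significant)
    } else {
      obs0 <- .row_tstats(mat, induced, 0, var_equal)      # classical t
      obs_s0 <- .row_tstats(mat, induced, s0, var_equal)
      df <- obs0$n_induced + obs0$n_control - 2
      p <- 2 * pt(-abs(obs0$t), df)
      q <- p.adjust(p, method = "BH")
      tibble(strain = strain, fraction = fraction, protein = prots,
             n_control = obs0$n_control, n_induced = obs0$n_induced,
             difference = obs0$difference, t_s0 = obs_s0$t,
             p = p, q = q, significant = !is.na(q) & q <= fdr)
    }
  })
  empty <- tibble(strain = character(), fraction = character(),
                  protein = character(), n_control = integer(),
                  n_induced = integer(), difference = double(),
                  t_s0 = double(), p = double(), q = double(),
                  significant = logical())
  out <- bind_rows(c(list(empty), res)) %>%
    mutate(neglog10_p = -log10(.data$p)) %>%
    select("strain", "fraction", "protein", "n_control", "n_induced",
           "difference", "t_s0", "p", "neglog10_p", "q", "significant")
  attr(out, "settings") <- list(s0 = s0, n_randomizations = n_randomizations,
                                fdr = fdr, method = method,
                                var_equal = var_equal, seed = seed)
  class(out) <- c("diff_abund", class(out))
  out
}

#' Assign regulation classes
#'
#' Merges differential-abundance results with presence calls into the
#' final per-protein regulation class: `ON` and `OFF` are taken from the
#' presence call; proteins quantified in both conditions become `up` if
#' significant with a positive log2 difference, `down` if significant
#' with a negative difference, and `unchanged` otherwise.
#'
#' @param diff A `diff_abund` tibble.
#' @param presence A `presence_call` tibble on the same qualified
#'   universe.
#' @return A tibble of class `regulation_classes` with one row per
#'   (strain, fraction, protein) called ON, OFF or both, carrying the
#'   statistics columns (NA for ON/OFF proteins) and `class`.
#' @export
classify_regulation <- function(diff, presence) {
  onoff <- presence %>%
    filter(.data$call %in% c("ON", "OFF")) %>%
    select("strain", "fraction", "protein", class = "call")
  dup <- diff %>%
    count(.data$strain, .data$fraction, .data$protein) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_secretomics("Duplicate (strain, fraction, protein) keys in `diff`.")
  }
  conflict <- semi_join(onoff, diff,
                        by = c("strain", "fraction", "protein"))
  if (nrow(conflict) > 0) {
    stop_secretomics(
      "Proteins appear both in the differential table and as ON/OFF calls.")
  }
  tested <- as_tibble(diff) %>%
    mutate(class = case_when(
      .data$significant & .data$difference > 0 ~ "up",
      .data$significant & .data$difference < 0 ~ "down",
      TRUE ~ "unchanged"))
  out <- bind_rows(tested, onoff) %>%
    arrange(.data$strain, .data$fraction, .data$protein)
  class(out) <- c("regulation_classes", class(out))
  out
}
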