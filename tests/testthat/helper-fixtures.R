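# shared fixture builders for the test suite (all generated in code)

# long-format quant tibble from named per-condition replicate values for a
# single strain/fraction; values are log2 intensities
quant_from_log2 <- function(values, strain = "s1", fraction = "cytosolic",
                            unique_peptides = 5) {
  rows <- list()
  for (prot in names(values)) {
    for (cond in names(values[[prot]])) {
      v <- values[[prot]][[cond]]
      if (length(v) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        protein = prot, strain = strain, condition = cond,
        fraction = fraction, replicate = seq_along(v),
        intensity = 2^v, unique_peptides = unique_peptides)
    }
  }
  dplyr::bind_rows(rows)
}

# all-cytoplasmic localization map for a set of proteins
cyto_maps <- function(proteins) {
  annotation_maps(
    localization = tibble::tibble(protein = proteins,
                                  localization = "Cytoplasmic"),
    sec_sp = tibble::tibble(protein = character(), sec_sp = logical()))
}

# presence calls marking every protein "both" in one block
presence_all_both <- function(proteins, strain = "s1",
                              fraction = "cytosolic") {
  tibble::tibble(strain = strain, fraction = fraction, protein = proteins,
                 call = "both", qualified_control = TRUE,
                 qualified_induced = TRUE,
                 n_detected_control = 3L, n_detected_induced = 3L)
}

# independent brute-force implementation of the S0/permutation FDR
# procedure on a complete (no missing values) matrix: plain loops and
# textbook formulas only. `mat` is proteins x 2n, first n columns control,
# last n induced.
brute_force_perm_fdr <- function(mat, n_control, s0 = 0.1, fdr = 0.05) {
  n_col <- ncol(mat)
  n_ind <- n_col - n_control
  tstat <- function(lab_ind) {
    out <- numeric(nrow(mat))
    for (i in seq_len(nrow(mat))) {
      a <- mat[i, lab_ind]          # induced
      b <- mat[i, setdiff(seq_len(n_col), lab_ind)]
      sp2 <- ((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
        (length(a) + length(b) - 2)
      se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
      out[i] <- (mean(a) - mean(b)) / (se + s0)
    }
    out
  }
  observed_ind <- seq.int(n_control + 1, n_col)
  t_obs <- tstat(observed_ind)
  combos <- utils::combn(n_col, n_ind, simplify = FALSE)
  # drop the observed assignment and its group-swap mirror
  keep <- vapply(combos, function(cb) {
    !identical(sort(cb), sort(observed_ind)) &&
      !identical(sort(cb), sort(setdiff(seq_len(n_col), observed_ind)))
  }, logical(1))
  combos <- combos[keep]
  perm_abs <- c()
  for (cb in combos) perm_abs <- c(perm_abs, abs(tstat(cb)))
  n_perm <- length(combos)

  abs_t <- abs(t_obs)
  p <- q <- numeric(length(abs_t))
  cand <- sort(unique(abs_t))
  fdr_at <- numeric(length(cand))
  for (k in seq_along(cand)) {
    obs_count <- sum(abs_t >= cand[k])
    perm_mean <- sum(perm_abs >= cand[k]) / n_perm
    fdr_at[k] <- min(1, perm_mean / obs_count)
  }
  for (k in seq_along(cand)) fdr_at[k] <- min(fdr_at[seq_len(k)])
  for (i in seq_along(abs_t)) {
    p[i] <- (1 + sum(perm_abs >= abs_t[i])) / (1 + length(perm_abs))
    q[i] <- fdr_at[which(cand == abs_t[i])]
  }
  list(t = t_obs, p = p, q = q, significant = q <= fdr)
}
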