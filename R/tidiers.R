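#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-abundance result
#'
#' @param x A `diff_abund` tibble.
#' @param ... Unused.
#' @return A plain tibble with one row per tested protein.
#' @method tidy diff_abund
#' @export
tidy.diff_abund <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a differential-abundance result
#'
#' @param x A `diff_abund` tibble.
#' @param ... Unused.
#' @return A tibble with the test settings and the numbers of tested and
#'   significant proteins.
#' @method glance diff_abund
#' @export
glance.diff_abund <- function(x, ...) {
  s <- attr(x, "settings")
  tibble(method = s$method, s0 = s$s0,
         n_randomizations = s$n_randomizations, fdr = s$fdr,
         n_tested = sum(!is.na(x$t_s0)),
         n_significant = sum(x$significant, na.rm = TRUE))
}

#' @rdname tidy.diff_abund
#' @method tidy lfq_pca
#' @export
tidy.lfq_pca <- function(x, ...) {
  x$scores
}

#' @rdname glance.diff_abund
#' @method glance lfq_pca
#' @export
glance.lfq_pca <- function(x, ...) {
  tibble(n_proteins = x$n_proteins,
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) >= 2) x$var_explained[2] else NA_real_,
         between_distance = x$between_distance,
         within_spread = x$within_spread,
         separated = x$separated)
}

#' @rdname tidy.diff_abund
#' @method tidy sec_proportion
#' @export
tidy.sec_proportion <- function(x, ...) {
  x$per_replicate
}

#' @rdname glance.diff_abund
#' @method glance sec_proportion
#' @export
glance.sec_proportion <- function(x, ...) {
  out <- x$summary
  if (!is.null(x$t_test)) {
    out$p_between_strains <- x$t_test$p.value
  }
  out
}

#' @rdname tidy.diff_abund
#' @method tidy tau_summary
#' @export
tidy.tau_summary <- function(x, ...) {
  x$profile
}

#' @rdname glance.diff_abund
#' @method glance tau_summary
#' @export
glance.tau_summary <- function(x, ...) {
  x$auc
}
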