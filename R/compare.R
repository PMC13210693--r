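# Pairwise comparison of diagnostic residual tables between runs sharing a
# design grid, and back-calculation of the implicit diagnostic scale.

#' Compare two diagnostics tables observation by observation
#'
#' Aligns two [nm_diagnostics()] tables by `(ID, TIME)` and computes the
#' comparison metrics: the per-observation IWRES ratio (B/A) summarized as
#' mean, SD, min, max; Pearson correlations between the IWRES, WRES and CWRESI
#' vectors; the SD of IWRES in each run; maximum absolute WRES and CWRESI
#' differences; the implicit scaling factor of run B (mean and SD of
#' IRES/IWRES); and the count of extreme ratios (|ratio| > 5). Ratios with
#' `|IWRES_A|` below `ratio_eps` are excluded from the ratio summaries and
#' counted in `n_ratio_excluded`.
#'
#' @param table_a,table_b `nm_diag` tibbles with identical `(ID, TIME)` grids;
#'   `table_a` is the reference (denominator) run.
#' @param ratio_eps Reference-IWRES magnitude below which a ratio is excluded.
#' @return A one-row tibble of class `resid_comparison`; the aligned
#'   per-observation rows (ratio, differences, IPRED) are attached as the
#'   `rows` attribute and used by [flag_extremes()] and `autoplot()`.
#' @examples
#' ds <- simulate_dataset(sim_protocol("additive", n_subjects = 5, seed = 1))
#' pop <- pop_params(5, 50, omega2_cl = 0.09, omega2_v = 0.09, err = err_params(sigma1 = 0.25))
#' a <- nm_diagnostics(ds, pop, error_coding("ADD.1"))
#' b <- nm_diagnostics(ds, pop, error_coding("ADD.2"))
#' compare_runs(a, b)
#' @export
compare_runs <- function(table_a, table_b, ratio_eps = 1e-12) {
  if (nrow(table_a) != nrow(table_b)) {
    abort("tables have different numbers of observations", class = "ruvdiag_alignment_error")
  }
  key_a <- paste(table_a$ID, table_a$TIME)
  key_b <- paste(table_b$ID, table_b$TIME)
  if (!all(key_a == key_b)) {
    m <- match(key_a, key_b)
    if (any(is.na(m))) {
      abort("tables are not aligned on (ID, TIME)", class = "ruvdiag_alignment_error")
    }
    table_b <- table_b[m, ]
  }
  id_a <- attr(table_a, "coding_id") %||% "A"
  id_b <- attr(table_b, "coding_id") %||% "B"

  rows <- tibble::tibble(
    ID = table_a$ID, TIME = table_a$TIME,
    IPRED_a = table_a$IPRED, IPRED_b = table_b$IPRED,
    iwres_a = table_a$IWRES, iwres_b = table_b$IWRES,
    ratio = ifelse(abs(table_a$IWRES) < ratio_eps, NA_real_,
      table_b$IWRES / table_a$IWRES
    ),
    d_wres = table_b$WRES - table_a$WRES,
    d_cwresi = table_b$CWRESI - table_a$CWRESI
  )
  ratio <- rows$ratio[!is.na(rows$ratio)]
  iw_b <- table_b$IRES / table_b$IWRES
  iw_b <- iw_b[is.finite(iw_b)]

  out <- tibble::tibble(
    run_a = id_a, run_b = id_b, n = nrow(rows),
    ratio_mean = mean(ratio), ratio_sd = sd(ratio),
    ratio_min = min(ratio), ratio_max = max(ratio),
    r_iwres = cor(table_a$IWRES, table_b$IWRES),
    r_wres = cor(table_a$WRES, table_b$WRES),
    r_cwresi = cor(table_a$CWRESI, table_b$CWRESI),
    sd_iwres_a = sd(table_a$IWRES), sd_iwres_b = sd(table_b$IWRES),
    max_abs_diff_wres = max(abs(rows$d_wres)),
    max_abs_diff_cwresi = max(abs(rows$d_cwresi)),
    implicit_w_mean = mean(iw_b), implicit_w_sd = sd(iw_b),
    n_extreme = sum(abs(ratio) > 5),
    n_ratio_excluded = sum(is.na(rows$ratio))
  )
  class(out) <- c("resid_comparison", class(out))
  attr(out, "rows") <- rows
  out
}

#' Back-calculated implicit scaling factor
#'
#' The effective W actually applied in a run, recovered observation by
#' observation as `IRES / IWRES`. For a correctly coded run this equals the
#' coding's W evaluated at each row's IPRED; for the `W = 1` coding its mean
#' is exactly 1.
#'
#' @param table An `nm_diag` tibble.
#' @return Tibble with `ID`, `TIME`, `IPRED`, `implicit_w` for rows with
#'   nonzero IWRES; the overall mean and SD are attached as attributes
#'   `mean` and `sd`.
#' @export
implicit_w <- function(table) {
  w <- table$IRES / table$IWRES
  keep <- is.finite(w)
  if (!any(keep)) abort("IWRES is zero everywhere; implicit W undefined", class = "ruvdiag_numerical_error")
  out <- tibble::tibble(
    ID = table$ID[keep], TIME = table$TIME[keep],
    IPRED = table$IPRED[keep], implicit_w = w[keep]
  )
  attr(out, "mean") <- mean(out$implicit_w)
  attr(out, "sd") <- sd(out$implicit_w)
  out
}

#' Extreme IWRES-ratio observations
#'
#' Rows of a comparison whose IWRES ratio exceeds the threshold in magnitude,
#' with their predicted concentrations. For codings whose W is a linear
#' approximation of the combined SD these concentrate at low IPRED; for
#' codings sharing W up to a constant the set is empty.
#'
#' @param comparison A [compare_runs()] result.
#' @param threshold Magnitude threshold for the ratio (default 5).
#' @return Tibble of flagged rows: `ID`, `TIME`, `IPRED` (reference run),
#'   `ratio`, `iwres_a`, `iwres_b`.
#' @export
flag_extremes <- function(comparison, threshold = 5) {
  stopifnot(inherits(comparison, "resid_comparison"))
  rows <- attr(comparison, "rows")
  hit <- !is.na(rows$ratio) & abs(rows$ratio) > threshold
  out <- rows[hit, c("ID", "TIME", "IPRED_a", "ratio", "iwres_a", "iwres_b")]
  dplyr::rename(out, IPRED = "IPRED_a")
}
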