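#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-locus estimates of an mlHKA-style fit
#'
#' @param x A `popgenscan_hka` object from [fit_and_test()].
#' @param ... Unused.
#' @return A tibble with one row per locus: `locus_id`, `selected`,
#'   `theta` (per-site), `k`.
#' @export
tidy.popgenscan_hka <- function(x, ...) {
  x$estimates
}

#' One-row model summary of an mlHKA-style fit
#'
#' @inheritParams tidy.popgenscan_hka
#' @return A one-row tibble: `logL0`, `logL1`, `lrt`, `df`, `p_value`,
#'   `tau`.
#' @export
glance.popgenscan_hka <- function(x, ...) {
  tibble(logL0 = x$logL0, logL1 = x$logL1, lrt = x$lrt, df = x$df,
         p_value = x$p, tau = x$tau1)
}

#' Tidy a scan report into one row per gene
#'
#' @param x A `scan_report` from [run_scan()].
#' @param ... Unused.
#' @return A tibble joining the gene-level calls with the pairwise
#'   population statistics.
#' @export
tidy.scan_report <- function(x, ...) {
  if (!nrow(x$calls)) return(tibble())
  x$calls |>
    left_join(x$pair_stats |> select("gene_id", "pi_a", "pi_b", "dxy", "fold_change"),
              by = "gene_id")
}

#' One-row summary of a scan report
#'
#' @inheritParams tidy.scan_report
#' @return The headline-counts tibble of the report.
#' @export
glance.scan_report <- function(x, ...) {
  x$headline
}
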