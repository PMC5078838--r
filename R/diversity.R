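#' Within-population diversity statistics
#'
#' Per-site nucleotide diversity (theta-pi), Watterson's estimator
#' (theta-w) and Tajima's D for one haplotype alignment.  Missing data
#' (`N` or `-`) is handled by pairwise deletion: a site enters a pair's
#' comparison only when both sequences carry a called base, and each pair's
#' difference count is normalised by its own number of comparable sites.
#'
#' `nucleotide_diversity()` returns the mean over all sample pairs of
#' (differences / comparable sites).  `watterson_theta()` is
#' `S / (a1 * L)` with `a1 = sum(1/i, i = 1..n-1)`, where `S` counts sites
#' with at least two distinct called bases and `L` counts sites with at
#' least two called bases.  `tajimas_d()` uses the standard constants
#' (a1, a2, b1, b2, c1, c2, e1, e2); the mean pairwise difference count is
#' the pairwise-deletion per-site diversity scaled by `L`, for consistency
#' with theta-pi under missing data.  A monomorphic alignment has an
#' undefined D, returned as `NA` (rendered "NA" in output tables).
#'
#' @param aln A [haplo_aln()] alignment with `n >= 2` (`n >= 3` for
#'   Tajima's D).
#' @return A single numeric value.
#' @examples
#' a <- haplo_aln(c("AAAA", "AAAT", "AATT"))
#' nucleotide_diversity(a)
#' watterson_theta(a)
#' @export
nucleotide_diversity <- function(aln) {
  check_n(aln, 2L, "nucleotide_diversity")
  pd <- pairwise_div(aln$seq)
  mean(pd$prop)
}

# 0/1 indicator matrices per base plus the called-base indicator; the
# workhorse representation behind all vectorised statistics.
base_indicators <- function(m) {
  ind <- lapply(c("A", "C", "G", "T"), function(b) (m == b) * 1)
  names(ind) <- c("A", "C", "G", "T")
  called <- ind$A + ind$C + ind$G + ind$T
  list(ind = ind, called = called)
}

# per-pair differences / comparable sites for all rows of a character matrix
# (pairwise deletion), via indicator-matrix cross-products; pairs with zero
# comparable sites contribute a 0 proportion.
pairwise_div <- function(m) {
  n <- nrow(m)
  bi <- base_indicators(m)
  comp_m <- tcrossprod(bi$called)
  match_m <- Reduce(`+`, lapply(bi$ind, tcrossprod))
  diff_m <- comp_m - match_m
  ut <- upper.tri(comp_m)
  comp <- comp_m[ut]; diffs <- diff_m[ut]
  list(prop = ifelse(comp > 0, diffs / comp, 0), diffs = diffs, comp = comp)
}

# S = sites with >=2 distinct called bases; L = sites with >=2 called bases
seg_sites <- function(m) {
  bi <- base_indicators(m)
  counts <- vapply(bi$ind, colSums, numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  ncalled <- rowSums(counts)
  nalleles <- rowSums(counts > 0)
  list(S = sum(ncalled >= 2L & nalleles >= 2L), L = sum(ncalled >= 2L))
}

#' @rdname nucleotide_diversity
#' @export
watterson_theta <- function(aln) {
  check_n(aln, 2L, "watterson_theta")
  ss <- seg_sites(aln$seq)
  if (ss$L == 0L) return(0)
  a1 <- harmonic(nrow(aln$seq) - 1L)
  ss$S / (a1 * ss$L)
}

harmonic <- function(k) if (k < 1L) 0 else sum(1 / seq_len(k))

#' @rdname nucleotide_diversity
#' @export
tajimas_d <- function(aln) {
  check_n(aln, 3L, "tajimas_d")
  n <- nrow(aln$seq)
  ss <- seg_sites(aln$seq)
  S <- ss$S
  if (S == 0L) return(NA_real_)
  Pi <- nucleotide_diversity(aln) * ss$L
  a1 <- harmonic(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (Pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Summarise diversity for one alignment
#'
#' One row per population present in the alignment, with sample size, used
#' length, segregating sites, theta-pi, theta-w and Tajima's D.
#'
#' @param aln A [haplo_aln()].
#' @return A tibble with columns `gene_id`, `feature`, `population`, `n`,
#'   `L`, `S`, `pi`, `theta_w`, `tajimas_d`.
#' @export
diversity_summary <- function(aln) {
  pops <- unique(aln$population)
  purrr::map(pops, function(p) {
    sub <- aln_pop(aln, p)
    ss <- seg_sites(sub$seq)
    tibble(
      gene_id = aln$gene_id, feature = aln$feature, population = p,
      n = nrow(sub$seq), L = ss$L, S = ss$S,
      pi = nucleotide_diversity(sub),
      theta_w = watterson_theta(sub),
      tajimas_d = if (nrow(sub$seq) >= 3L) tajimas_d(sub) else NA_real_
    )
  }) |> list_rbind()
}

#' Hudson's F_ST between two populations
#'
#' `F_ST = 1 - H_w / H_b`, where `H_w` is the unweighted mean of the two
#' within-population per-site diversities and `H_b` is the per-site mean
#' pairwise difference between populations (d_xy).  When both populations
#' are identical and monomorphic (`H_b = 0`) the statistic is defined as 0.
#' Negative values (possible under this estimator) are reported as computed.
#'
#' @param aln_a,aln_b [haplo_aln()] alignments over the same region, each
#'   with `n >= 2`.
#' @return F_ST as a single numeric.
#' @export
hudson_fst <- function(aln_a, aln_b) {
  check_n(aln_a, 2L, "hudson_fst"); check_n(aln_b, 2L, "hudson_fst")
  if (ncol(aln_a$seq) != ncol(aln_b$seq)) abort("Alignments differ in length.")
  hw <- (nucleotide_diversity(aln_a) + nucleotide_diversity(aln_b)) / 2
  hb <- dxy(aln_a, aln_b)
  if (hb == 0) return(0)
  1 - hw / hb
}

#' Between-population per-site diversity (d_xy)
#'
#' Mean over all cross-population sequence pairs of differences per
#' comparable site (pairwise deletion).
#'
#' @inheritParams hudson_fst
#' @return d_xy as a single numeric.
#' @export
dxy <- function(aln_a, aln_b) {
  ba <- base_indicators(aln_a$seq)
  bb <- base_indicators(aln_b$seq)
  comp <- tcrossprod(ba$called, bb$called)
  matches <- Reduce(`+`, purrr::map2(ba$ind, bb$ind, tcrossprod))
  prop <- ifelse(comp > 0, (comp - matches) / comp, 0)
  mean(prop)
}

#' Pairwise population statistics for one gene
#'
#' @inheritParams hudson_fst
#' @return A one-row tibble: `gene_id`, `pop_a`, `pop_b`, `pi_a`, `pi_b`,
#'   `dxy`, `fst`, `fold_change` (pi_a / pi_b, see [fold_change()]).
#' @export
pairwise_pop_stats <- function(aln_a, aln_b) {
  pa <- nucleotide_diversity(aln_a)
  pb <- nucleotide_diversity(aln_b)
  tibble(
    gene_id = aln_a$gene_id,
    pop_a = unique(aln_a$population)[1], pop_b = unique(aln_b$population)[1],
    pi_a = pa, pi_b = pb, dxy = dxy(aln_a, aln_b),
    fst = hudson_fst(aln_a, aln_b),
    fold_change = fold_change(pa, pb, digits = NULL)
  )
}

#' Per-site diversity, d_xy and F_ST
#'
#' Site-wise versions of the within- and between-population statistics for
#' the base-pair-level scan.  The within-population per-site diversity is
#' the unbiased heterozygosity `(n/(n-1)) * (1 - sum(p^2))` over called
#' bases; per-site F_ST is the Hudson form restricted to that site, with
#' the `H_b = 0` convention giving 0.  Sites with fewer than two called
#' bases in a population are `NA` for that population (and for F_ST).
#'
#' @inheritParams hudson_fst
#' @return A tibble with one row per site: `site` (1-based), `div_a`,
#'   `div_b`, `dxy`, `fst`.
#' @export
per_site_stats <- function(aln_a, aln_b) {
  if (ncol(aln_a$seq) != ncol(aln_b$seq)) abort("Alignments differ in length.")
  L <- ncol(aln_a$seq)
  div_a <- site_diversity(aln_a$seq)
  div_b <- site_diversity(aln_b$seq)
  dxy_s <- site_dxy(aln_a$seq, aln_b$seq)
  hw <- (div_a + div_b) / 2
  fst <- ifelse(is.na(hw) | is.na(dxy_s), NA_real_,
                ifelse(dxy_s == 0, 0, 1 - hw / dxy_s))
  tibble(site = seq_len(L), div_a = div_a, div_b = div_b, dxy = dxy_s, fst = fst)
}

site_base_counts <- function(m) {
  bi <- base_indicators(m)
  counts <- vapply(bi$ind, colSums, numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(bi$ind)))
  counts
}

site_diversity <- function(m) {
  counts <- site_base_counts(m)
  nb <- rowSums(counts)
  sump2 <- rowSums((counts / pmax(nb, 1))^2)
  ifelse(nb < 2, NA_real_, (nb / (nb - 1)) * (1 - sump2))
}

site_dxy <- function(ma, mb) {
  ca <- site_base_counts(ma); cb <- site_base_counts(mb)
  na <- rowSums(ca); nb <- rowSums(cb)
  fa <- ca / pmax(na, 1); fb <- cb / pmax(nb, 1)
  ifelse(na < 1 | nb < 1, NA_real_, 1 - rowSums(fa * fb))
}

#' Fold change of nucleotide diversity
#'
#' Ratio `pi_a / pi_b`, reported to one decimal place as in diversity
#' fold-change summaries.  `pi_b = 0` with `pi_a > 0` is flagged infinite;
#' `0 / 0` is undefined (`NA`).
#'
#' @param pi_a,pi_b Non-negative per-site diversities.
#' @param digits Decimal places for reporting (default 1); `NULL` returns
#'   the unrounded ratio.
#' @return Numeric ratio (possibly `Inf` or `NA`).
#' @examples
#' fold_change(0.007699, 0.0002358) # 32.7
#' @export
fold_change <- function(pi_a, pi_b, digits = 1) {
  if (any(c(pi_a, pi_b) < 0)) abort("Diversities must be non-negative.", class = "popgenscan_domain_error")
  r <- ifelse(pi_b == 0, ifelse(pi_a == 0, NA_real_, Inf), pi_a / pi_b)
  if (!is.null(digits)) r <- round(r, digits)
  r
}
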