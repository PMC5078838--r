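#' Empirical percentile of a value in a distribution
#'
#' Inclusive-rank percentile: `100 * (count of values <= value) / N`, so
#' ties share the higher rank, the minimum of the distribution maps to its
#' tied rank and the maximum to 100.  Deterministic and conservative at the
#' lower tail.
#'
#' @param dist Numeric vector (the empirical background); `NA` dropped.
#' @param value Numeric vector of query values.
#' @return Percentiles in `[0, 100]`, vectorised over `value`.
#' @examples
#' empirical_quantile(1:20, 1) # 5
#' @export
empirical_quantile <- function(dist, value) {
  dist <- dist[!is.na(dist)]
  if (!length(dist)) abort("Empty background distribution.", class = "popgenscan_empty_error")
  vapply(value, function(v) {
    if (is.na(v)) NA_real_ else 100 * sum(dist <= v) / length(dist)
  }, numeric(1))
}

#' Default empirical-quantile thresholds
#'
#' The percent thresholds of the gene-level classification: purifying
#' requires descendant theta-pi and theta-w at or below the lower
#' `purifying_diversity` percent, F_ST above the `purifying_fst` percent,
#' and a negative (or undefined) Tajima's D; balancing requires theta-pi
#' and theta-w in the upper `100 - balancing_diversity` percent, Tajima's D
#' in the upper `100 - balancing_tajd` percent, and F_ST strictly between
#' `fst_low` and `fst_high` percent of the population-pair distribution.
#'
#' @param purifying_diversity,purifying_fst,balancing_diversity,
#'   balancing_tajd,fst_low,fst_high Percent thresholds in `[0, 100]`.
#' @return A named list of thresholds.
#' @export
scan_thresholds <- function(purifying_diversity = 5, purifying_fst = 95,
                            balancing_diversity = 75, balancing_tajd = 95,
                            fst_low = 10, fst_high = 90) {
  th <- list(purifying_diversity = purifying_diversity, purifying_fst = purifying_fst,
             balancing_diversity = balancing_diversity, balancing_tajd = balancing_tajd,
             fst_low = fst_low, fst_high = fst_high)
  if (any(unlist(th) < 0 | unlist(th) > 100))
    abort("Thresholds must be in [0, 100].", class = "popgenscan_config_error")
  th
}

#' Classify genes as purifying / balancing / none
#'
#' Applies the empirical-distribution criteria to per-gene statistics of
#' the descendant population.  Purifying: theta-pi and theta-w in the lower
#' 5% of the background, F_ST above 95% of the background, negative
#' Tajima's D — where an undefined D (invariant descendant gene) satisfies
#' the negative-D clause, since complete sweeps produce exactly this
#' pattern.  Balancing: theta-pi and theta-w in the upper 25%, Tajima's D
#' in the upper 5%, and F_ST between 10% and 90% of the pairwise
#' distribution.  Purifying is evaluated first; the diversity bands make
#' both calls impossible simultaneously.
#'
#' @param stats A tibble with one row per gene: `gene_id`, `pi`, `theta_w`,
#'   `tajimas_d` (descendant population) and `fst` (population pair).
#' @param background A list of numeric vectors `pi`, `theta_w`, `tajimas_d`,
#'   `fst` forming the empirical distributions (may be the gene universe
#'   itself, or a genome-wide surrogate).
#' @param thresholds A [scan_thresholds()] list.
#' @return `stats` with added columns `pct_pi`, `pct_theta_w`, `pct_tajd`,
#'   `pct_fst`, and `call` in `purifying`, `balancing`, `none`.
#' @export
classify_gene <- function(stats, background, thresholds = scan_thresholds()) {
  need <- c("gene_id", "pi", "theta_w", "tajimas_d", "fst")
  if (!all(need %in% names(stats)))
    abort(sprintf("stats needs columns: %s", paste(need, collapse = ", ")),
          class = "popgenscan_classification_error")
  if (any(is.na(stats$pi)) || any(is.na(stats$theta_w)) || any(is.na(stats$fst)))
    abort("pi, theta_w and fst must be defined for every gene.",
          class = "popgenscan_classification_error")
  th <- thresholds
  out <- stats |>
    mutate(
      pct_pi = empirical_quantile(background$pi, .data$pi),
      pct_theta_w = empirical_quantile(background$theta_w, .data$theta_w),
      pct_tajd = empirical_quantile(background$tajimas_d, .data$tajimas_d),
      pct_fst = empirical_quantile(background$fst, .data$fst)
    )
  purifying <- out$pct_pi <= th$purifying_diversity &
    out$pct_theta_w <= th$purifying_diversity &
    out$pct_fst > th$purifying_fst &
    (is.na(out$tajimas_d) | out$tajimas_d < 0)
  balancing <- !purifying &
    out$pct_pi >= th$balancing_diversity &
    out$pct_theta_w >= th$balancing_diversity &
    !is.na(out$pct_tajd) & out$pct_tajd >= th$balancing_tajd &
    out$pct_fst > th$fst_low & out$pct_fst < th$fst_high
  out$call <- dplyr::case_when(purifying ~ "purifying",
                               balancing ~ "balancing",
                               TRUE ~ "none")
  out
}

#' Classify individual sites as purifying / balancing
#'
#' Base-pair-level criteria on an ancestral/descendant comparison: a site
#' is called purifying when its diversity reduction (descendant minus
#' ancestral per-site diversity, negative) exceeds in magnitude the mean
#' per-gene diversity-change magnitude of the background, its per-site
#' F_ST is positive, and the gene-level descendant Tajima's D is negative
#' (or undefined); balancing mirrors this with an increase in diversity and
#' a positive gene-level D.  Per-site Tajima's D is not meaningful, so the
#' sign clause is taken at gene level.
#'
#' @param site_stats Output of [per_site_stats()] (ancestral = `div_a`,
#'   descendant = `div_b`), plus a `gene_id` column if several genes are
#'   stacked.
#' @param gene_tajd Gene-level descendant Tajima's D (single value, or a
#'   named vector by gene when `site_stats` covers several genes).
#' @param background_mean Mean per-gene diversity-change magnitude over the
#'   background gene set (see [site_background_mean()]).
#' @return Tibble of called sites: `gene_id`, `site`, `call`, `change`,
#'   `fst`.
#' @export
classify_sites <- function(site_stats, gene_tajd, background_mean) {
  ss <- site_stats
  if (!"gene_id" %in% names(ss)) ss$gene_id <- "gene"
  if (is.null(names(gene_tajd))) {
    gene_tajd <- setNames(rep_len(gene_tajd, 1L), unique(ss$gene_id)[1])
  }
  ss |>
    mutate(change = .data$div_b - .data$div_a,
           tajd = unname(gene_tajd[.data$gene_id])) |>
    filter(!is.na(.data$change), !is.na(.data$fst), .data$fst > 0) |>
    mutate(call = dplyr::case_when(
      .data$change < 0 & abs(.data$change) > background_mean &
        (is.na(.data$tajd) | .data$tajd < 0) ~ "purifying",
      .data$change > 0 & .data$change > background_mean &
        !is.na(.data$tajd) & .data$tajd > 0 ~ "balancing",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$call)) |>
    select("gene_id", "site", "call", "change", "fst")
}

#' Mean per-gene diversity-change magnitude
#'
#' The genome-background scalar for the site-level criteria: for each gene
#' the mean over sites of (descendant - ancestral) per-site diversity is
#' taken, and the absolute values of these per-gene means are averaged.
#'
#' @param site_stats_list A list of [per_site_stats()] tibbles, one per
#'   background gene.
#' @return A single non-negative numeric.
#' @export
site_background_mean <- function(site_stats_list) {
  ch <- map_dbl(site_stats_list, function(s) mean(s$div_b - s$div_a, na.rm = TRUE))
  mean(abs(ch), na.rm = TRUE)
}

#' Annotate site calls with codon effects
#'
#' For calls falling in coding sequence, determines the codon index, whether
#' the segregating alleles are synonymous (identical amino acids given each
#' sequence's own codon context; the majority context per allele is used
#' when contexts differ), and for non-synonymous changes the residue class
#' of the variant amino acid: nonpolar (A,V,L,I,P,F,M,W,G), polar
#' (S,T,C,Y,N,Q), acidic (D,E) or basic (K,R,H).
#'
#' @param site_calls Tibble from [classify_sites()]; `site` is 1-based
#'   within the CDS alignment.
#' @param cds_aln A [haplo_aln()] of the coding sequences (both
#'   populations), frame anchored at position 1.
#' @return `site_calls` with added `codon_index`, `effect`
#'   (`synonymous` / `non-synonymous` / `noncoding`) and `residue_class`.
#' @export
annotate_codon_effects <- function(site_calls, cds_aln) {
  tab <- codon_tables()
  L <- ncol(cds_aln$seq)
  if (L %% 3 != 0)
    abort("CDS alignment length not divisible by 3.", class = "popgenscan_frame_error")
  classes <- c(
    setNames(rep("nonpolar", 9), c("A", "V", "L", "I", "P", "F", "M", "W", "G")),
    setNames(rep("polar", 6), c("S", "T", "C", "Y", "N", "Q")),
    setNames(rep("acidic", 2), c("D", "E")),
    setNames(rep("basic", 3), c("K", "R", "H"))
  )
  annotate_one <- function(site) {
    if (site < 1 || site > L) {
      return(tibble(codon_index = NA_integer_, effect = "noncoding",
                    residue_class = NA_character_))
    }
    cidx <- (site - 1L) %/% 3L + 1L
    pos_in_codon <- (site - 1L) %% 3L + 1L
    cod_cols <- (cidx - 1L) * 3L + 1:3
    codons <- apply(cds_aln$seq[, cod_cols, drop = FALSE], 1L, paste, collapse = "")
    alleles_all <- cds_aln$seq[, site]
    ok <- alleles_all %in% c("A", "C", "G", "T") & !grepl("[^ACGT]", codons)
    alleles <- alleles_all[ok]; codons <- codons[ok]
    if (length(unique(alleles)) < 2L) {
      return(tibble(codon_index = cidx, effect = "synonymous",
                    residue_class = NA_character_))
    }
    # majority codon context per allele, translated
    aa_of <- vapply(unique(alleles), function(al) {
      ctx <- codons[alleles == al]
      maj <- names(sort(table(ctx), decreasing = TRUE))[1]
      tab$aas[match(maj, tab$codons)]
    }, character(1))
    if (length(unique(aa_of)) == 1L) {
      tibble(codon_index = cidx, effect = "synonymous", residue_class = NA_character_)
    } else {
      freqs <- table(alleles)
      minor <- names(sort(freqs))[1]
      variant_aa <- aa_of[[minor]]
      tibble(codon_index = cidx, effect = "non-synonymous",
             residue_class = unname(classes[variant_aa]))
    }
  }
  ann <- purrr::map(site_calls$site, annotate_one) |> list_rbind()
  dplyr::bind_cols(site_calls, ann)
}

#' Delimit a selective sweep around a purifying gene
#'
#' Starting from the windows overlapping the focal gene, extends left and
#' right in `window_kb` steps while window descendant diversity stays below
#' the given threshold (typically the genome lower-5% quantile of window
#' diversity).  The reported span covers all retained windows; member genes
#' are those overlapping the span.
#'
#' @param focal_gene Gene id; must be called purifying in `gene_calls`.
#' @param gene_calls Tibble with `gene_id` and `call`.
#' @param gene_pos Tibble with `gene_id`, `start`, `end` (bp).
#' @param window_diversity Tibble with `start`, `end`, `pi` per window
#'   (descendant population), covering the axis contiguously.
#' @param threshold Diversity threshold below which a window extends the
#'   sweep.
#' @return One-row tibble: `gene_id`, `span_start`, `span_end`, `span_kb`,
#'   `members` (list column of overlapped gene ids).
#' @export
detect_sweep <- function(focal_gene, gene_calls, gene_pos, window_diversity,
                         threshold) {
  cl <- gene_calls$call[match(focal_gene, gene_calls$gene_id)]
  if (is.na(cl) || cl != "purifying")
    abort("Focal gene is not called purifying.", class = "popgenscan_usage_error")
  g <- gene_pos[gene_pos$gene_id == focal_gene, ]
  wd <- dplyr::arrange(window_diversity, .data$start)
  in_focal <- which(wd$end >= g$start & wd$start <= g$end)
  lo <- min(in_focal); hi <- max(in_focal)
  below <- !is.na(wd$pi) & wd$pi < threshold
  while (lo > 1 && below[lo - 1]) lo <- lo - 1
  while (hi < nrow(wd) && below[hi + 1]) hi <- hi + 1
  span_start <- min(wd$start[lo], g$start)
  span_end <- max(wd$end[hi], g$end)
  members <- gene_pos$gene_id[gene_pos$end >= span_start & gene_pos$start <= span_end]
  members <- members[order(gene_pos$start[match(members, gene_pos$gene_id)])]
  tibble(gene_id = focal_gene, span_start = span_start, span_end = span_end,
         span_kb = (span_end - span_start + 1) / 1000, members = list(members))
}

#' Detect invariant genes
#'
#' A gene is invariant in a group when it has no segregating site there
#' (`S = 0`), and invariant overall when it is monomorphic pooling all
#' samples.
#'
#' @param summaries Tibble with columns `gene_id`, `population`, `S`;
#'   optionally a pooled population labelled `"all"`.
#' @return Tibble `gene_id`, `population`, `invariant` (logical), one row
#'   per gene per group present in `summaries`.
#' @export
detect_invariant_genes <- function(summaries) {
  summaries |>
    mutate(invariant = .data$S == 0L) |>
    select("gene_id", "population", "invariant")
}
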