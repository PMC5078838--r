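#' Run the full domestication selection scan
#'
#' Orchestrates all stages over a dataset: per-gene diversity statistics in
#' both populations, pairwise population statistics (F_ST, d_xy, fold
#' change), Ka/Ks for codon genes, empirical backgrounds, gene- and
#' site-level classification, sweep delimitation, HKA validation of called
#' genes against the neutral panel, and haplotype networks for called
#' genes.  The scan itself is deterministic: identical datasets give
#' byte-identical reports.
#'
#' The empirical background for the quantile thresholds is either the
#' analysed gene set itself (`background = "geneset"`, self-inclusive
#' ranking) or a genome-wide surrogate (`background = "genome"`): the genes
#' named in `genome_background_ids`, defaulting to the dataset's
#' neutral-regime genes, which play the role of the genome-wide empirical
#' distribution a full-genome scan would supply.
#'
#' @param dataset A `sim_dataset` from [generate_dataset()] (or a list with
#'   the same shape built from real alignments).
#' @param gene_ids Genes to analyse; default all.  An empty vector yields
#'   an empty report.
#' @param thresholds A [scan_thresholds()] list.
#' @param background `"geneset"` or `"genome"` (see above).
#' @param genome_background_ids Gene ids forming the genome surrogate
#'   background.
#' @param window_kb Sweep-scan window size in kb.
#' @param run_kaks,run_hka,run_networks Stage switches.
#' @return A `scan_report` list: `gene_stats`, `pair_stats`, `kaks`,
#'   `calls`, `site_calls`, `sweeps`, `invariant`, `hka`,
#'   `networks`, `family_summary`, `headline`, `manifest`.
#' @export
run_scan <- function(dataset, gene_ids = names(dataset$genes),
                     thresholds = scan_thresholds(),
                     background = c("geneset", "genome"),
                     genome_background_ids = NULL,
                     window_kb = 10,
                     run_kaks = TRUE, run_hka = TRUE, run_networks = TRUE) {
  background <- match.arg(background)
  meta <- dataset$gene_meta
  if (length(gene_ids) == 0) {
    return(structure(list(
      gene_stats = tibble(), pair_stats = tibble(), kaks = tibble(),
      calls = tibble(), site_calls = tibble(), sweeps = tibble(),
      invariant = tibble(), hka = NULL, networks = list(),
      family_summary = tibble(),
      headline = headline_counts(tibble(pi_a = numeric(0), pi_b = numeric(0))),
      manifest = scan_manifest(dataset, thresholds, background)
    ), class = "scan_report"))
  }
  # --- stage: diversity -----------------------------------------------------
  gene_stats <- purrr::map(gene_ids, function(g) {
    gd <- dataset$genes[[g]]
    dplyr::bind_rows(diversity_summary(gd$ancestral), diversity_summary(gd$descendant))
  }) |> list_rbind()
  pair_stats <- purrr::map(gene_ids, function(g) {
    gd <- dataset$genes[[g]]
    pairwise_pop_stats(gd$ancestral, gd$descendant)
  }) |> list_rbind()
  site_stats <- purrr::map(gene_ids, function(g) {
    gd <- dataset$genes[[g]]
    per_site_stats(gd$ancestral, gd$descendant) |> mutate(gene_id = g, .before = 1)
  })
  names(site_stats) <- gene_ids
  # --- stage: Ka/Ks (codon genes) -------------------------------------------
  kaks_tbl <- tibble()
  if (run_kaks) {
    codon_genes <- gene_ids[vapply(gene_ids, function(g)
      dataset$genes[[g]]$descendant$feature == "CDS", logical(1))]
    kaks_tbl <- purrr::map(codon_genes, function(g) {
      gd <- dataset$genes[[g]]
      comb <- aln_bind(gd$ancestral, gd$descendant)
      tryCatch(group_kaks(comb, "WildWeedy", "Landrace"),
               error = function(e) tibble())
    }) |> list_rbind()
    if (nrow(kaks_tbl)) kaks_tbl$direction <- classify_direction(kaks_tbl$ratio)
  }
  # --- stage: empirical backgrounds and gene calls --------------------------
  desc <- gene_stats |> filter(population == "Landrace")
  stats_in <- desc |>
    select("gene_id", "pi", "theta_w", "tajimas_d") |>
    left_join(pair_stats |> select("gene_id", "fst"), by = "gene_id")
  bg_ids <- switch(background,
    geneset = gene_ids,
    genome = genome_background_ids %||%
      meta$gene_id[meta$regime == "neutral" & meta$gene_id %in% gene_ids]
  )
  if (!length(bg_ids)) abort("Empty background gene set.", class = "popgenscan_config_error")
  bg_rows <- stats_in |> filter(.data$gene_id %in% bg_ids)
  bg <- list(pi = bg_rows$pi, theta_w = bg_rows$theta_w,
             tajimas_d = bg_rows$tajimas_d, fst = bg_rows$fst)
  calls <- classify_gene(stats_in, bg, thresholds)
  # --- stage: site-level calls ----------------------------------------------
  bg_mean <- site_background_mean(site_stats[bg_ids])
  gene_tajd <- setNames(desc$tajimas_d, desc$gene_id)
  site_calls <- purrr::map(gene_ids, function(g) {
    sc <- classify_sites(site_stats[[g]], gene_tajd[g], bg_mean)
    if (nrow(sc) && dataset$genes[[g]]$descendant$feature == "CDS") {
      comb <- aln_bind(dataset$genes[[g]]$ancestral, dataset$genes[[g]]$descendant)
      sc <- annotate_codon_effects(sc, comb)
    }
    sc
  }) |> list_rbind()
  # --- stage: sweeps --------------------------------------------------------
  pur_genes <- calls$gene_id[calls$call == "purifying"]
  sweeps <- tibble()
  if (length(pur_genes)) {
    pos <- meta[match(gene_ids, meta$gene_id), c("gene_id", "start", "end")]
    wd <- window_diversity(pos, desc, window_kb)
    thr <- unname(quantile(bg_rows$pi, 0.05, type = 1))
    sweeps <- purrr::map(pur_genes, function(g) {
      detect_sweep(g, calls, pos, wd, thr)
    }) |> list_rbind()
  }
  # --- stage: invariance ----------------------------------------------------
  pooled <- purrr::map(gene_ids, function(g) {
    gd <- dataset$genes[[g]]
    comb <- aln_bind(gd$ancestral, gd$descendant)
    tibble(gene_id = g, population = "all", S = seg_sites(comb$seq)$S)
  }) |> list_rbind()
  invariant <- detect_invariant_genes(
    dplyr::bind_rows(gene_stats |> select("gene_id", "population", "S"), pooled))
  # --- stage: HKA validation ------------------------------------------------
  hka <- NULL
  called <- calls$gene_id[calls$call != "none"]
  if (run_hka && length(called)) {
    panel_ids <- unique(c(bg_ids, called))
    lc <- locus_counts(dataset, population = "Landrace", gene_ids = panel_ids)
    hka <- tryCatch(fit_and_test(lc, selected_ids = called),
                    error = function(e) NULL)
  }
  # --- stage: haplotype networks --------------------------------------------
  networks <- list()
  if (run_networks && length(called)) {
    networks <- lapply(setNames(called, called), function(g) {
      gd <- dataset$genes[[g]]
      comb <- aln_bind(gd$ancestral, gd$descendant)
      tab <- collapse_haplotypes(comb, dataset$metadata)
      network_report(tab, build_network(hamming_matrix(tab)), "group")
    })
  }
  # --- summaries ------------------------------------------------------------
  fam <- family_summary(gene_stats, meta |> select("gene_id", "family"))
  report <- structure(list(
    gene_stats = gene_stats, pair_stats = pair_stats, kaks = kaks_tbl,
    calls = calls, site_calls = site_calls, sweeps = sweeps,
    invariant = invariant, hka = hka, networks = networks,
    family_summary = fam, headline = tibble(),
    manifest = scan_manifest(dataset, thresholds, background)
  ), class = "scan_report")
  report$headline <- headline_counts(report)
  report
}

scan_manifest <- function(dataset, thresholds, background) {
  list(package_version = as.character(utils::packageVersion("popgenscan")),
       seed = dataset$config$seed %||% NA_integer_,
       thresholds = thresholds, background = background,
       fst_estimator = "Hudson 1 - Hw/Hb, unweighted within-population mean",
       n_genes = length(dataset$genes))
}

# mean descendant per-gene diversity per fixed-width window along the axis
window_diversity <- function(gene_pos, desc_stats, window_kb) {
  w <- window_kb * 1000
  axis_end <- max(gene_pos$end)
  starts <- seq(1, axis_end, by = w)
  pis <- desc_stats$pi[match(gene_pos$gene_id, desc_stats$gene_id)]
  purrr::map(starts, function(s0) {
    e0 <- s0 + w - 1
    hit <- which(gene_pos$end >= s0 & gene_pos$start <= e0)
    tibble(start = s0, end = e0,
           pi = if (length(hit)) mean(pis[hit]) else NA_real_)
  }) |> list_rbind()
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("<scan_report> %d genes; calls: %s\n",
              nrow(x$pair_stats),
              if (nrow(x$calls)) paste(sprintf("%s: %d", names(table(x$calls$call)),
                                               as.integer(table(x$calls$call))), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Mean diversity per gene family
#'
#' Unweighted arithmetic mean of per-gene theta-pi within each family, per
#' population.
#'
#' @param summaries Tibble with `gene_id`, `population`, `pi`.
#' @param family_map Tibble with `gene_id`, `family`; every analysed gene
#'   must be mapped exactly once.
#' @return Tibble `family`, `population`, `mean_pi`, `n_genes`.
#' @export
family_summary <- function(summaries, family_map) {
  unmapped <- setdiff(unique(summaries$gene_id), family_map$gene_id)
  if (length(unmapped))
    abort(sprintf("Genes without a family: %s", paste(unmapped, collapse = ", ")),
          class = "popgenscan_config_error")
  summaries |>
    left_join(family_map, by = "gene_id") |>
    group_by(.data$family, .data$population) |>
    summarise(mean_pi = mean(.data$pi), n_genes = dplyr::n_distinct(.data$gene_id),
              .groups = "drop")
}

#' Headline counts and percentages for a scan report
#'
#' Number and percentage (one decimal place) of genes whose descendant
#' diversity fell below the ancestral value, gene-level call counts,
#' counts of genes with at least one site-level call per direction, and
#' the maximal per-gene diversity fold increase.
#'
#' @param report A `scan_report`, or a pair-stats tibble with `pi_a`
#'   (ancestral) and `pi_b` (descendant).
#' @return A one-row tibble of headline quantities.
#' @export
headline_counts <- function(report) {
  ps <- if (inherits(report, "scan_report")) report$pair_stats else report
  if (!nrow(ps)) {
    return(tibble(n_genes = 0L, n_decreased = 0L, pct_decreased = NA_real_))
  }
  n_tot <- nrow(ps)
  n_dec <- sum(ps$pi_b < ps$pi_a)
  out <- tibble(
    n_genes = n_tot, n_decreased = n_dec,
    pct_decreased = pct_1dp(n_dec, n_tot),
    max_fold_increase = {
      fc <- fold_change(ps$pi_b, ps$pi_a)
      if (any(is.finite(fc))) max(fc[is.finite(fc)]) else NA_real_
    }
  )
  if (inherits(report, "scan_report") && nrow(report$calls)) {
    out$n_purifying <- sum(report$calls$call == "purifying")
    out$n_balancing <- sum(report$calls$call == "balancing")
    out$n_none <- sum(report$calls$call == "none")
    sc <- report$site_calls
    out$n_genes_site_purifying <- if (nrow(sc)) dplyr::n_distinct(sc$gene_id[sc$call == "purifying"]) else 0L
    out$n_genes_site_balancing <- if (nrow(sc)) dplyr::n_distinct(sc$gene_id[sc$call == "balancing"]) else 0L
  }
  out
}

#' Percentage to one decimal place
#'
#' Truncated (not rounded) to one decimal, the convention used when
#' reporting headline gene percentages (e.g. 183 of 230 -> 79.5).
#'
#' @param k,n Numerator and denominator counts.
#' @return `100 * k / n` truncated to one decimal.
#' @examples
#' pct_1dp(183, 230)
#' @export
pct_1dp <- function(k, n) {
  if (n == 0) return(NA_real_)
  trunc(1000 * k / n) / 10
}

#' Write a scan report to disk
#'
#' Emits the positive-selection-style Ka/Ks table, the gene-level call
#' table (call, sweep kb, diversity, Tajima's D, F_ST), the per-site
#' BED-like call table (0-based half-open starts), per-network JSON/DOT
#' files, and a JSON run manifest.  Numeric cells use six decimals and
#' undefined values the literal `NA`, so repeated runs on the same dataset
#' are byte-identical.
#'
#' @param report A `scan_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scan_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(report$kaks)) {
    t1 <- report$kaks |>
      tidyr::pivot_wider(id_cols = "gene_id", names_from = "comparison",
                         values_from = "ratio") |>
      left_join(report$pair_stats |> select("gene_id", "pi_b", "pi_a"), by = "gene_id") |>
      rename(kaks_landrace = "within_b", kaks_wildweedy = "within_a",
             kaks_domestication = "between",
             pi_landrace = "pi_b", pi_wildweedy = "pi_a")
    write_results_table(t1, file.path(dir, "positive_selection.tsv"))
  }
  sweeps <- if (nrow(report$sweeps)) {
    report$sweeps |> select("gene_id", "span_kb")
  } else {
    tibble(gene_id = character(0), span_kb = numeric(0))
  }
  t2 <- report$calls |>
    left_join(report$pair_stats |> select("gene_id", "pi_a", "pi_b"), by = "gene_id") |>
    left_join(sweeps, by = "gene_id") |>
    left_join(report$gene_stats |> filter(population == "WildWeedy") |>
                select("gene_id", anc_tajd = "tajimas_d"), by = "gene_id") |>
    select("gene_id", "call", sweep_kb = "span_kb", pi_landrace = "pi_b",
           pi_wildweedy = "pi_a", tajd_landrace = "tajimas_d",
           tajd_wildweedy = "anc_tajd", "fst")
  write_results_table(t2, file.path(dir, "gene_selection.tsv"))
  if (nrow(report$site_calls)) {
    bed <- report$site_calls |>
      mutate(chrom_start = .data$site - 1L, chrom_end = .data$site) |>
      select("gene_id", "chrom_start", "chrom_end", "call",
             dplyr::any_of(c("effect", "residue_class")))
    write_results_table(bed, file.path(dir, "site_selection.tsv"))
  }
  for (g in names(report$networks)) {
    writeLines(network_json(report$networks[[g]]), file.path(dir, paste0("network_", g, ".json")))
    writeLines(network_dot(report$networks[[g]]), file.path(dir, paste0("network_", g, ".dot")))
  }
  write_results_table(report$family_summary, file.path(dir, "family_summary.tsv"))
  write_results_table(report$headline, file.path(dir, "headline.tsv"))
  writeLines(jsonlite::toJSON(report$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
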