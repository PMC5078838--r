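cfg_small <- function(...) {
  args <- utils::modifyList(
    list(n_ancestral = 8, n_descendant = 12, effective_size_ancestral = 25,
         gene_length = 600, burn_in_factor = 6, outgroup_divergence_time = 150,
         n_genes = 1),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(bottleneck_fraction = 0), class = "popgenscan_config_error")
  expect_error(sim_config(bottleneck_fraction = 1.2), class = "popgenscan_config_error")
  expect_error(sim_config(gene_length = -3), class = "popgenscan_config_error")
  expect_error(sim_config(regimes = c("neutral", "weird")), class = "popgenscan_config_error")
  expect_error(sim_config(gene_length = 1000, regimes = c("positive")),
               class = "popgenscan_config_error")
  expect_error(simulate_selected_gene(cfg_small(), "weird"),
               class = "popgenscan_config_error")
})

test_that("zero mutation rate yields identical sequences in both populations", {
  g <- simulate_neutral_gene(cfg_small(per_site_mutation_rate = 0), seed = 1)
  expect_equal(nucleotide_diversity(g$ancestral), 0)
  expect_equal(nucleotide_diversity(g$descendant), 0)
})

test_that("the simulator is byte-identical under a fixed seed", {
  a <- simulate_neutral_gene(cfg_small(), seed = 99)
  b <- simulate_neutral_gene(cfg_small(), seed = 99)
  expect_identical(a$ancestral$seq, b$ancestral$seq)
  expect_identical(a$descendant$seq, b$descendant$seq)
  expect_identical(a$outgroup, b$outgroup)

  cfg <- cfg_small(n_genes = 4, seed = 7)
  d1 <- generate_dataset(cfg); d2 <- generate_dataset(cfg)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$genes[[3]]$descendant$seq, d2$genes[[3]]$descendant$seq)
})

test_that("neutral segregating sites match the closed-form expectation", {
  cfg <- cfg_small(gene_length = 500)
  set.seed(61)
  S <- replicate(100, {
    g <- simulate_neutral_gene(cfg, seed = NULL)
    popgenscan:::seg_sites(g$ancestral$seq)$S
  })
  theta_L <- 4 * cfg$effective_size_ancestral * cfg$per_site_mutation_rate * 500
  a1 <- sum(1 / (1:(cfg$n_ancestral - 1)))
  expectation <- theta_L * a1
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expectation), 3 * se + 1e-9)
})

test_that("a complete sweep empties descendant diversity", {
  g <- simulate_selected_gene(cfg_small(sweep_completeness = 1), "purifying", seed = 3)
  expect_equal(nucleotide_diversity(g$descendant), 0)
  expect_gt(hudson_fst(g$ancestral, g$descendant), 0)
})

test_that("balancing classes reproduce the d/2 pairwise-difference expectation", {
  # two haplotype classes at frequency 0.5 differing at d sites
  cfg <- cfg_small(balancing_extra_divergence = 0, n_descendant = 12)
  g <- simulate_selected_gene(cfg, "balancing", seed = 5)
  m <- g$descendant$seq
  # oracle: direct mean pairwise difference count
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  mean_pw <- tot / (n * (n - 1) / 2)
  # class representatives: most common sequences of each half
  seqs <- apply(m, 1, paste, collapse = "")
  cls <- unique(seqs)
  expect_gte(length(cls), 2)
  d <- sum(strsplit(cls[1], "")[[1]] != strsplit(cls[2], "")[[1]])
  # two pure classes at 0.5 give n1*n2*d / C(n,2) ~ d/2 (plus within-class noise)
  expect_lt(abs(mean_pw - d / 2), d / 2 + 1)
  expect_gt(tajimas_d(g$descendant), 0)
})

test_that("codon-pair simulation respects branch length and omega truth", {
  p0 <- simulate_codon_pair(300, omega = 1, branch_length = 0, seed = 1)
  expect_identical(p0$cds_a, p0$cds_b)
  expect_error(simulate_codon_pair(300, 1, branch_length = -1),
               class = "popgenscan_config_error")
  expect_error(simulate_codon_pair(301, 1), class = "popgenscan_config_error")

  set.seed(62)
  ratios <- replicate(40, {
    p <- simulate_codon_pair(900, omega = 3, branch_length = 0.1)
    kaks_ng86(p$cds_a, p$cds_b)$ratio
  })
  expect_gte(mean(ratios > 1, na.rm = TRUE), 0.9)
})

test_that("datasets carry exact truth tables and the neutral HKA panel", {
  cfg <- cfg_small(regimes = rep("neutral", 10), seed = 2)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$truth), 10)
  expect_equal(sum(ds$truth$regime == "neutral"), 10)
  expect_setequal(names(ds$genes), ds$truth$gene_id)
  # alignments rectangular, gap-free
  expect_true(all(vapply(ds$genes, function(g)
    all(g$descendant$seq %in% c("A", "C", "G", "T")), logical(1))))
  # default config carries >= 30 neutral reference genes
  expect_gte(sum(sim_config()$regimes == "neutral"), 30)
})

test_that("the default dataset shows the genome-wide-scale diversity reduction", {
  # overall descendant/ancestral mean diversity ratio tuned to the ~1.7-fold
  # genome-wide domestication reduction, allowed to range about [1/2.2, 1/1.3]
  ds <- generate_dataset(sim_config(seed = 19))
  r <- vapply(names(ds$genes), function(g) {
    gd <- ds$genes[[g]]
    c(nucleotide_diversity(gd$ancestral), nucleotide_diversity(gd$descendant))
  }, numeric(2))
  ratio <- mean(r[2, ]) / mean(r[1, ])
  expect_gte(ratio, 1 / 2.2)
  expect_lte(ratio, 1 / 1.3)
})

test_that("expected descendant diversity does not increase as the bottleneck tightens", {
  base <- cfg_small(gene_length = 400)
  mean_pi <- function(frac) {
    cfg <- cfg_small(gene_length = 400, bottleneck_fraction = frac)
    mean(replicate(12, nucleotide_diversity(
      simulate_neutral_gene(cfg, seed = NULL)$descendant)))
  }
  set.seed(63)
  pis <- c(tight = mean_pi(0.08), mid = mean_pi(0.4), open = mean_pi(1))
  expect_lt(pis["tight"], pis["open"])
})
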