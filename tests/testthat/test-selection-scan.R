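test_that("empirical percentiles use inclusive ranks with ties high", {
  expect_equal(empirical_quantile(1:20, 20), 100)
  expect_equal(empirical_quantile(1:20, 0.5), 0)
  expect_equal(empirical_quantile(1:20, 1), 5)           # first order statistic
  expect_equal(empirical_quantile(c(1, 1, 1, 2), 1), 75) # ties share the higher rank
  expect_error(empirical_quantile(numeric(0), 1), class = "popgenscan_empty_error")
  set.seed(71)
  d <- runif(37)
  for (v in sample(d, 5)) expect_equal(empirical_quantile(d, v), oracle_quantile(d, v))
})

test_that("gene classification reproduces the printed domestication calls", {
  # stipulated background placing the five published rows in the stated bands
  set.seed(72)
  bg <- list(
    pi = seq(0.0005, 0.0035, length.out = 100),
    theta_w = seq(0.0005, 0.0035, length.out = 100),
    tajimas_d = seq(-0.3, 1.5, length.out = 100),
    fst = seq(0.05, 0.5, length.out = 100)
  )
  rows <- tibble::tibble(
    gene_id = c("Sobic.001G422300", "Sobic.002G413100", "Sobic.007G078500",
                "Sobic.006G169500", "Sobic.009G225700"),
    pi = c(0, 0, 0.000026, 0.007699, 0.003671),
    theta_w = c(0, 0, 0.000026, 0.007699, 0.003671),
    tajimas_d = c(NA, NA, -0.567739, 2.001733, 3.008451),
    fst = c(0.694667, 0.593150, 0.644061, 0.274193, 0.188190)
  )
  out <- classify_gene(rows, bg)
  expect_equal(out$call, c("purifying", "purifying", "purifying",
                           "balancing", "balancing"))
  # a gene sitting at the background median is not called
  mid <- tibble::tibble(gene_id = "mid", pi = 0.002, theta_w = 0.002,
                        tajimas_d = 0.6, fst = 0.27)
  expect_equal(classify_gene(mid, bg)$call, "none")
  expect_error(classify_gene(mid[, -2], bg), class = "popgenscan_classification_error")
})

test_that("site classification follows the three clauses and an independent reimplementation", {
  # forced purifying call: diversity collapse, positive F_ST, negative gene D
  ss <- tibble::tibble(site = 1:3,
                       div_a = c(0.5, 0, 0.2), div_b = c(0, 0, 0.2),
                       dxy = c(0.5, 0, 0.2), fst = c(0.5, NA, 0))
  out <- classify_sites(ss, gene_tajd = -1, background_mean = 0.1)
  expect_equal(out$site, 1L)
  expect_equal(out$call, "purifying")

  set.seed(73)
  a <- random_alignment(8, 60); b <- random_alignment(8, 60)
  st <- per_site_stats(a, b) |> dplyr::mutate(gene_id = "g")
  bgm <- 0.05
  got <- classify_sites(st, gene_tajd = c(g = 1.5), background_mean = bgm)
  # straight-line clause-by-clause oracle
  want <- integer(0)
  for (i in seq_len(nrow(st))) {
    ch <- st$div_b[i] - st$div_a[i]
    if (!is.na(ch) && !is.na(st$fst[i]) && st$fst[i] > 0 && ch > bgm) {
      want <- c(want, i)  # gene D positive: only balancing possible
    }
  }
  expect_equal(got$site, want)
  if (nrow(got)) expect_true(all(got$call == "balancing"))
})

test_that("codon effects and residue classes are annotated from codon context", {
  # third-position GGT/GGC is synonymous (both Gly)
  aln <- haplo_aln(c("GGTAAA", "GGCAAA", "GGTAAA"), feature = "CDS")
  calls <- tibble::tibble(gene_id = "g", site = 3L, call = "purifying",
                          change = -0.2, fst = 0.5)
  ann <- annotate_codon_effects(calls, aln)
  expect_equal(ann$effect, "synonymous")
  expect_equal(ann$codon_index, 1L)

  # first-position GAA/AAA: Glu -> Lys, variant residue basic
  aln2 <- haplo_aln(c("GAAACC", "GAAACC", "AAAACC"), feature = "CDS")
  ann2 <- annotate_codon_effects(dplyr::mutate(calls, site = 1L), aln2)
  expect_equal(ann2$effect, "non-synonymous")
  expect_equal(ann2$residue_class, "basic")

  # simulated CDS with a known single mutation annotates consistently
  set.seed(74)
  p <- simulate_codon_pair(90, omega = 3, branch_length = 0.02)
  m <- rbind(strsplit(p$cds_a, "")[[1]], strsplit(p$cds_b, "")[[1]],
             strsplit(p$cds_b, "")[[1]])
  diffsites <- which(m[1, ] != m[2, ])
  if (length(diffsites)) {
    alnp <- haplo_aln(m, feature = "CDS")
    annp <- annotate_codon_effects(
      tibble::tibble(gene_id = "g", site = diffsites[1], call = "purifying",
                     change = -0.1, fst = 0.3), alnp)
    cod <- (diffsites[1] - 1) %/% 3 + 1
    c1 <- substr(p$cds_a, (cod - 1) * 3 + 1, cod * 3)
    c2 <- substr(p$cds_b, (cod - 1) * 3 + 1, cod * 3)
    same_aa <- .oracle_gc[[c1]] == .oracle_gc[[c2]]
    expect_equal(annp$effect, if (same_aa) "synonymous" else "non-synonymous")
  }
})

test_that("sweep delimitation extends through low-diversity windows only", {
  calls <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          call = c("purifying", "none", "purifying"))
  pos <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        start = c(10001, 30001, 50001), end = c(12000, 32000, 52000))
  win <- function(pis) tibble::tibble(start = seq(1, 60001, 10000),
                                      end = seq(10000, 70000, 10000), pi = pis)
  # isolated low-diversity gene: high-diversity flanks stop the extension
  wd <- win(c(0.01, 0.0001, 0.01, 0.01, 0.01, 0.01, 0.01))
  sw <- detect_sweep("g1", calls, pos, wd, threshold = 0.001)
  expect_equal(sw$span_start, 10001)
  expect_equal(sw$span_end, 20000)
  expect_equal(sw$members[[1]], "g1")
  # a shared five-window trough gives both purifying genes the same members
  wd2 <- win(c(0.01, 0.0001, 0.0001, 0.0001, 0.0001, 0.0001, 0.01))
  s1 <- detect_sweep("g1", calls, pos, wd2, threshold = 0.001)
  s3 <- detect_sweep("g3", calls, pos, wd2, threshold = 0.001)
  expect_equal(s1$members[[1]], s3$members[[1]])
  expect_equal(s1$span_kb, 50)
  expect_error(detect_sweep("g2", calls, pos, wd, 0.001),
               class = "popgenscan_usage_error")
})

test_that("invariance detection recovers forced monomorphic genes", {
  sums <- tibble::tibble(gene_id = c("a", "a", "b", "b"),
                         population = c("x", "y", "x", "y"),
                         S = c(0L, 3L, 0L, 0L))
  inv <- detect_invariant_genes(sums)
  expect_true(inv$invariant[inv$gene_id == "a" & inv$population == "x"])
  expect_false(inv$invariant[inv$gene_id == "a" & inv$population == "y"])
  expect_true(all(inv$invariant[inv$gene_id == "b"]))
})
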