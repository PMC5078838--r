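#' Simulation configuration for a two-population domestication dataset
#'
#' Parameters of the forward Wright-Fisher simulator that emulates a
#' resequencing panel: an ancestral (wild) population at mutation-drift
#' equilibrium, a descendant (landrace) population derived from it through a
#' domestication bottleneck, and an outgroup lineage for divergence-based
#' tests.  Defaults are chosen to echo a 44-genotype sorghum-like panel:
#' 14 wild-type and 36 landrace-type haplotypes, a per-site theta of
#' `4 * N * mu = 0.003`, and a bottleneck calibrated so that expected
#' descendant diversity is reduced about 1.7-fold
#' (`exp(d_b / N_b + g_post / (2N)) ~ 1.7`), matching genome-wide
#' domestication estimates for this system.
#'
#' @param n_ancestral,n_descendant Haplotypes sampled from the wild and
#'   landrace populations.
#' @param effective_size_ancestral Diploid effective size `N` of the
#'   ancestral population (the simulator tracks `2N` haplotypes).
#' @param bottleneck_fraction Fraction of `2N` retained during the
#'   bottleneck, in `(0, 1]`.
#' @param bottleneck_duration Generations spent at the reduced size.
#' @param post_bottleneck_generations Generations at full size between the
#'   end of the bottleneck and sampling.
#' @param per_site_mutation_rate Mutations per site per generation.
#' @param n_genes Number of genes when `regimes` is not given.
#' @param gene_length Gene length in bp (multiple of 3 for codon genes).
#' @param regimes Per-gene labels in `neutral`, `purifying`, `balancing`,
#'   `positive`; default 50/10/10/5 in that order.
#' @param outgroup_divergence_time Generations before sampling at which the
#'   outgroup lineage split from the ancestral population.
#' @param burn_in_factor Burn-in length in units of `2N` generations.
#' @param sweep_completeness Fraction of the descendant sample carrying the
#'   swept haplotype under the purifying regime.
#' @param sweep_extra_divergence Extra private divergence (substitutions per
#'   site) carried by the swept haplotype, modelling selection on a rare
#'   divergent allele plus hitchhiking — what distinguishes a sweep from
#'   pure bottleneck drift.
#' @param balancing_freq Frequency of the first maintained haplotype class
#'   under the balancing regime.
#' @param balancing_extra_divergence Shared private divergence
#'   (substitutions per site) of the second maintained class, modelling a
#'   balanced allele whose coalescence predates the neutral TMRCA.
#' @param positive_omega Nonsynonymous/synonymous rate ratio for the
#'   positive regime.
#' @param positive_divergence Substitutions per site accumulated by the
#'   descendant lineage of a positive-regime gene.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ancestral = 14, n_descendant = 36,
                       effective_size_ancestral = 50,
                       bottleneck_fraction = 0.1,
                       bottleneck_duration = 8,
                       post_bottleneck_generations = 10,
                       per_site_mutation_rate = 1.5e-5,
                       n_genes = 75, gene_length = 1500,
                       regimes = NULL,
                       outgroup_divergence_time = 400,
                       burn_in_factor = 8,
                       sweep_completeness = 1,
                       sweep_extra_divergence = 0.004,
                       balancing_freq = 0.5,
                       balancing_extra_divergence = 0.004,
                       positive_omega = 3,
                       positive_divergence = 0.05,
                       seed = 1L) {
  if (is.null(regimes)) {
    regimes <- if (n_genes == 75) {
      rep(c("neutral", "purifying", "balancing", "positive"), c(50, 10, 10, 5))
    } else {
      rep("neutral", n_genes)
    }
  }
  cfg <- list(
    n_ancestral = n_ancestral, n_descendant = n_descendant,
    effective_size_ancestral = effective_size_ancestral,
    bottleneck_fraction = bottleneck_fraction,
    bottleneck_duration = bottleneck_duration,
    post_bottleneck_generations = post_bottleneck_generations,
    per_site_mutation_rate = per_site_mutation_rate,
    n_genes = length(regimes), gene_length = gene_length, regimes = regimes,
    outgroup_divergence_time = outgroup_divergence_time,
    burn_in_factor = burn_in_factor,
    sweep_completeness = sweep_completeness,
    sweep_extra_divergence = sweep_extra_divergence,
    balancing_freq = balancing_freq,
    balancing_extra_divergence = balancing_extra_divergence,
    positive_omega = positive_omega,
    positive_divergence = positive_divergence,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (bottleneck_fraction <= 0 || bottleneck_fraction > 1)
      abort("bottleneck_fraction must be in (0, 1].", class = "popgenscan_config_error")
    counts <- c(n_ancestral, n_descendant, effective_size_ancestral,
                gene_length, n_genes)
    if (any(counts <= 0))
      abort("All counts and sizes must be positive.", class = "popgenscan_config_error")
    if (per_site_mutation_rate < 0)
      abort("per_site_mutation_rate must be >= 0.", class = "popgenscan_config_error")
    if (!all(regimes %in% c("neutral", "purifying", "balancing", "positive")))
      abort("Unknown regime label.", class = "popgenscan_config_error")
    if (any(regimes == "positive") && gene_length %% 3 != 0)
      abort("gene_length must be divisible by 3 for codon (positive-regime) genes.",
            class = "popgenscan_config_error")
    m2 <- 2 * effective_size_ancestral
    post_split <- bottleneck_duration + post_bottleneck_generations
    if (outgroup_divergence_time < post_split ||
        outgroup_divergence_time > burn_in_factor * m2 + post_split)
      abort("outgroup_divergence_time must fall within the simulated ancestral epoch.",
            class = "popgenscan_config_error")
    if (n_ancestral > m2 || n_descendant > m2)
      abort("Sample sizes cannot exceed 2N haplotypes.", class = "popgenscan_config_error")
  })
  invisible(cfg)
}

# one Wright-Fisher generation step loop; pop is a list of integer vectors of
# mutation ids, env$next_id the mutation counter; returns the evolved pop.
wf_evolve <- function(pop, size, gens, mu_gene, env) {
  if (gens <= 0) return(pop)
  for (g in seq_len(gens)) {
    pop <- pop[sample.int(length(pop), size, replace = TRUE)]
    nm <- rpois(1L, size * mu_gene)
    if (nm > 0L) {
      who <- sample.int(size, nm, replace = TRUE)
      for (k in seq_len(nm)) {
        id <- env$next_id
        env$next_id <- id + 1L
        pop[[who[k]]] <- c(pop[[who[k]]], id)
      }
    }
  }
  pop
}

# Forward simulation of one (non-codon) gene: burn-in, split, bottleneck,
# outgroup snapshot.  Returns sampled mutation-id sets and the outgroup's.
sim_gene_core <- function(cfg, gene_length) {
  M <- 2L * cfg$effective_size_ancestral
  mu_gene <- cfg$per_site_mutation_rate * gene_length
  burn_in <- as.integer(round(cfg$burn_in_factor * M))
  post_split <- cfg$bottleneck_duration + cfg$post_bottleneck_generations
  snap_gen <- burn_in + post_split - cfg$outgroup_divergence_time  # in [0, burn_in]
  env <- new.env(parent = emptyenv())
  env$next_id <- 1L
  pop <- rep(list(integer(0)), M)
  pop <- wf_evolve(pop, M, snap_gen, mu_gene, env)
  out_progenitor <- pop[[sample.int(M, 1L)]]
  pop <- wf_evolve(pop, M, burn_in - snap_gen, mu_gene, env)
  wild <- wf_evolve(pop, M, post_split, mu_gene, env)
  Mb <- max(2L, as.integer(round(cfg$bottleneck_fraction * M)))
  dom <- wf_evolve(pop, Mb, cfg$bottleneck_duration, mu_gene, env)
  dom <- wf_evolve(dom, M, cfg$post_bottleneck_generations, mu_gene, env)
  n_out_mut <- rpois(1L, mu_gene * cfg$outgroup_divergence_time)
  out_ids <- c(out_progenitor, seq.int(env$next_id, length.out = n_out_mut))
  env$next_id <- env$next_id + n_out_mut
  anc_idx <- sample.int(M, cfg$n_ancestral)
  des_idx <- sample.int(M, cfg$n_descendant)
  list(anc = wild[anc_idx], des = dom[des_idx], outgroup = out_ids,
       wild_pop = wild)
}

# map mutation-id sets to a character alignment over a random reference
ids_to_sequences <- function(sets, gene_length) {
  ids <- sort(unique(unlist(sets)))
  if (length(ids) > gene_length)
    abort("More segregating mutations than sites; increase gene_length.",
          class = "popgenscan_config_error")
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, gene_length, replace = TRUE)
  pos <- if (length(ids)) sort(sample.int(gene_length, length(ids))) else integer(0)
  derived <- vapply(pos, function(p) sample(setdiff(bases, ref[p]), 1L), character(1))
  seqs <- matrix(rep(ref, each = length(sets)), nrow = length(sets))
  for (i in seq_along(sets)) {
    hit <- match(sets[[i]], ids)
    hit <- hit[!is.na(hit)]
    if (length(hit)) seqs[i, pos[hit]] <- derived[hit]
  }
  list(matrix = seqs, ref = ref, pos = pos, derived = derived, ids = ids)
}

sample_names <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))

core_to_alignments <- function(core, cfg, gene_length, gene_id) {
  all_sets <- c(core$anc, core$des, list(core$outgroup))
  sq <- ids_to_sequences(all_sets, gene_length)
  na <- length(core$anc); nd <- length(core$des)
  anc <- haplo_aln(sq$matrix[seq_len(na), , drop = FALSE],
                   samples = sample_names("WW", na),
                   populations = "WildWeedy", gene_id = gene_id)
  des <- haplo_aln(sq$matrix[na + seq_len(nd), , drop = FALSE],
                   samples = sample_names("LR", nd),
                   populations = "Landrace", gene_id = gene_id)
  outg <- paste(sq$matrix[na + nd + 1L, ], collapse = "")
  list(ancestral = anc, descendant = des, outgroup = outg)
}

#' Simulate one neutral gene
#'
#' Runs the forward Wright-Fisher model for a single gene and returns the
#' sampled ancestral and descendant alignments plus the outgroup sequence.
#' The descendant population derives from the ancestral one through a
#' bottleneck of `bottleneck_fraction * 2N` haplotypes lasting
#' `bottleneck_duration` generations followed by recovery; the outgroup
#' lineage split `outgroup_divergence_time` generations before sampling.
#'
#' @param config A [sim_config()].
#' @param gene_length Gene length in bp; defaults to the config value.
#' @param seed Seed for this gene; defaults to the config seed.
#' @param gene_id Identifier attached to the alignments.
#' @return A list: `ancestral`, `descendant` ([haplo_aln()]), `outgroup`
#'   (character string), `truth` (one-row tibble).
#' @export
simulate_neutral_gene <- function(config, gene_length = config$gene_length,
                                  seed = config$seed, gene_id = "gene") {
  if (gene_length < 1) abort("gene_length must be >= 1.", class = "popgenscan_config_error")
  if (!is.null(seed)) set.seed(seed)
  core <- sim_gene_core(config, gene_length)
  out <- core_to_alignments(core, config, gene_length, gene_id)
  out$truth <- tibble(gene_id = gene_id, regime = "neutral", omega = NA_real_)
  out
}

#' Simulate one gene under a selection regime
#'
#' Selection regimes are imposed phenomenologically on the neutral
#' two-population model so that truth labels are exact: `purifying` applies
#' a post-bottleneck selective sweep (one haplotype rises to
#' `sweep_completeness` of the descendant sample, suppressing diversity,
#' inflating F_ST and pushing Tajima's D negative); `balancing` maintains
#' the two most-divergent ancestral haplotype classes at intermediate
#' frequency in the descendant sample (elevated diversity, positive
#' Tajima's D); `positive` simulates the gene as a codon sequence whose
#' descendant lineage fixes substitutions under `omega = positive_omega`.
#'
#' @inheritParams simulate_neutral_gene
#' @param regime One of `"purifying"`, `"balancing"`, `"positive"`.
#' @return As [simulate_neutral_gene()], with the regime recorded in
#'   `truth`.
#' @export
simulate_selected_gene <- function(config, regime, gene_length = config$gene_length,
                                   seed = config$seed, gene_id = "gene") {
  if (!regime %in% c("purifying", "balancing", "positive"))
    abort(sprintf("Unknown regime '%s'.", regime), class = "popgenscan_config_error")
  if (!is.null(seed)) set.seed(seed)
  if (regime == "positive") return(simulate_positive_gene(config, gene_length, gene_id))
  core <- sim_gene_core(config, gene_length)
  n_des <- length(core$des)
  symdiff_size <- function(a, b) length(union(a, b)) - length(intersect(a, b))
  if (regime == "purifying") {
    # directional selection fixes a previously rare, divergent allele: sweep
    # the available haplotype most distant from the ancestral consensus, so
    # the sweep is distinguishable from pure drift (elevated F_ST)
    maj <- table(unlist(lapply(core$anc, unique)))
    maj_ids <- as.integer(names(maj)[maj > length(core$anc) / 2])
    dists <- vapply(core$wild_pop, function(h) symdiff_size(h, maj_ids), numeric(1))
    swept <- core$wild_pop[[which.max(dists)]]
    n_extra <- rpois(1L, config$sweep_extra_divergence * gene_length)
    if (n_extra > 0L) {
      swept <- c(swept, max(c(0L, unlist(core$anc), unlist(core$des),
                              core$outgroup)) + seq_len(n_extra))
    }
    k <- round(config$sweep_completeness * n_des)
    which_rows <- sample.int(n_des, k)
    for (i in which_rows) core$des[[i]] <- swept
  } else {
    # balancing: both of the two most-divergent ancestral haplotype classes
    # persist at intermediate frequency, retaining within-class variation
    cand <- unique(core$anc)
    if (length(cand) < 2L) cand <- list(cand[[1]], c(cand[[1]], -1L))  # forced variant
    best <- c(1L, min(2L, length(cand))); bestd <- -1L
    for (i in seq_along(cand)) for (j in seq_along(cand)) {
      if (i < j) {
        d <- symdiff_size(cand[[i]], cand[[j]])
        if (d > bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    h1 <- cand[[best[1]]]; h2 <- cand[[best[2]]]
    cluster <- vapply(core$wild_pop, function(h)
      symdiff_size(h, h1) <= symdiff_size(h, h2), logical(1))
    pool1 <- core$wild_pop[cluster]; pool2 <- core$wild_pop[!cluster]
    if (!length(pool1)) pool1 <- list(h1)
    if (!length(pool2)) pool2 <- list(h2)
    # a balanced allele class older than the neutral TMRCA: private shared
    # divergence marks the maintained second class
    n_extra <- rpois(1L, config$balancing_extra_divergence * gene_length)
    if (n_extra > 0L) {
      extra <- max(c(0L, unlist(core$anc), unlist(core$des), unlist(pool2),
                     core$outgroup)) + seq_len(n_extra)
      pool2 <- lapply(pool2, function(h) c(h, extra))
    }
    n1 <- round(config$balancing_freq * n_des)
    core$des <- c(pool1[sample.int(length(pool1), n1, replace = TRUE)],
                  pool2[sample.int(length(pool2), n_des - n1, replace = TRUE)])
  }
  out <- core_to_alignments(core, config, gene_length, gene_id)
  out$truth <- tibble(gene_id = gene_id, regime = regime,
                      omega = if (regime == "positive") config$positive_omega else NA_real_)
  out
}

# positive regime: codon gene; ancestral sample carries sparse neutral codon
# polymorphism around a random stop-free CDS; the descendant lineage fixes
# substitutions drawn with omega = positive_omega.
simulate_positive_gene <- function(config, gene_length, gene_id) {
  ref <- random_cds(gene_length)
  theta_site <- 4 * config$effective_size_ancestral * config$per_site_mutation_rate
  anc_seqs <- t(vapply(seq_len(config$n_ancestral), function(i) {
    evolve_codon_seq(ref, omega = 1, kappa_R = 1, kappa_Y = 1,
                     branch_length = theta_site / 2)
  }, character(gene_length)))
  des_hap <- evolve_codon_seq(ref, omega = config$positive_omega, kappa_R = 1,
                              kappa_Y = 1, branch_length = config$positive_divergence)
  des_seqs <- matrix(rep(des_hap, each = config$n_descendant),
                     nrow = config$n_descendant)
  outg <- evolve_codon_seq(ref, omega = 1, kappa_R = 1, kappa_Y = 1,
                           branch_length = 2 * config$per_site_mutation_rate *
                             config$outgroup_divergence_time)
  list(
    ancestral = haplo_aln(anc_seqs, samples = sample_names("WW", config$n_ancestral),
                          populations = "WildWeedy", gene_id = gene_id, feature = "CDS"),
    descendant = haplo_aln(des_seqs, samples = sample_names("LR", config$n_descendant),
                           populations = "Landrace", gene_id = gene_id, feature = "CDS"),
    outgroup = paste(outg, collapse = ""),
    truth = tibble(gene_id = gene_id, regime = "positive", omega = config$positive_omega)
  )
}

random_cds <- function(gene_length) {
  tab <- codon_tables()
  ok <- which(!tab$is_stop)
  idx <- sample(ok, gene_length / 3, replace = TRUE)
  unlist(strsplit(tab$codons[idx], ""), use.names = FALSE)
}

# evolve a codon sequence (character vector) under the event-count codon
# model; expected realised divergence is branch_length substitutions/site.
evolve_codon_seq <- function(seq_chars, omega, kappa_R, kappa_Y, branch_length) {
  if (branch_length < 0) abort("branch_length must be >= 0.", class = "popgenscan_config_error")
  tab <- codon_tables()
  L <- length(seq_chars)
  ncod <- L / 3
  cod_idx <- match(paste0(seq_chars[seq(1, L, 3)],
                          seq_chars[seq(2, L, 3)],
                          seq_chars[seq(3, L, 3)]), tab$codons)
  n_events <- rpois(1L, branch_length * L)
  if (n_events == 0L) return(seq_chars)
  wclass <- c(kappa_R, kappa_Y, 1)
  codon_w <- function(ci) {
    # 3 pos x 3 alts weight matrix for codon index ci
    w <- matrix(0, 3, 3)
    for (p in 1:3) for (k in 1:3) {
      if (tab$nb_viable[ci, p, k]) {
        w[p, k] <- wclass[tab$nb_class[ci, p, k]] *
          (if (tab$nb_syn[ci, p, k]) 1 else omega)
      }
    }
    w
  }
  W <- array(0, c(ncod, 3, 3))
  for (c0 in seq_len(ncod)) W[c0, , ] <- codon_w(cod_idx[c0])
  for (e in seq_len(n_events)) {
    flat <- as.vector(W)
    pick <- sample.int(length(flat), 1L, prob = flat)
    k <- (pick - 1L) %/% (ncod * 3L) + 1L
    p <- ((pick - 1L) %/% ncod) %% 3L + 1L
    c0 <- (pick - 1L) %% ncod + 1L
    cod_idx[c0] <- tab$nb_codon[cod_idx[c0], p, k]
    W[c0, , ] <- codon_w(cod_idx[c0])
  }
  unlist(strsplit(tab$codons[cod_idx], ""), use.names = FALSE)
}

#' Simulate a diverged pair of coding sequences
#'
#' Test harness for the Ka/Ks estimators: evolves a random stop-free CDS
#' along a branch under a codon model with nonsynonymous/synonymous rate
#' ratio `omega` and transition weights `kappa_R` (purine) and `kappa_Y`
#' (pyrimidine).  The number of substitution events is Poisson with mean
#' `branch_length * gene_length`, so `branch_length` is the expected
#' realised divergence in substitutions per site.
#'
#' @param gene_length CDS length, divisible by 3.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param kappa_R,kappa_Y Purine / pyrimidine transition weights.
#' @param branch_length Expected substitutions per site (>= 0).
#' @param seed Optional seed.
#' @return A list: `cds_a`, `cds_b` (character strings), `truth` (tibble
#'   with the generating parameters).
#' @export
simulate_codon_pair <- function(gene_length, omega, kappa_R = 1, kappa_Y = 1,
                                branch_length = 0.1, seed = NULL) {
  if (gene_length %% 3 != 0)
    abort("gene_length must be divisible by 3.", class = "popgenscan_config_error")
  if (branch_length < 0) abort("branch_length must be >= 0.", class = "popgenscan_config_error")
  if (!is.null(seed)) set.seed(seed)
  a <- random_cds(gene_length)
  b <- evolve_codon_seq(a, omega, kappa_R, kappa_Y, branch_length)
  list(cds_a = paste(a, collapse = ""), cds_b = paste(b, collapse = ""),
       truth = tibble(omega = omega, kappa_R = kappa_R, kappa_Y = kappa_Y,
                      branch_length = branch_length))
}

#' Generate a full synthetic dataset
#'
#' Simulates every gene in `config$regimes` (neutral genes double as the
#' neutral reference panel for HKA-style tests), assigns gene families and
#' tandem chromosome positions, and builds the sample metadata table.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list: `genes` (named list with `ancestral`,
#'   `descendant`, `outgroup` per gene), `gene_meta` (tibble: gene_id,
#'   regime, family, chrom, start, end), `truth` (tibble), `metadata`
#'   (sample metadata tibble), `config`.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  fams <- c("AMT1", "AMT2", "NRT1/PTR", "NRT2", "NRT3", "NR", "NiR", "GS",
            "GOGAT", "GDH", "AST", "AS", "ASPG", "AAL")
  n <- config$n_genes
  ids <- sprintf("gene%03d", seq_len(n))
  genes <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    r <- config$regimes[i]
    g <- if (r == "neutral") {
      simulate_neutral_gene(config, seed = NULL, gene_id = ids[i])
    } else {
      simulate_selected_gene(config, r, seed = NULL, gene_id = ids[i])
    }
    truth[[i]] <- g$truth
    genes[[i]] <- g[c("ancestral", "descendant", "outgroup")]
  }
  names(genes) <- ids
  gene_meta <- tibble(
    gene_id = ids, regime = config$regimes,
    family = fams[(seq_len(n) - 1L) %% length(fams) + 1L],
    chrom = "chr1",
    start = (seq_len(n) - 1L) * 20000L + 1L,
    end = (seq_len(n) - 1L) * 20000L + config$gene_length
  )
  geo <- c("EastAfrica", "WestAfrica", "SouthAfrica", "Asia", "NewWorld")
  races <- c("caudatum", "complex", "durra", "guinea", "kafir")
  meta <- tibble(
    sample = c(sample_names("WW", config$n_ancestral),
               sample_names("LR", config$n_descendant), "OUT01"),
    group = c(rep("WildWeedy", config$n_ancestral),
              rep("Landrace", config$n_descendant), "Spropinquum"),
    geography = c(sample(geo, config$n_ancestral + config$n_descendant, replace = TRUE),
                  "Asia"),
    race = c(rep("wild", config$n_ancestral),
             sample(races, config$n_descendant, replace = TRUE), "Spropinquum")
  )
  structure(list(genes = genes, gene_meta = gene_meta,
                 truth = list_rbind(truth), metadata = meta, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genes (%s); %d + %d samples + outgroup; seed %d\n",
              length(x$genes),
              paste(sprintf("%s: %d", names(table(x$gene_meta$regime)),
                            as.integer(table(x$gene_meta$regime))), collapse = ", "),
              x$config$n_ancestral, x$config$n_descendant, x$config$seed))
  invisible(x)
}
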