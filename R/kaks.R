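#' @title Ka/Ks estimation for coding sequence pairs
#' @description Pairwise estimates of the nonsynonymous (Ka) and synonymous
#'   (Ks) substitution rates by the NG86 pathway-counting method and by an
#'   approximate MYN-style method that models distinct purine-transition and
#'   pyrimidine-transition rates.  A ratio above one indicates positive
#'   selection, below one purifying selection, equal to one neutrality.
#' @name kaks
NULL

# --- genetic code tables -----------------------------------------------------

.pg <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.pg$tab)) return(.pg$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)                      # 64, TTT..GGG order
  aas <- unname(gc)
  bases <- c("A", "C", "G", "T")
  nt <- do.call(rbind, strsplit(codons, ""))
  is_stop <- aas == "*"
  # change class: 1 = purine transition (A<->G), 2 = pyrimidine (C<->T), 3 = tv
  cls <- function(x, y) {
    if ((x == "A" && y == "G") || (x == "G" && y == "A")) 1L
    else if ((x == "C" && y == "T") || (x == "T" && y == "C")) 2L
    else 3L
  }
  # neighbour table: for codon c, pos p, alternative base k (3 per pos)
  nb_codon <- array(NA_integer_, c(64, 3, 3))  # index of neighbour codon
  nb_syn <- array(FALSE, c(64, 3, 3))
  nb_viable <- array(FALSE, c(64, 3, 3))
  nb_class <- array(NA_integer_, c(64, 3, 3))
  for (c0 in 1:64) {
    for (p in 1:3) {
      alts <- setdiff(bases, nt[c0, p])
      for (k in 1:3) {
        cd <- nt[c0, ]
        cd[p] <- alts[k]
        j <- match(paste(cd, collapse = ""), codons)
        nb_codon[c0, p, k] <- j
        nb_viable[c0, p, k] <- !is_stop[j]
        nb_syn[c0, p, k] <- aas[j] == aas[c0]
        nb_class[c0, p, k] <- cls(nt[c0, p], alts[k])
      }
    }
  }
  # per-codon counts of viable / viable-synonymous changes by class and pos
  cnt_all <- array(0, c(64, 3, 3))  # codon x pos x class
  cnt_syn <- array(0, c(64, 3, 3))
  for (c0 in 1:64) for (p in 1:3) for (k in 1:3) {
    if (nb_viable[c0, p, k]) {
      cl <- nb_class[c0, p, k]
      cnt_all[c0, p, cl] <- cnt_all[c0, p, cl] + 1
      if (nb_syn[c0, p, k]) cnt_syn[c0, p, cl] <- cnt_syn[c0, p, cl] + 1
    }
  }
  # pathway-averaged difference counts for all 64x64 codon pairs
  SD <- matrix(0, 64, 64); ND <- matrix(0, 64, 64)
  CC <- vector("list", 6)  # class-resolved: synAG synCT synTV nonAG nonCT nonTV
  for (q in 1:6) CC[[q]] <- matrix(0, 64, 64)
  for (i in 1:64) {
    if (is_stop[i]) next
    for (j in 1:64) {
      if (is_stop[j] || i == j) next
      pw <- codon_path_counts(nt[i, ], nt[j, ], codons, aas, cls)
      SD[i, j] <- pw$sd; ND[i, j] <- pw$nd
      for (q in 1:6) CC[[q]][i, j] <- pw$byclass[q]
    }
  }
  # alternative base at (codon, pos, k), matching nb_codon's ordering
  nb_alt <- array(NA_character_, c(64, 3, 3))
  for (c0 in 1:64) for (p in 1:3) nb_alt[c0, p, ] <- setdiff(bases, nt[c0, p])
  .pg$tab <- list(codons = codons, aas = aas, is_stop = is_stop, nt = nt,
                  cnt_all = cnt_all, cnt_syn = cnt_syn, SD = SD, ND = ND, CC = CC,
                  nb_codon = nb_codon, nb_syn = nb_syn, nb_viable = nb_viable,
                  nb_class = nb_class, nb_alt = nb_alt)
  .pg$tab
}

# average syn/nonsyn (and class-resolved) step counts over all mutational
# pathways between two codons, skipping pathways through stop codons; if every
# pathway passes a stop, average over all pathways (stop steps = nonsynonymous).
codon_path_counts <- function(ca, cb, codons, aas, cls) {
  dpos <- which(ca != cb)
  perms <- perms_of(dpos)
  acc <- function(valid_only) {
    tot <- rep(0, 8); npath <- 0
    for (ord in perms) {
      cur <- ca
      steps <- matrix(0, length(ord), 8)  # sd, nd, synAG..nonTV (6)
      ok <- TRUE
      for (s in seq_along(ord)) {
        p <- ord[s]
        nxt <- cur; nxt[p] <- cb[p]
        aan <- aas[match(paste(nxt, collapse = ""), codons)]
        aac <- aas[match(paste(cur, collapse = ""), codons)]
        if (valid_only && aan == "*" && s < length(ord)) { ok <- FALSE; break }
        syn <- aan == aac && aan != "*"
        cl <- cls(cur[p], cb[p])
        steps[s, 1] <- as.numeric(syn); steps[s, 2] <- as.numeric(!syn)
        steps[s, 2 + (if (syn) 0 else 3) + cl] <- 1
        cur <- nxt
      }
      if (ok) { tot <- tot + colSums(steps); npath <- npath + 1 }
    }
    list(tot = tot, npath = npath)
  }
  r <- acc(TRUE)
  if (r$npath == 0) r <- acc(FALSE)
  avg <- r$tot / r$npath
  list(sd = avg[1], nd = avg[2], byclass = avg[3:8])
}

perms_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# --- codon alignment handling ------------------------------------------------

# split two CDS strings into codon index vectors, dropping (pairwise) codons
# with any non-ACGT character; errors on frame violations and internal stops.
codon_indices <- function(cds_a, cds_b) {
  tab <- codon_tables()
  a <- toupper(cds_a); b <- toupper(cds_b)
  if (nchar(a) != nchar(b)) abort("CDS lengths differ.", class = "popgenscan_frame_error")
  if (nchar(a) %% 3 != 0) abort("CDS length not divisible by 3.", class = "popgenscan_frame_error")
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  ia <- match(ca, tab$codons); ib <- match(cb, tab$codons)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  ncod <- length(ia)
  stop_a <- tab$is_stop[ia]; stop_b <- tab$is_stop[ib]
  # a terminal stop in both is tolerated and dropped; internal stops are errors
  if (ncod && stop_a[ncod] && stop_b[ncod]) {
    ia <- ia[-ncod]; ib <- ib[-ncod]
    stop_a <- stop_a[-ncod]; stop_b <- stop_b[-ncod]
  }
  if (any(stop_a) || any(stop_b)) {
    abort("Internal stop codon in coding sequence.", class = "popgenscan_data_error")
  }
  list(ia = ia, ib = ib, ncodon = length(ia))
}

#' NG86 site and difference counts
#'
#' Counts synonymous and nonsynonymous sites (each codon position contributes
#' its fraction of synonymous single-nucleotide changes among viable,
#' non-stop-producing changes, averaged over the two sequences) and
#' pathway-averaged synonymous/nonsynonymous differences (codons differing at
#' more than one position average over all orderings of the changes, skipping
#' orderings that pass through a stop codon).  Codons containing `N` or gaps
#' in either sequence are dropped from both.
#'
#' @param cds_a,cds_b Coding sequences (character strings), equal length
#'   divisible by 3, frame anchored at position 1.
#' @return A list: `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`,
#'   `ncodon`.
#' @export
count_ng86 <- function(cds_a, cds_b) {
  tab <- codon_tables()
  ci <- codon_indices(cds_a, cds_b)
  if (ci$ncodon == 0L) abort("No comparable codons.", class = "popgenscan_data_error")
  s_a <- ng86_sites(ci$ia, 1, 1); s_b <- ng86_sites(ci$ib, 1, 1)
  syn_sites <- (s_a + s_b) / 2
  nonsyn_sites <- 3 * ci$ncodon - syn_sites
  diff <- ci$ia != ci$ib
  sd <- sum(tab$SD[cbind(ci$ia[diff], ci$ib[diff])])
  nd <- sum(tab$ND[cbind(ci$ia[diff], ci$ib[diff])])
  list(syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       syn_diffs = sd, nonsyn_diffs = nd, ncodon = ci$ncodon)
}

# total synonymous sites of a codon-index vector under transition weights
ng86_sites <- function(idx, kappa_R, kappa_Y) {
  tab <- codon_tables()
  w <- c(kappa_R, kappa_Y, 1)
  # fraction synonymous at each codon x pos, weighted by class
  num <- tab$cnt_syn[idx, , 1, drop = FALSE] * w[1] +
    tab$cnt_syn[idx, , 2, drop = FALSE] * w[2] +
    tab$cnt_syn[idx, , 3, drop = FALSE] * w[3]
  den <- tab$cnt_all[idx, , 1, drop = FALSE] * w[1] +
    tab$cnt_all[idx, , 2, drop = FALSE] * w[2] +
    tab$cnt_all[idx, , 3, drop = FALSE] * w[3]
  sum(ifelse(den > 0, num / den, 0))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

kaks_row <- function(ka, ks, method, counts, kappa_R = NA_real_, kappa_Y = NA_real_,
                     converged = TRUE) {
  ka <- unname(ka); ks <- unname(ks)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  out <- tibble(
    ka = ka, ks = ks, ratio = ratio, p_value = NA_real_, method = method,
    kappa_R = kappa_R, kappa_Y = kappa_Y,
    syn_sites = counts$syn_sites, nonsyn_sites = counts$nonsyn_sites,
    syn_diffs = counts$syn_diffs, nonsyn_diffs = counts$nonsyn_diffs,
    ncodon = counts$ncodon, converged = converged
  )
  out$p_value <- kaks_significance(out)
  out
}

#' Ka/Ks by the NG86 method
#'
#' Proportions `pN`, `pS` from [count_ng86()] are Jukes-Cantor corrected
#' (`d = -3/4 log(1 - 4p/3)`); a proportion of 3/4 or more makes that
#' distance inestimable (`NA`), and `Ks = 0` makes the ratio `NA`.
#'
#' @inheritParams count_ng86
#' @return A one-row tibble (`ka`, `ks`, `ratio`, `p_value`, `method`,
#'   `kappa_R`, `kappa_Y`, the counts, `converged`).
#' @examples
#' kaks_ng86("ATGGCT", "ATGGCA")
#' @export
kaks_ng86 <- function(cds_a, cds_b) {
  ct <- count_ng86(cds_a, cds_b)
  pn <- ct$nonsyn_diffs / ct$nonsyn_sites
  ps <- ct$syn_diffs / ct$syn_sites
  kaks_row(jc_correct(pn), jc_correct(ps), "NG86", ct)
}

# --- MYN-style estimator -----------------------------------------------------

# equal-frequency Tamura-Nei-form distance from (P1, P2, Q): P1 = purine
# transition fraction, P2 = pyrimidine transition fraction, Q = transversion
# fraction, all per site.  Returns list(d, a1t, a2t, bt) or NULL if
# inestimable.
tn_distance <- function(P1, P2, Q) {
  w1 <- 1 - Q - 4 * P1
  w2 <- 1 - Q - 4 * P2
  w3 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NULL)
  bt <- -0.25 * log(w3)
  a1t <- -0.5 * log(w1) - bt
  a2t <- -0.5 * log(w2) - bt
  if (a1t < 0) a1t <- 0
  if (a2t < 0) a2t <- 0
  list(d = (a1t + a2t) / 2 + 2 * bt, a1t = a1t, a2t = a2t, bt = bt)
}

kappa_bounds <- function(k) min(max(k, 0.1), 50)

#' Ka/Ks by an approximate MYN-style method
#'
#' Distinct purine-transition and pyrimidine-transition weights `kappa_R`,
#' `kappa_Y` are estimated from the data and iterated with the
#' rate-weighted site counts until successive (Ka, Ks) change by less than
#' 1e-8 (at most 100 iterations).  Differences are pathway-averaged as in
#' NG86 but resolved into purine-transition, pyrimidine-transition and
#' transversion steps, and each of Ka and Ks is corrected under an
#' equal-frequency Tamura-Nei-form three-class model.  Saturated or
#' degenerate configurations yield a flagged (`converged = FALSE`) result
#' with `NA` distances rather than an error.
#'
#' @inheritParams count_ng86
#' @return A one-row tibble as for [kaks_ng86()], with `kappa_R`, `kappa_Y`
#'   filled in.
#' @export
kaks_myn <- function(cds_a, cds_b) {
  tab <- codon_tables()
  ci <- codon_indices(cds_a, cds_b)
  if (ci$ncodon == 0L) abort("No comparable codons.", class = "popgenscan_data_error")
  diff <- ci$ia != ci$ib
  # class-resolved pathway-averaged difference counts
  byc <- vapply(1:6, function(q) sum(tab$CC[[q]][cbind(ci$ia[diff], ci$ib[diff])]),
                numeric(1))
  names(byc) <- c("synAG", "synCT", "synTV", "nonAG", "nonCT", "nonTV")
  sd <- byc["synAG"] + byc["synCT"] + byc["synTV"]
  nd <- byc["nonAG"] + byc["nonCT"] + byc["nonTV"]
  kR <- 1; kY <- 1
  ka <- ks <- Inf
  converged <- FALSE
  for (it in 1:100) {
    s_sites <- (ng86_sites(ci$ia, kR, kY) + ng86_sites(ci$ib, kR, kY)) / 2
    n_sites <- 3 * ci$ncodon - s_sites
    ds <- tn_distance(byc["synAG"] / s_sites, byc["synCT"] / s_sites, byc["synTV"] / s_sites)
    dn <- tn_distance(byc["nonAG"] / n_sites, byc["nonCT"] / n_sites, byc["nonTV"] / n_sites)
    if (is.null(ds) || is.null(dn)) {
      counts <- list(syn_sites = s_sites, nonsyn_sites = n_sites,
                     syn_diffs = unname(sd), nonsyn_diffs = unname(nd), ncodon = ci$ncodon)
      return(kaks_row(NA_real_, NA_real_, "MYN", counts, kR, kY, converged = FALSE))
    }
    ka_new <- dn$d; ks_new <- ds$d
    # pooled corrected rates drive the kappa update
    a1 <- (ds$a1t * s_sites + dn$a1t * n_sites) / (s_sites + n_sites)
    a2 <- (ds$a2t * s_sites + dn$a2t * n_sites) / (s_sites + n_sites)
    b <- (ds$bt * s_sites + dn$bt * n_sites) / (s_sites + n_sites)
    if (b > 1e-9) {
      kR <- kappa_bounds(a1 / b)
      kY <- kappa_bounds(a2 / b)
    }
    if (abs(ka_new - ka) < 1e-8 && abs(ks_new - ks) < 1e-8) {
      ka <- ka_new; ks <- ks_new; converged <- TRUE
      break
    }
    ka <- ka_new; ks <- ks_new
  }
  counts <- list(syn_sites = (ng86_sites(ci$ia, kR, kY) + ng86_sites(ci$ib, kR, kY)) / 2,
                 nonsyn_sites = NA_real_, syn_diffs = unname(sd),
                 nonsyn_diffs = unname(nd), ncodon = ci$ncodon)
  counts$nonsyn_sites <- 3 * ci$ncodon - counts$syn_sites
  kaks_row(ka, ks, "MYN", counts, kR, kY, converged = converged)
}

#' Significance of Ka differing from Ks
#'
#' Two-sided Fisher exact test on the 2x2 table of rounded synonymous /
#' nonsynonymous differences against their site counts.
#'
#' @param result A one-row Ka/Ks result tibble (or anything with
#'   `syn_diffs`, `syn_sites`, `nonsyn_diffs`, `nonsyn_sites`).
#' @return p-value in `[0, 1]`, or `NA` if counts are undefined.
#' @export
kaks_significance <- function(result) {
  sdf <- round(result$syn_diffs); ssi <- round(result$syn_sites)
  ndf <- round(result$nonsyn_diffs); nsi <- round(result$nonsyn_sites)
  if (any(is.na(c(sdf, ssi, ndf, nsi))) || ssi <= 0 || nsi <= 0) return(NA_real_)
  m <- matrix(c(sdf, ssi - sdf, ndf, nsi - ndf), nrow = 2, byrow = TRUE)
  if (any(m < 0)) return(NA_real_)
  stats::fisher.test(m)$p.value
}

#' Selection direction from a Ka/Ks ratio
#'
#' @param ratio Numeric vector of Ka/Ks ratios (may contain `NA`).
#' @return Character vector: `"positive"` (> 1), `"purifying"` (< 1),
#'   `"neutral"` (equal to 1 within 1e-9), or `NA`.
#' @examples
#' classify_direction(c(1.57499, 0.245, 1, NA))
#' @export
classify_direction <- function(ratio) {
  dplyr::case_when(
    is.na(ratio) ~ NA_character_,
    abs(ratio - 1) <= 1e-9 ~ "neutral",
    ratio > 1 ~ "positive",
    TRUE ~ "purifying"
  )
}

#' Population-level Ka/Ks over sequence pairs
#'
#' Within-group values average the NG86 Ka and Ks over all within-group
#' sequence pairs; the between-group ("domestication") value averages over
#' all cross-group pairs.  The ratio reported is the ratio of the averaged
#' Ka to the averaged Ks (a per-pair ratio is undefined whenever a pair has
#' Ks = 0, so averaging the rates first is the stable choice; recorded in
#' the `scheme` attribute).
#'
#' @param cds_aln A [haplo_aln()] of coding sequences (feature `"CDS"`).
#' @param pop_a,pop_b The two population labels to compare.
#' @return A tibble with one row per comparison (`within_a`, `within_b`,
#'   `between`) and columns `gene_id`, `comparison`, `ka`, `ks`, `ratio`,
#'   `n_pairs`.
#' @export
group_kaks <- function(cds_aln, pop_a, pop_b) {
  rows_a <- which(cds_aln$population == pop_a)
  rows_b <- which(cds_aln$population == pop_b)
  seqs <- apply(cds_aln$seq, 1L, paste, collapse = "")
  uniq <- unique(seqs)
  uidx <- match(seqs, uniq)
  cache <- new.env(parent = emptyenv())
  kaks_cached <- function(i, j) {
    key <- paste(sort(c(uidx[i], uidx[j])), collapse = "_")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- kaks_ng86(uniq[uidx[i]], uniq[uidx[j]])
      cache[[key]] <- got
    }
    got
  }
  pair_mean <- function(pairs) {
    if (!nrow(pairs)) return(tibble(ka = NA_real_, ks = NA_real_, ratio = NA_real_, n_pairs = 0L))
    res <- purrr::map(seq_len(nrow(pairs)), function(k) {
      kaks_cached(pairs[k, 1], pairs[k, 2])
    }) |> list_rbind()
    ka <- mean(res$ka, na.rm = TRUE); ks <- mean(res$ks, na.rm = TRUE)
    tibble(ka = ka, ks = ks,
           ratio = if (is.finite(ks) && ks > 0 && is.finite(ka)) ka / ks else NA_real_,
           n_pairs = nrow(pairs))
  }
  within <- function(rows) {
    if (length(rows) < 2) return(matrix(integer(0), ncol = 2))
    t(combn(rows, 2))
  }
  between <- as.matrix(expand.grid(rows_a, rows_b))
  out <- dplyr::bind_rows(
    pair_mean(within(rows_a)) |> mutate(comparison = "within_a"),
    pair_mean(within(rows_b)) |> mutate(comparison = "within_b"),
    pair_mean(between) |> mutate(comparison = "between")
  ) |>
    mutate(gene_id = cds_aln$gene_id, .before = 1)
  attr(out, "scheme") <- "mean Ka and mean Ks over pairs; ratio of means"
  out
}
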