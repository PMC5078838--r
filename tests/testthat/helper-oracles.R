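# Independent brute-force oracles: deliberately written as plain loops over
# pairs and sites (or exhaustive enumeration), sharing no code path with the
# package's vectorised implementations.

random_alignment <- function(n, L, miss = 0, pops = "pop1") {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  if (miss > 0) {
    idx <- which(runif(n * L) < miss)
    m[idx] <- sample(c("N", "-"), length(idx), replace = TRUE)
  }
  haplo_aln(m, populations = pops)
}

oracle_pi <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- 0; c <- 0
    for (s in seq_len(ncol(m))) {
      a <- m[i, s]; b <- m[j, s]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        c <- c + 1
        if (a != b) d <- d + 1
      }
    }
    tot <- tot + if (c > 0) d / c else 0
  }
  tot / (n * (n - 1) / 2)
}

oracle_seg <- function(m) {
  S <- 0L; L <- 0L
  for (s in seq_len(ncol(m))) {
    b <- m[, s]
    b <- b[b %in% c("A", "C", "G", "T")]
    if (length(b) >= 2) {
      L <- L + 1L
      if (length(unique(b)) >= 2) S <- S + 1L
    }
  }
  list(S = S, L = L)
}

oracle_watterson <- function(m) {
  ss <- oracle_seg(m)
  if (ss$L == 0) return(0)
  a1 <- 0
  for (i in 1:(nrow(m) - 1)) a1 <- a1 + 1 / i
  ss$S / (a1 * ss$L)
}

oracle_tajd <- function(m) {
  n <- nrow(m)
  ss <- oracle_seg(m)
  S <- ss$S
  if (S == 0) return(NA_real_)
  Pi <- oracle_pi(m) * ss$L
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (Pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_dxy <- function(ma, mb) {
  tot <- 0
  for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
    d <- 0; c <- 0
    for (s in seq_len(ncol(ma))) {
      a <- ma[i, s]; b <- mb[j, s]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        c <- c + 1
        if (a != b) d <- d + 1
      }
    }
    tot <- tot + if (c > 0) d / c else 0
  }
  tot / (nrow(ma) * nrow(mb))
}

oracle_fst <- function(ma, mb) {
  hw <- (oracle_pi(ma) + oracle_pi(mb)) / 2
  hb <- oracle_dxy(ma, mb)
  if (hb == 0) 0 else 1 - hw / hb
}

oracle_quantile <- function(dist, v) {
  dist <- dist[!is.na(dist)]
  cnt <- 0
  for (x in dist) if (x <= v) cnt <- cnt + 1
  100 * cnt / length(dist)
}

oracle_hamming <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  sum(a != b)
}

# exhaustive minimum spanning tree weight over all k^(k-2)-ish trees: try all
# subsets of k-1 edges and keep connected ones (k small)
oracle_mst_weight <- function(d) {
  k <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(pairs)
  best <- Inf
  for (comb in utils::combn(ne, k - 1, simplify = FALSE)) {
    # connectivity check via repeated merging
    grp <- seq_len(k)
    for (e in comb) {
      ga <- grp[pairs[e, 1]]; gb <- grp[pairs[e, 2]]
      grp[grp == gb] <- ga
    }
    if (length(unique(grp)) == 1) {
      w <- sum(d[pairs[comb, , drop = FALSE]])
      if (w < best) best <- w
    }
  }
  best
}

oracle_fisher <- function(a, b, c, d) {
  # two-sided Fisher exact p by hypergeometric enumeration
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1))
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- independent NG86 oracle -------------------------------------------------

.oracle_gc <- as.list(Biostrings::GENETIC_CODE)

oracle_codon_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- .oracle_gc[[codon]]
  total <- 0
  for (p in 1:3) {
    nsyn <- 0; nviable <- 0
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      aam <- .oracle_gc[[mut]]
      if (aam != "*") {
        nviable <- nviable + 1
        if (aam == aa0) nsyn <- nsyn + 1
      }
    }
    if (nviable > 0) total <- total + nsyn / nviable
  }
  total
}

oracle_codon_path <- function(c1, c2, skip_stops = TRUE) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  orders <- if (length(dpos) == 1) list(dpos) else {
    perms <- list()
    rec <- function(left, acc) {
      if (!length(left)) { perms[[length(perms) + 1]] <<- acc; return(invisible()) }
      for (i in seq_along(left)) rec(left[-i], c(acc, left[i]))
    }
    rec(dpos, integer(0))
    perms
  }
  tally <- function(require_viable) {
    tot <- c(sd = 0, nd = 0); np <- 0
    for (ord in orders) {
      cur <- c1; path <- c(sd = 0, nd = 0); ok <- TRUE
      for (s in seq_along(ord)) {
        p <- ord[s]
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (require_viable && .oracle_gc[[nxt]] == "*" && s < length(ord)) { ok <- FALSE; break }
        if (.oracle_gc[[nxt]] == .oracle_gc[[cur]] && .oracle_gc[[nxt]] != "*") {
          path["sd"] <- path["sd"] + 1
        } else {
          path["nd"] <- path["nd"] + 1
        }
        cur <- nxt
      }
      if (ok) { tot <- tot + path; np <- np + 1 }
    }
    list(tot = tot, np = np)
  }
  r <- tally(skip_stops)
  if (r$np == 0) r <- tally(FALSE)
  r$tot / r$np
}

oracle_ng86 <- function(cds_a, cds_b) {
  split_codons <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  syn_sites <- 0; sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    syn_sites <- syn_sites + (oracle_codon_syn_sites(ca[i]) + oracle_codon_syn_sites(cb[i])) / 2
    pw <- oracle_codon_path(ca[i], cb[i])
    sd <- sd + pw["sd"]; nd <- nd + pw["nd"]
  }
  list(syn_sites = syn_sites, nonsyn_sites = 3 * length(ca) - syn_sites,
       syn_diffs = unname(sd), nonsyn_diffs = unname(nd))
}

# random stop-free CDS as a string
random_cds_string <- function(ncodon) {
  bases <- c("A", "C", "G", "T")
  out <- character(ncodon)
  for (i in seq_len(ncodon)) {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (.oracle_gc[[cd]] != "*") { out[i] <- cd; break }
    }
  }
  paste(out, collapse = "")
}
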