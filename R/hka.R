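#' Per-locus polymorphism and divergence counts
#'
#' Builds the `LocusCounts` table consumed by the HKA-family tests from a
#' simulated or assembled dataset: within-species segregating sites `S`
#' from the chosen population sample, and divergence `D` as the number of
#' differences between the outgroup sequence and the within-species
#' majority consensus (polymorphic sites still count in `S`; counting the
#' consensus avoids double counting polymorphism as divergence).
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @param population Which population supplies the within-species sample.
#' @param gene_ids Genes to include (default: all).
#' @return A tibble: `locus_id`, `n`, `L`, `S`, `D`.
#' @export
locus_counts <- function(dataset, population = "Landrace",
                         gene_ids = names(dataset$genes)) {
  purrr::map(gene_ids, function(g) {
    gd <- dataset$genes[[g]]
    aln <- if (population == "Landrace") gd$descendant else gd$ancestral
    ss <- seg_sites(aln$seq)
    cons <- consensus_seq(aln$seq)
    outg <- strsplit(gd$outgroup, "")[[1]]
    ok <- cons %in% c("A", "C", "G", "T") & outg %in% c("A", "C", "G", "T")
    tibble(locus_id = g, n = nrow(aln$seq), L = ncol(aln$seq),
           S = ss$S, D = sum(cons[ok] != outg[ok]))
  }) |> list_rbind()
}

consensus_seq <- function(m) {
  counts <- site_base_counts(m)
  top <- max.col(counts, ties.method = "first")
  out <- c("A", "C", "G", "T")[top]
  out[rowSums(counts) == 0] <- "N"
  out
}

#' Classic HKA test
#'
#' Moment-fit multilocus HKA: per-locus scaled mutation parameters and the
#' species divergence time are solved from `E[S_i] = theta_i a1(n_i) L_i`
#' and `E[D_i] = theta_i L_i (tau + 1)` (the `+ 1` carries the expected
#' ancestral coalescence), and the goodness-of-fit statistic sums the
#' standardised squared deviations of `S` and `D` with
#' `Var[S] = E[S] + a2(n) (theta L)^2` and `Var[D] = E[D] + (theta L)^2`.
#' The statistic is referred to a chi-squared distribution with
#' `2 * n_loci - (n_loci + 1)` degrees of freedom.
#'
#' @param loci Tibble of locus counts: `locus_id`, `n`, `L`, `S`, `D`.
#' @return A list: `x2`, `df`, `p`, `tau`, `theta` (per-locus per-site),
#'   `expected` (tibble of fitted `E[S]`, `E[D]`).
#' @export
classic_hka <- function(loci) {
  if (nrow(loci) < 2L) abort("classic_hka needs >= 2 loci.", class = "popgenscan_usage_error")
  if (all(loci$S == 0) && all(loci$D == 0))
    abort("All counts are zero; the HKA fit is degenerate.",
          class = "popgenscan_degenerate_error")
  a1 <- vapply(loci$n, function(n) harmonic(n - 1L), numeric(1))
  a2 <- vapply(loci$n, function(n) sum(1 / seq_len(n - 1L)^2), numeric(1))
  tot <- loci$S + loci$D
  gfun <- function(tau) {
    thL <- tot / (a1 + tau + 1)
    sum(loci$D) - (tau + 1) * sum(thL)
  }
  # g is decreasing in tau; handle boundary cases then solve
  tau <- if (gfun(1e-9) <= 0) {
    1e-9
  } else if (gfun(1e6) >= 0) {
    1e6
  } else {
    uniroot(gfun, c(1e-9, 1e6), tol = 1e-10)$root
  }
  thL <- tot / (a1 + tau + 1)
  eS <- thL * a1
  eD <- thL * (tau + 1)
  vS <- eS + a2 * thL^2
  vD <- eD + thL^2
  x2 <- sum((loci$S - eS)^2 / vS + (loci$D - eD)^2 / vD)
  df <- 2 * nrow(loci) - (nrow(loci) + 1)
  list(x2 = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE),
       tau = tau, theta = thL / loci$L,
       expected = tibble(locus_id = loci$locus_id, e_s = eS, e_d = eD))
}

#' Log-likelihood of the mlHKA-style model
#'
#' Poisson observation model: `S_i ~ Poisson(k_i theta_i a1(n_i) L_i)` and
#' `D_i ~ Poisson(theta_i L_i (tau + 1))`, with the selection parameter
#' `k_i = 1` at non-selected loci.  A zero expectation facing a nonzero
#' count yields `-Inf` (returned, not raised).
#'
#' @param model A list: `theta` (per-site, per locus), `tau`, `k` (per
#'   locus, 1 for neutral loci).
#' @param loci Locus-count tibble as in [classic_hka()].
#' @return The log-likelihood (scalar; possibly `-Inf`).
#' @export
mlhka_loglik <- function(model, loci) {
  a1 <- vapply(loci$n, function(n) harmonic(n - 1L), numeric(1))
  thL <- model$theta * loci$L
  k <- rep_len(model$k %||% 1, nrow(loci))
  lamS <- k * thL * a1
  lamD <- thL * (model$tau + 1)
  ll_term <- function(x, lam) {
    ifelse(lam == 0, ifelse(x == 0, 0, -Inf), dpois(x, lam, log = TRUE))
  }
  sum(ll_term(loci$S, lamS)) + sum(ll_term(loci$D, lamD))
}

# profile log-likelihood over tau: per-locus theta (and k at selected loci)
# maximised in closed form.  Selected loci are saturated (S and D fitted
# exactly), so they contribute a tau-free constant.
profile_loglik <- function(tau, loci, selected) {
  a1 <- vapply(loci$n, function(n) harmonic(n - 1L), numeric(1))
  neutral <- !selected
  thL <- numeric(nrow(loci))
  thL[neutral] <- (loci$S[neutral] + loci$D[neutral]) /
    (a1[neutral] + tau + 1)
  ll <- 0
  if (any(neutral)) {
    lamS <- thL[neutral] * a1[neutral]
    lamD <- thL[neutral] * (tau + 1)
    term <- function(x, lam) ifelse(lam == 0, ifelse(x == 0, 0, -Inf),
                                    dpois(x, lam, log = TRUE))
    ll <- sum(term(loci$S[neutral], lamS)) + sum(term(loci$D[neutral], lamD))
  }
  if (any(selected)) {
    sat <- function(x) ifelse(x == 0, 0, dpois(x, x, log = TRUE))
    ll <- ll + sum(sat(loci$S[selected])) + sum(sat(loci$D[selected]))
  }
  ll
}

#' Fit and test the mlHKA-style selection model
#'
#' Maximises the Poisson likelihood under the neutral model (all `k = 1`)
#' and under the selection model (free `k > 0` at the designated loci) by
#' bounded multi-start optimisation over the divergence parameter, with
#' per-locus nuisance parameters profiled in closed form, and forms the
#' likelihood-ratio test `LRT = 2 (logL1 - logL0)` on `df = number of
#' selected loci` degrees of freedom.
#'
#' @param loci Locus-count tibble.
#' @param selected_ids Character vector of selected `locus_id`s (may be
#'   empty: then `LRT = 0`, `p = 1`).
#' @param n_starts Number of optimisation starts (>= 5 by default; start
#'   points are deterministic spacings of log-tau).
#' @return An object of class `popgenscan_hka`: list with `logL0`, `logL1`,
#'   `lrt`, `df`, `p`, `tau0`, `tau1`, and a per-locus tibble `estimates`
#'   (`theta` per site and `k`).
#' @export
fit_and_test <- function(loci, selected_ids = character(0), n_starts = 7) {
  if (!all(selected_ids %in% loci$locus_id))
    abort("selected_ids must be a subset of loci$locus_id.", class = "popgenscan_usage_error")
  selected <- loci$locus_id %in% selected_ids
  if (all(loci$S == 0) && all(loci$D == 0))
    abort("All counts are zero.", class = "popgenscan_degenerate_error")
  a1 <- vapply(loci$n, function(n) harmonic(n - 1L), numeric(1))
  maximise <- function(sel) {
    obj <- function(lt) -profile_loglik(exp(lt), loci, sel)
    starts <- log(c(0.05, 0.3, 1, 3, 10, 30, 100))[seq_len(max(5, n_starts))]
    starts <- starts[!is.na(starts)]
    fits <- lapply(starts, function(s0) {
      tryCatch(optim(s0, obj, method = "Brent", lower = log(1e-8), upper = log(1e8)),
               error = function(e) NULL)
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (!length(fits))
      abort("All optimisation starts failed.", class = "popgenscan_fit_error")
    best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
    list(tau = exp(best$par), logL = -best$value)
  }
  f0 <- maximise(rep(FALSE, nrow(loci)))
  if (!length(selected_ids)) {
    f1 <- f0
  } else {
    f1 <- maximise(selected)
  }
  lrt <- max(0, 2 * (f1$logL - f0$logL))
  df <- length(selected_ids)
  thL1 <- numeric(nrow(loci))
  thL1[!selected] <- (loci$S[!selected] + loci$D[!selected]) / (a1[!selected] + f1$tau + 1)
  thL1[selected] <- loci$D[selected] / (f1$tau + 1)
  k <- rep(1, nrow(loci))
  k[selected] <- ifelse(thL1[selected] > 0,
                        loci$S[selected] / (thL1[selected] * a1[selected]),
                        ifelse(loci$S[selected] == 0, 1, Inf))
  structure(list(
    logL0 = f0$logL, logL1 = f1$logL, lrt = lrt, df = df,
    p = if (df == 0) 1 else pchisq(lrt, df, lower.tail = FALSE),
    tau0 = f0$tau, tau1 = f1$tau,
    estimates = tibble(locus_id = loci$locus_id, selected = selected,
                       theta = thL1 / loci$L, k = k)
  ), class = "popgenscan_hka")
}

#' @export
print.popgenscan_hka <- function(x, ...) {
  cat(sprintf("mlHKA-style likelihood-ratio test\n  logL0 = %.3f, logL1 = %.3f\n  LRT = %.3f on %d df, p = %.4g\n  tau (selection model) = %.3f; %d selected loci\n",
              x$logL0, x$logL1, x$lrt, x$df, x$p, x$tau1, sum(x$estimates$selected)))
  invisible(x)
}

#' Simulate neutral locus-count panels
#'
#' Two generative nulls for calibration: `"coalescent"` draws `S` from a
#' Poisson mixed over the coalescent total tree length and `D` from a
#' Poisson mixed over an Exp(1) ancestral coalescence (variances match the
#' classic HKA moment assumptions), while `"poisson"` draws both counts
#' from the plain Poisson observation model of the mlHKA-style likelihood.
#'
#' @param n_loci Number of loci.
#' @param n Sample size per locus.
#' @param L Locus length (bp).
#' @param theta Per-site scaled mutation rate.
#' @param tau Scaled divergence time.
#' @param model `"coalescent"` or `"poisson"`.
#' @return A locus-count tibble.
#' @export
simulate_locus_panel <- function(n_loci, n = 14, L = 1500, theta = 0.003,
                                 tau = 4, model = c("coalescent", "poisson")) {
  model <- match.arg(model)
  thL <- theta * L
  a1 <- harmonic(n - 1L)
  S <- D <- integer(n_loci)
  for (i in seq_len(n_loci)) {
    if (model == "coalescent") {
      kk <- 2:n
      tlen <- sum(kk * rexp(length(kk), rate = kk * (kk - 1) / 2))
      S[i] <- rpois(1L, thL * tlen / 2)
      D[i] <- rpois(1L, thL * (tau + rexp(1L)))
    } else {
      S[i] <- rpois(1L, thL * a1)
      D[i] <- rpois(1L, thL * (tau + 1))
    }
  }
  tibble(locus_id = sprintf("locus%03d", seq_len(n_loci)),
         n = n, L = L, S = S, D = D)
}
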