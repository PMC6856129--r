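#' Kosambi map-function conversions
#'
#' Converts genetic map distance to recombination fraction under the Kosambi
#' map function, \eqn{r = \tanh(2d)/2} with `d` in Morgans (here taken in
#' centimorgans, so \eqn{r = \tanh(2d/100)/2}), and back via
#' `d = 25 ln((1 + 2r) / (1 - 2r))` cM. Kosambi's function accounts for
#' positive crossover interference; `r` approaches 0.5 as loci become
#' effectively unlinked (about 50 cM or more apart).
#'
#' @param d_cm genetic map distance in centimorgans (non-negative).
#' @return `kosambi_rf()`: recombination fraction in `[0, 0.5)`.
#' @examples
#' kosambi_rf(88.8129)  # ~0.4721, an effectively unlinked syntenic pair
#' kosambi_rf(11.9410)  # ~0.1172, a tightly linked pair
#' @export
kosambi_rf <- function(d_cm) {
  if (any(d_cm < 0)) {
    stop_kinstr("map distance must be non-negative",
                class = "kinstr_linkage_error")
  }
  0.5 * tanh(2 * d_cm / 100)
}

#' @rdname kosambi_rf
#' @param r recombination fraction in `[0, 0.5)`.
#' @return `kosambi_inverse()`: map distance in centimorgans.
#' @export
kosambi_inverse <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop_kinstr("recombination fraction must lie in [0, 0.5)",
                class = "kinstr_linkage_error")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Recombination fraction of a syntenic locus pair from map positions
#'
#' Computes the map distance between two same-chromosome loci as the
#' absolute difference of their cumulative genetic map positions and
#' converts it to a recombination fraction with [kosambi_rf()].
#'
#' @param loci a [kit_panel()] or a locus table (`locus`, `chromosome`,
#'   `map_position_cm`).
#' @param locus_a,locus_b locus names.
#' @return data.frame (one row, class `syntenic_pair`) with columns
#'   `locus_a`, `locus_b`, `chromosome`, `cm_a`, `cm_b`, `distance_cm`,
#'   `rf`, and `rf_4dp` (rounded half-up to 4 decimals, the conventional
#'   reporting precision).
#' @export
pair_rf_from_map <- function(loci, locus_a, locus_b) {
  tab <- as_locus_table(loci)
  pick <- function(nm) {
    i <- match(nm, tab$locus)
    if (is.na(i)) stop_kinstr("unknown locus: ", nm,
                              class = "kinstr_linkage_error")
    tab[i, ]
  }
  a <- pick(locus_a); b <- pick(locus_b)
  if (a$chromosome != b$chromosome) {
    stop_kinstr(locus_a, " and ", locus_b, " are on different chromosomes",
                class = "kinstr_linkage_error")
  }
  if (is.na(a$map_position_cm) || is.na(b$map_position_cm)) {
    stop_kinstr("both loci need map positions", class = "kinstr_linkage_error")
  }
  d <- abs(a$map_position_cm - b$map_position_cm)
  out <- data.frame(locus_a = locus_a, locus_b = locus_b,
                    chromosome = a$chromosome,
                    cm_a = a$map_position_cm, cm_b = b$map_position_cm,
                    distance_cm = d, rf = kosambi_rf(d),
                    rf_4dp = round_half_up(kosambi_rf(d), 4),
                    stringsAsFactors = FALSE)
  class(out) <- c("syntenic_pair", "data.frame")
  out
}

#' Enumerate syntenic locus pairs
#'
#' Lists every unordered pair of loci sharing a chromosome, the configuration
#' that raises independence concerns when multi-kit locus sets are combined
#' for kinship work. Pairs are sorted by chromosome then locus name; map
#' distance and Kosambi recombination fraction are filled in where both map
#' positions are known.
#'
#' @param loci a [kit_panel()] or locus table (see [combined_loci()] for the
#'   usual 38-locus input).
#' @param exclude locus names to drop before enumeration.
#' @param exclude_pairs character vector of `"A/B"` pairs to drop from the
#'   result (order-insensitive), for reproducing published tables that omit
#'   pairs whose recombination fraction is already established elsewhere.
#' @return data.frame with one row per syntenic pair: `chromosome`,
#'   `locus_a`, `locus_b`, `distance_cm`, `rf` (NA where unmapped).
#' @export
enumerate_syntenic_pairs <- function(loci, exclude = NULL,
                                     exclude_pairs = NULL) {
  tab <- as_locus_table(loci)
  tab <- tab[!tab$locus %in% exclude, ]
  out <- do.call(rbind, lapply(split(tab, tab$chromosome), function(ch) {
    if (nrow(ch) < 2) return(NULL)
    ch <- ch[order(ch$locus), ]
    idx <- combn(nrow(ch), 2)
    d <- abs(ch$map_position_cm[idx[1, ]] - ch$map_position_cm[idx[2, ]])
    data.frame(chromosome = ch$chromosome[1],
               locus_a = ch$locus[idx[1, ]], locus_b = ch$locus[idx[2, ]],
               distance_cm = d, rf = ifelse(is.na(d), NA, kosambi_rf(d)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(chromosome = character(), locus_a = character(),
                      locus_b = character(), distance_cm = numeric(),
                      rf = numeric(), stringsAsFactors = FALSE)
  }
  if (length(exclude_pairs)) {
    key <- function(a, b) {
      paste(pmin(a, b), pmax(a, b), sep = "/")
    }
    drop <- do.call(rbind, strsplit(exclude_pairs, "/", fixed = TRUE))
    out <- out[!key(out$locus_a, out$locus_b) %in% key(drop[, 1], drop[, 2]), ]
  }
  ord <- order(suppressWarnings(as.numeric(out$chromosome)), out$chromosome,
               out$locus_a, out$locus_b)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance threshold
#'
#' Per-test threshold `alpha / k` controlling the family-wise error rate
#' over `k` tests, plus the 3-decimal rounding used in reports.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param k number of tests (>= 1).
#' @return list with `threshold` (exact) and `threshold_3dp`.
#' @examples
#' bonferroni_threshold(0.05, 18)  # 0.00278, reported as 0.003
#' @export
bonferroni_threshold <- function(alpha, k) {
  stopifnot(alpha > 0, alpha < 1, k >= 1)
  list(threshold = alpha / k, threshold_3dp = round_half_up(alpha / k, 3))
}

## ---- two-locus genotype data -------------------------------------------
## internal representation: integer allele indices per locus plus genotype
## class ids; individuals with a no-call at either locus dropped pairwise.
two_locus_data <- function(g_a1, g_a2, g_b1, g_b2) {
  keep <- !(is.na(g_a1) | is.na(g_a2) | is.na(g_b1) | is.na(g_b2))
  g_a1 <- g_a1[keep]; g_a2 <- g_a2[keep]
  g_b1 <- g_b1[keep]; g_b2 <- g_b2[keep]
  alleles_a <- sort(unique(c(g_a1, g_a2)))
  alleles_b <- sort(unique(c(g_b1, g_b2)))
  a1 <- match(g_a1, alleles_a); a2 <- match(g_a2, alleles_a)
  b1 <- match(g_b1, alleles_b); b2 <- match(g_b2, alleles_b)
  ## unordered within locus
  sw <- a2 < a1; tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
  sw <- b2 < b1; tmp <- b1[sw]; b1[sw] <- b2[sw]; b2[sw] <- tmp
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       ka = length(alleles_a), kb = length(alleles_b),
       alleles_a = alleles_a, alleles_b = alleles_b, n = length(a1))
}

## allele frequencies per locus from a two_locus_data object
tl_allele_freqs <- function(d) {
  pa <- tabulate(c(d$a1, d$a2), d$ka) / (2 * d$n)
  pb <- tabulate(c(d$b1, d$b2), d$kb) / (2 * d$n)
  list(pa = pa, pb = pb)
}

## genotype-pair class table: unique (a1,a2,b1,b2) with counts and, per
## class, the compatible unordered haplotype pairs (indices into the
## ka*kb haplotype vector, h[a, b] at (b-1)*ka + a)
tl_classes <- function(d) {
  ## integer-coded genotype-pair classes (hot path: rebuilt per permutation)
  code <- (((d$a1 - 1L) * d$ka + (d$a2 - 1L)) * d$kb + (d$b1 - 1L)) *
    d$kb + d$b2
  cnt <- tabulate(code, nbins = d$ka * d$ka * d$kb * d$kb)
  nz <- which(cnt > 0L)
  z <- nz - 1L
  b2 <- z %% d$kb; z <- z %/% d$kb
  b1 <- z %% d$kb; z <- z %/% d$kb
  a2 <- z %% d$ka; a1 <- z %/% d$ka
  a1 <- a1 + 1L; a2 <- a2 + 1L; b1 <- b1 + 1L; b2 <- b2 + 1L
  hap <- function(a, b) (b - 1L) * d$ka + a
  ## phase 1: (a1,b1)+(a2,b2); phase 2: (a1,b2)+(a2,b1).
  ## identical for anything but double heterozygotes.
  h11 <- hap(a1, b1); h22 <- hap(a2, b2)
  h12 <- hap(a1, b2); h21 <- hap(a2, b1)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, count = cnt[nz],
       h11 = h11, h22 = h22, h12 = h12, h21 = h21,
       mult1 = 1 + (h11 != h22),
       dh = as.numeric(a1 != a2 & b1 != b2),
       idx = c(h11, h22, h12, h21))
}

## P(genotype class | haplotype freqs h): 2*h_x*h_y per unordered pair
## (h_x^2 if x == y), summed over compatible phases
tl_class_prob <- function(cls, h) {
  cls$mult1 * h[cls$h11] * h[cls$h22] +
    cls$dh * 2 * h[cls$h12] * h[cls$h21]
}

tl_loglik <- function(cls, h) {
  p <- tl_class_prob(cls, h)
  if (any(p <= 0)) return(-Inf)
  sum(cls$count * log(p))
}

## one EM run from starting haplotype frequencies h0
em_run <- function(cls, ka, kb, h0, tol, max_iter) {
  h <- h0
  ll <- tl_loglik(cls, h)
  n2 <- 2 * sum(cls$count)
  nh <- ka * kb
  for (it in seq_len(max_iter)) {
    ## E-step: split double heterozygotes by current phase odds
    w1 <- cls$mult1 * h[cls$h11] * h[cls$h22]
    w2 <- cls$dh * 2 * h[cls$h12] * h[cls$h21]
    tot <- w1 + w2
    f1 <- w1 / pmax(tot, .Machine$double.xmin)
    ## accumulate expected haplotype counts over (h11, h22, h12, h21)
    inc1 <- cls$count * f1
    inc2 <- cls$count * (1 - f1)
    rs <- rowsum(c(inc1, inc1, inc2, inc2), cls$idx)
    cnt <- numeric(nh)
    cnt[as.integer(rownames(rs))] <- rs[, 1]
    h_new <- cnt / n2
    ll_new <- tl_loglik(cls, h_new)
    h <- h_new
    if (is.finite(ll) && ll_new < ll - 1e-8) {
      stop_kinstr("EM log-likelihood decreased", class = "kinstr_em_error")
    }
    converged <- is.finite(ll) && (ll_new - ll) < tol
    ll <- ll_new
    if (converged) return(list(h = h, loglik = ll, iterations = it,
                               converged = TRUE))
  }
  list(h = h, loglik = ll, iterations = max_iter, converged = FALSE)
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies from unphased two-locus
#' genotypes. Only double heterozygotes are phase-ambiguous; the E-step
#' splits them between the two phase configurations in proportion to their
#' current haplotype-frequency products, and the M-step renormalises
#' expected haplotype counts. The first start is the linkage-equilibrium
#' point (products of observed allele frequencies); further restarts draw
#' random starting frequencies.
#'
#' @param genotypes data.frame with columns `a1`, `a2`, `b1`, `b2` (allele
#'   labels at locus A and B per individual; NA = no call, dropped
#'   pairwise).
#' @param restarts number of EM starting conditions (the conventional
#'   setting in population-genetics software is 2).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap per start.
#' @param seed integer seed for the random restarts.
#' @return list with `haplotypes` (data.frame `allele_a`, `allele_b`,
#'   `frequency`), `loglik`, `iterations`, `converged`, and `D` (the
#'   disequilibrium coefficient of the first allele pair,
#'   `h[1,1] - p_a1 * p_b1`).
#' @export
em_haplotype_freqs <- function(genotypes, restarts = 2, tol = 1e-8,
                               max_iter = 1000, seed = 1L) {
  d <- two_locus_data(genotypes$a1, genotypes$a2, genotypes$b1, genotypes$b2)
  if (d$n < 2) {
    stop_kinstr("need at least two individuals called at both loci",
                class = "kinstr_linkage_error")
  }
  cls <- tl_classes(d)
  fr <- tl_allele_freqs(d)
  best <- NULL
  set.seed(seed)
  for (s in seq_len(restarts)) {
    h0 <- if (s == 1) as.vector(outer(fr$pa, fr$pb)) else {
      x <- rgamma(d$ka * d$kb, 1); x / sum(x)
    }
    fit <- em_run(cls, d$ka, d$kb, h0, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    warning("EM did not converge in ", max_iter, " iterations")
  }
  hap <- expand.grid(allele_a = d$alleles_a, allele_b = d$alleles_b,
                     stringsAsFactors = FALSE)
  hap$frequency <- best$h
  list(haplotypes = hap, loglik = best$loglik,
       iterations = best$iterations, converged = best$converged,
       D = best$h[1] - fr$pa[1] * fr$pb[1])
}

#' Likelihood-ratio permutation test of linkage disequilibrium
#'
#' Tests non-random association between two loci from unphased genotypes.
#' The statistic is `G = 2 (logL_EM - logL_0)`, where `logL_EM` is the
#' maximised haplotype-frequency likelihood ([em_haplotype_freqs()]) and
#' `logL_0` the likelihood under linkage equilibrium (haplotype frequencies
#' equal to products of observed allele frequencies). Because the gametic
#' phase is unknown, the null distribution is obtained by permuting the
#' locus-B genotypes across individuals and recomputing `G`; the p-value is
#' `(1 + #{G_perm >= G_obs}) / (1 + n_permutations)`, which is never
#' exactly zero.
#'
#' @inheritParams em_haplotype_freqs
#' @param n_permutations number of genotype permutations.
#' @return list of class `ld_test` with `G`, `p_value`, `n_permutations`,
#'   `em_restarts`, `seed`, and `haplotypes` from the observed-data fit.
#' @export
ld_lr_test <- function(genotypes, n_permutations = 1000, restarts = 2,
                       seed = 1L, tol = 1e-8, max_iter = 1000) {
  d <- two_locus_data(genotypes$a1, genotypes$a2, genotypes$b1, genotypes$b2)
  if (d$n < 2) {
    stop_kinstr("need at least two individuals called at both loci",
                class = "kinstr_linkage_error")
  }
  if (d$ka < 2 || d$kb < 2) {
    return(structure(list(G = 0, p_value = 1,
                          n_permutations = n_permutations,
                          em_restarts = restarts, seed = seed,
                          haplotypes = NULL,
                          note = "monomorphic locus"), class = "ld_test"))
  }
  fr <- tl_allele_freqs(d)
  h0_vec <- as.vector(outer(fr$pa, fr$pb))
  g_stat <- function(dd, s) {
    cls <- tl_classes(dd)
    ll0 <- tl_loglik(cls, h0_vec)
    best <- -Inf
    for (r in seq_len(restarts)) {
      hstart <- if (r == 1) h0_vec else {
        x <- rgamma(dd$ka * dd$kb, 1); x / sum(x)
      }
      fit <- em_run(cls, dd$ka, dd$kb, hstart, tol, max_iter)
      if (fit$loglik > best) best <- fit$loglik
    }
    max(0, 2 * (best - ll0))
  }
  set.seed(seed)
  g_obs <- g_stat(d, seed)
  obs_fit <- em_haplotype_freqs(genotypes, restarts = restarts, tol = tol,
                                max_iter = max_iter, seed = seed)
  set.seed(derive_seed(seed, 1L))
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(d$n)
    dp <- d
    dp$b1 <- d$b1[idx]; dp$b2 <- d$b2[idx]
    if (g_stat(dp, b) >= g_obs - 1e-9) exceed <- exceed + 1L
  }
  structure(list(G = g_obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations, em_restarts = restarts,
                 seed = seed, haplotypes = obs_fit$haplotypes,
                 D = obs_fit$D),
            class = "ld_test")
}

#' @export
print.ld_test <- function(x, ...) {
  cat(sprintf("LD likelihood-ratio test: G = %.4f, p = %.4g (%d permutations)\n",
              x$G, x$p_value, x$n_permutations))
  invisible(x)
}
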