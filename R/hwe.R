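#' Genotype count array for one locus
#'
#' Collapses diploid genotypes at one locus into the symmetric count table
#' `n_ij` (i <= j) that the exact Hardy-Weinberg test conditions on, along
#' with its margins: allele counts `m_i = 2 n_ii + sum_{j != i} n_ij` and
#' the heterozygote total.
#'
#' @param profiles a `str_profiles` data.frame, or `NULL` if `counts` is
#'   given directly.
#' @param locus locus name (when building from profiles).
#' @param counts alternatively, a symmetric k x k genotype count matrix
#'   (only the lower triangle is read).
#' @param alleles optional allele labels for `counts` rows/columns.
#' @return list of class `genotype_array`: `counts` (k x k symmetric
#'   matrix), `alleles`, `k`, `N`, `m` (allele counts), `n_het`.
#' @export
genotype_array <- function(profiles = NULL, locus = NULL, counts = NULL,
                           alleles = NULL) {
  if (is.null(counts)) {
    g <- profiles[profiles$marker == locus & !is.na(profiles$allele1), ]
    if (!nrow(g)) {
      stop_kinstr("no called genotypes at ", locus,
                  class = "kinstr_hwe_error")
    }
    alleles <- unique(c(g$allele1, g$allele2))
    alleles <- alleles[order_alleles(alleles)]
    k <- length(alleles)
    counts <- matrix(0L, k, k, dimnames = list(alleles, alleles))
    i <- match(g$allele1, alleles)
    j <- match(g$allele2, alleles)
    lo <- pmax(i, j); hi <- pmin(i, j)
    for (r in seq_along(lo)) {
      counts[lo[r], hi[r]] <- counts[lo[r], hi[r]] + 1L
    }
    counts[upper.tri(counts)] <- t(counts)[upper.tri(counts)]
  } else {
    counts <- as.matrix(counts)
    k <- nrow(counts)
    counts[upper.tri(counts)] <- t(counts)[upper.tri(counts)]
    alleles <- alleles %||% rownames(counts) %||% as.character(seq_len(k))
    dimnames(counts) <- list(alleles, alleles)
  }
  if (any(counts < 0)) {
    stop_kinstr("genotype counts must be non-negative",
                class = "kinstr_hwe_error")
  }
  storage.mode(counts) <- "integer"
  low <- counts
  low[upper.tri(low)] <- 0L
  N <- sum(low)
  m <- vapply(seq_len(nrow(counts)), function(i) {
    2L * counts[i, i] + sum(counts[i, -i])
  }, numeric(1))
  names(m) <- alleles
  structure(list(counts = counts, alleles = alleles, k = nrow(counts),
                 N = N, m = m, n_het = sum(low) - sum(diag(counts))),
            class = "genotype_array")
}

#' Conditional probability of a genotype table
#'
#' Probability of the genotype count table given its allele counts under
#' Hardy-Weinberg proportions:
#' `P = N! / prod n_ij! * 2^n_het * prod m_i! / (2N)!`.
#' Evaluated through log-factorials.
#'
#' @param array a [genotype_array()].
#' @param log return the log probability.
#' @return probability in `(0, 1]` (or its log).
#' @export
table_probability <- function(array, log = FALSE) {
  lo <- array$counts
  lo[upper.tri(lo)] <- 0
  lp <- lfactorial(array$N) - sum(lfactorial(lo[lower.tri(lo, diag = TRUE)])) +
    array$n_het * base::log(2) + sum(lfactorial(array$m)) -
    lfactorial(2 * array$N)
  if (log) lp else exp(lp)
}

## enumerate all genotype tables with the given allele-count margins,
## calling fn(lowmat, logP) on each; cap guards against state-space blowup
enumerate_tables <- function(m, cap = 1e6, fn) {
  k <- length(m)
  cells <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 2], cells[, 1]), , drop = FALSE]
  n_seen <- 0L
  low <- matrix(0L, k, k)
  N <- sum(m) / 2
  ## per-table log P = const - sum lfact(n_ij) + n_het log 2
  lp_const <- lfactorial(N) + sum(lfactorial(m)) - lfactorial(2 * N)
  diag_idx <- which(cells[, 1] == cells[, 2])
  recurse <- function(idx, resid) {
    if (idx > nrow(cells)) {
      if (any(resid != 0)) return(invisible())
      n_seen <<- n_seen + 1L
      if (n_seen > cap) {
        stop_kinstr("more than ", cap, " tables with these margins",
                    class = "kinstr_hwe_error")
      }
      vals <- low[cells]
      n_het <- N - sum(vals[diag_idx])
      lp <- lp_const - sum(lfactorial(vals)) + n_het * base::log(2)
      fn(low, lp)
      return(invisible())
    }
    i <- cells[idx, 1]; j <- cells[idx, 2]
    max_c <- if (i == j) resid[i] %/% 2 else min(resid[i], resid[j])
    ## last chance to zero out column j's residual?
    last_in_col <- idx == nrow(cells) || cells[idx + 1, 2] > j
    for (c in 0:max_c) {
      low[i, j] <<- c
      r2 <- resid
      r2[i] <- r2[i] - c
      r2[j] <- r2[j] - c
      if (!last_in_col || r2[j] == 0) recurse(idx + 1, r2)
    }
    low[i, j] <<- 0L
    invisible()
  }
  recurse(1L, as.integer(m))
  n_seen
}

#' Exhaustive exact Hardy-Weinberg test
#'
#' Enumerates every genotype table with the observed allele counts and sums
#' the conditional probabilities of tables no more probable than the
#' observed one: `p = sum P(T) over {T : P(T) <= P(obs)}` (ties included,
#' with a 1e-12 relative tolerance). Feasible for small tables only; serves
#' as the exact oracle for the Markov-chain test.
#'
#' @param array a [genotype_array()].
#' @param cap maximum number of tables to enumerate before aborting.
#' @return list: `p_value`, `n_tables`, `total_probability` (sums to 1 over
#'   the enumeration, a built-in self-check).
#' @export
enumerate_exact_test <- function(array, cap = 1e6) {
  lp_obs <- table_probability(array, log = TRUE)
  acc <- new.env()
  acc$p <- 0; acc$tot <- 0
  n <- enumerate_tables(array$m, cap = cap, fn = function(low, lp) {
    acc$tot <- acc$tot + exp(lp)
    if (lp <= lp_obs + 1e-12 * abs(lp_obs) + 1e-12) acc$p <- acc$p + exp(lp)
  })
  list(p_value = min(acc$p, 1), n_tables = n, total_probability = acc$tot)
}

#' Markov-chain exact Hardy-Weinberg test
#'
#' Estimates the exact-test p-value by a Guo-Thompson Markov chain over
#' genotype tables with the observed allele counts: degree-2 switch
#' proposals exchanging one allele between two genotype cells, Metropolis
#' acceptance `min(1, P(new)/P(old))`. After the dememorization phase the
#' p-value is the fraction of visited tables whose conditional probability
#' does not exceed the observed table's; a Monte-Carlo standard error is
#' estimated from batch means. A p-value of exactly zero (no visited table
#' at or below the observed probability) is floored at `1/steps` and
#' flagged, since the chain can only bound it above by its resolution.
#'
#' @param array a [genotype_array()].
#' @param steps Markov chain steps counted towards the estimate.
#' @param dememorization burn-in steps discarded first.
#' @param seed integer seed.
#' @return list of class `hwe_result`: `p_value`, `se`, `chain_steps`,
#'   `dememorization_steps`, `seed`, `floored` (TRUE if the zero-count
#'   floor was applied).
#' @export
gt_exact_test <- function(array, steps = 1e6, dememorization = 1e5,
                          seed = 1L) {
  if (array$k < 2) {
    warning("monomorphic locus: p = 1")
    return(structure(list(p_value = 1, se = 0, chain_steps = 0,
                          dememorization_steps = 0, seed = seed,
                          floored = FALSE), class = "hwe_result"))
  }
  if (array$N < 2) {
    stop_kinstr("need N >= 2", class = "kinstr_hwe_error")
  }
  set.seed(seed)
  res <- .gt_chain_cpp(array$counts, as.integer(steps),
                       as.integer(dememorization))
  p <- res$p
  floored <- p == 0
  if (floored) p <- 1 / steps
  structure(list(p_value = p, se = res$se, chain_steps = as.integer(steps),
                 dememorization_steps = as.integer(dememorization),
                 seed = seed, floored = floored),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("exact HWE test (MCMC): p = %.4g +/- %.2g (%g steps)%s\n",
              x$p_value, x$se, x$chain_steps,
              if (x$floored) " [zero count floored at 1/steps]" else ""))
  invisible(x)
}

#' Exact HWE test for every locus of a profile set
#'
#' @param profiles a `str_profiles` data.frame.
#' @param loci loci to test (default all).
#' @inheritParams gt_exact_test
#' @return data.frame: `locus`, `p_value`, `se`, `k`, `N`.
#' @export
hwe_test_all <- function(profiles, loci = NULL, steps = 1e6,
                         dememorization = 1e5, seed = 1L) {
  loci <- loci %||% sort(unique(profiles$marker))
  out <- lapply(seq_along(loci), function(i) {
    arr <- genotype_array(profiles, loci[i])
    r <- gt_exact_test(arr, steps = steps, dememorization = dememorization,
                       seed = derive_seed(seed, i))
    data.frame(locus = loci[i], p_value = r$p_value, se = r$se,
               k = arr$k, N = arr$N, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
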