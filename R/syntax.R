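# Microstate syntax: observed vs expected transition probabilities, the
# randomized chi-square test of sequence randomness, and group-level paired
# tests per transition with FDR control.

run_labels_of <- function(runs) {
  if (inherits(runs, "ms_runs") || is.data.frame(runs)) runs$label
  else as.integer(runs)
}

#' Observed transition probability matrix
#'
#' Counts consecutive run-label pairs (self-transitions cannot occur by
#' construction of a run sequence) and row-normalises. Rows whose label has
#' no outgoing transition are left as zeros and reported via the
#' `"empty_rows"` attribute.
#'
#' @param runs A `ms_runs` tibble from [segment_runs()] (or an integer
#'   run-label vector).
#' @param k Number of maps.
#' @return A k x k row-stochastic matrix with zero diagonal.
#' @export
observed_transitions <- function(runs, k) {
  lab <- run_labels_of(runs)
  if (length(lab) < 2L) stop("need at least two runs", call. = FALSE)
  counts <- transition_counts(lab, k)
  rs <- rowSums(counts)
  out <- counts / ifelse(rs == 0, 1, rs)
  attr(out, "empty_rows") <- which(rs == 0)
  out
}

transition_counts <- function(lab, k) {
  a <- lab[-length(lab)]
  b <- lab[-1L]
  matrix(tabulate(a + k * (b - 1L), nbins = k * k), k, k)
}

#' Expected transition probability matrix under label-share independence
#'
#' With `q(X)` the share of runs labelled X, the chance expectation for a
#' transition A -> B (A != B) is `q(B) / (1 - q(A))`: the next run is drawn
#' from the label distribution conditioned on differing from the current
#' label. Rows sum to one.
#'
#' @inheritParams observed_transitions
#' @return A k x k row-stochastic matrix with zero diagonal.
#' @export
expected_transitions <- function(runs, k) {
  lab <- run_labels_of(runs)
  if (length(lab) < 2L) stop("need at least two runs", call. = FALSE)
  q <- tabulate(lab, nbins = k) / length(lab)
  if (any(q == 1)) stop("single-label sequence has no expected transitions",
                        call. = FALSE)
  E <- outer(1 - q, q, function(d, n) n / d)
  diag(E) <- 0
  E
}

# chi-square statistic on transition COUNTS with expectations from run-label
# shares; self-transitions are structurally excluded.
syntax_chisq_stat <- function(lab, k) {
  O <- transition_counts(lab, k)
  q <- tabulate(lab, nbins = k) / length(lab)
  rowtot <- rowSums(O)
  E <- outer(seq_len(k), seq_len(k), function(a, b) {
    rowtot[a] * q[b] / (1 - q[a])
  })
  diag(E) <- 0
  off <- is.finite(E) & E > 0
  sum((O[off] - E[off])^2 / E[off])
}

# shuffle run labels preserving the multiset, with no adjacent equal labels;
# adjacent duplicates are repaired by local redraws (swaps with random
# positions), falling back to a fresh permutation if repair stalls.
shuffle_no_adjacent <- function(lab) {
  n <- length(lab)
  swap_ok <- function(x, b, j) {
    vb <- x[b]; vj <- x[j]
    if (vb == vj) return(FALSE)
    # placing vj at b and vb at j must not create new adjacent repeats
    nb <- c(if (b > 1L && b - 1L != j) x[b - 1L],
            if (b < n && b + 1L != j) x[b + 1L])
    nj <- c(if (j > 1L && j - 1L != b) x[j - 1L],
            if (j < n && j + 1L != b) x[j + 1L])
    !any(nb == vj) && !any(nj == vb)
  }
  for (attempt in seq_len(5L)) {
    x <- lab[sample.int(n)]
    for (rep in seq_len(20L)) {
      bad <- which(x[-1L] == x[-n]) + 1L
      if (length(bad) == 0L) return(x)
      # element-wise targeted swaps preserve the multiset exactly
      for (b in bad) {
        for (try in seq_len(30L)) {
          j <- sample.int(n, 1L)
          if (swap_ok(x, b, j)) {
            tmp <- x[b]; x[b] <- x[j]; x[j] <- tmp
            break
          }
        }
      }
    }
  }
  # near-infeasible multisets (one label close to half the runs): build the
  # arrangement sequentially, sampling each label proportionally to its
  # remaining count among the choices that keep completion feasible
  shuffle_sequential(lab)
}

shuffle_sequential <- function(lab) {
  n <- length(lab)
  k <- max(lab)
  cnt <- tabulate(lab, k)
  out <- integer(n)
  prev <- 0L
  for (i in seq_len(n)) {
    rem2 <- n - i                       # slots left after this one
    cl <- (rem2 + 1L) %/% 2L            # max feasible count afterwards
    cand <- which(cnt > 0L)
    cand <- cand[cand != prev]
    if (length(cand) == 0L) cand <- which(cnt > 0L)  # infeasible: repeat
    ok <- vapply(cand, function(l) {
      c2 <- cnt
      c2[l] <- c2[l] - 1L
      max(c2) <= cl && !(c2[l] == cl && rem2 %% 2L == 1L)
    }, logical(1))
    if (any(ok)) cand <- cand[ok]
    l <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), 1L, prob = cnt[cand])]
    out[i] <- l
    cnt[l] <- cnt[l] - 1L
    prev <- l
  }
  out
}

#' Randomized chi-square test of microstate syntax randomness
#'
#' Tests whether the order of the run-label sequence departs from chance.
#' The statistic is the chi-square distance between observed and expected
#' transition counts (expectations from run-label shares, self-transitions
#' structurally excluded). The null distribution is built by shuffling the
#' run labels (preserving the label multiset and the no-adjacent-repeat
#' structure of a run sequence); the p-value uses the add-one permutation
#' estimator `(1 + #{null >= observed}) / (1 + n_perm)`, whose floor at 5000
#' permutations is 1/5001, i.e. just below 0.0002.
#'
#' @inheritParams observed_transitions
#' @param n_perm Number of random shuffles (default 5000).
#' @param seed Integer seed.
#' @return A list: `chi2`, `p`, `n_perm`, `n_runs`.
#' @export
syntax_chisq_test <- function(runs, k, n_perm = 5000L, seed = 1L) {
  lab <- run_labels_of(runs)
  if (length(lab) < 10L) stop("need at least 10 runs", call. = FALSE)
  if (n_perm < 100L) stop("need n_perm >= 100", call. = FALSE)
  if (length(unique(lab)) < 2L) stop("degenerate single-label sequence",
                                     call. = FALSE)
  obs <- syntax_chisq_stat(lab, k)
  exceed <- 0L
  with_local_seed(seed, {
    for (i in seq_len(n_perm)) {
      null_stat <- syntax_chisq_stat(shuffle_no_adjacent(lab), k)
      if (null_stat >= obs) exceed <- exceed + 1L
    }
  })
  list(chi2 = obs, p = (1 + exceed) / (1 + n_perm),
       n_perm = as.integer(n_perm), n_runs = length(lab))
}

#' Group-level paired tests of observed vs expected transitions
#'
#' For each of the k(k-1) ordered transitions, a paired two-sided t-test of
#' the per-epoch differences (observed - expected probability) against zero,
#' Benjamini-Hochberg adjusted across the k(k-1) tests within the group.
#' The direction flag says whether a transition occurs more or less often
#' than chance; the two significance thresholds (0.05 and 0.1) mirror the
#' usual strong/weak annotation of transition graphs.
#'
#' @param per_epoch_stats A list with one element per epoch, each a list
#'   holding matrices `observed` and `expected` (aligned to a common map
#'   order), e.g. built from [observed_transitions()] and
#'   [expected_transitions()].
#' @param alpha Strong significance threshold (default 0.05).
#' @param alpha_weak Weak threshold (default 0.1).
#' @return A tibble with one row per ordered transition: `from`, `to`,
#'   `mean_diff`, `direction` ("more"/"less"), `p`, `p_fdr`, `sig`
#'   ("strong"/"weak"/"ns"), `n_epochs`, `degenerate` (TRUE when the paired
#'   differences had zero variance and the test is undefined).
#' @export
transition_group_test <- function(per_epoch_stats, alpha = 0.05,
                                  alpha_weak = 0.1) {
  n_ep <- length(per_epoch_stats)
  if (n_ep < 3L) stop("need at least 3 epochs per group", call. = FALSE)
  k <- nrow(per_epoch_stats[[1]]$observed)
  cells <- expand.grid(from = seq_len(k), to = seq_len(k))
  cells <- cells[cells$from != cells$to, ]
  res <- purrr::pmap_dfr(cells, function(from, to) {
    d <- vapply(per_epoch_stats, function(s) {
      s$observed[from, to] - s$expected[from, to]
    }, numeric(1))
    degen <- stats::sd(d) == 0
    p <- if (degen) NA_real_ else stats::t.test(d)$p.value
    tibble::tibble(from = from, to = to, mean_diff = mean(d),
                   direction = ifelse(mean(d) >= 0, "more", "less"),
                   p = p, degenerate = degen)
  })
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res$sig <- dplyr::case_when(
    is.na(res$p_fdr) ~ "ns",
    res$p_fdr < alpha ~ "strong",
    res$p_fdr < alpha_weak ~ "weak",
    TRUE ~ "ns"
  )
  res$n_epochs <- n_ep
  dplyr::arrange(res, .data$from, .data$to)
}
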