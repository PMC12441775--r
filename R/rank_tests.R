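#' Within-block Friedman ranks
#'
#' Ranks responses within each block (experimental field) from 1 to k;
#' ties receive mid-ranks, so every row sums to `k(k+1)/2`.
#'
#' @param m Numeric matrix, rows = blocks, columns = treatments; complete
#'   (no missing cells).
#' @return Matrix of the same shape holding within-block ranks.
#' @examples
#' friedman_ranks(rbind(c(1.07, 1.37, 1.40, 1.53)))
#' @export
friedman_ranks <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 1L || ncol(m) < 2L) {
    stop("need at least 1 block and 2 treatments", call. = FALSE)
  }
  miss <- which(apply(m, 1L, anyNA))
  if (length(miss)) {
    stop("missing cell(s) in block(s) ", paste(miss, collapse = ", "),
         "; the exact test needs a complete block design", call. = FALSE)
  }
  r <- t(apply(m, 1L, rank))
  dimnames(r) <- dimnames(m)
  r
}

# pmf of the rank difference r_i - r_j between two fixed treatments in one
# block of k untied ranks: P(d) = (k - |d|) / (k (k - 1)), d in
# {-(k-1), ..., -1, 1, ..., k-1}.  Returned over the full integer support
# -(k-1):(k-1) including P(0) = 0.
single_block_diff_pmf <- function(k) {
  d <- -(k - 1):(k - 1)
  p <- (k - abs(d)) / (k * (k - 1))
  p[d == 0] <- 0
  p
}

# n-fold convolution of the single-block difference pmf; support
# -n(k-1):n(k-1).  Cached per (n, k) within a session.
pair_diff_null <- local({
  cache <- new.env(parent = emptyenv())
  function(n, k) {
    key <- paste(n, k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p1 <- single_block_diff_pmf(k)
    p <- p1
    for (i in seq_len(n - 1L)) {
      # direct convolution keeps full support and exact symmetry
      m <- outer(p, p1)
      s <- row(m) + col(m)
      p <- as.vector(tapply(as.vector(m), as.vector(s), sum))
    }
    cache[[key]] <- p
    p
  }
})

#' Exact two-sided p-value for a pairwise Friedman rank-sum difference
#'
#' Under the null hypothesis that each block's joint ranking of k
#' treatments is uniform over the k! permutations (blocks independent),
#' the difference D between the rank sums of two fixed treatments over n
#' blocks has the n-fold convolution of the single-block difference
#' distribution `P(d) = (k - |d|)/(k (k - 1))`.  The exact two-sided
#' p-value is `P(|D*| >= |D|)`.
#'
#' @param D Observed rank-sum difference (integer for untied ranks).
#' @param n Number of blocks.
#' @param k Number of treatments.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' exact_pair_pvalue(4, n = 2, k = 3)
#' @export
exact_pair_pvalue <- function(D, n, k) {
  if (n < 1L || k < 2L) stop("need n >= 1 blocks, k >= 2 treatments",
                             call. = FALSE)
  if (abs(D) > n * (k - 1)) {
    stop("|D| cannot exceed n(k-1) = ", n * (k - 1), call. = FALSE)
  }
  if (abs(D - round(D)) > 1e-8) {
    stop("non-integer D: the exact null assumes tie-free ranks; ",
         "use the Monte-Carlo fallback for tied data", call. = FALSE)
  }
  pmf <- pair_diff_null(n, k)
  supp <- -(n * (k - 1)):(n * (k - 1))
  sum(pmf[abs(supp) >= abs(round(D))])
}

# Monte-Carlo two-sided p-values for all pairs when blocks contain ties:
# each block's observed (mid-)ranks are randomly permuted across
# treatments, preserving the tie pattern.
mc_pair_pvalues <- function(r, nsim = 1e5) {
  n <- nrow(r); k <- ncol(r)
  pairs <- utils::combn(k, 2L)
  obs <- apply(pairs, 2L, function(ij) {
    sum(r[, ij[1L]]) - sum(r[, ij[2L]])
  })
  exceed <- integer(ncol(pairs))
  for (s in seq_len(nsim)) {
    rp <- t(apply(r, 1L, sample))
    cs <- colSums(rp)
    dstar <- cs[pairs[1L, ]] - cs[pairs[2L, ]]
    exceed <- exceed + (abs(dstar) >= abs(obs) - 1e-9)
  }
  (exceed + 1) / (nsim + 1)
}

# Compact letter display by insert-and-absorb: start from one set holding
# all treatments; for every significant pair split each set containing
# both; absorb sets contained in others.  Treatments sharing a letter are
# exactly the pairs not declared significant.
insert_absorb_letters <- function(treatments, sig_pairs) {
  sets <- list(treatments)
  if (nrow(sig_pairs)) {
    for (row in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[row, 1L]; j <- sig_pairs[row, 2L]
      nxt <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          nxt <- c(nxt, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          nxt <- c(nxt, list(s))
        }
      }
      nxt <- nxt[lengths(nxt) > 0L]
      keep <- rep(TRUE, length(nxt))
      for (u in seq_along(nxt)) {
        for (v in seq_along(nxt)) {
          if (u != v && keep[v] &&
              all(nxt[[u]] %in% nxt[[v]]) &&
              (length(nxt[[u]]) < length(nxt[[v]]) || u > v)) {
            keep[u] <- FALSE
            break
          }
        }
      }
      sets <- nxt[keep]
    }
  }
  # order letter sets by first (highest-ranked) member for determinism
  ord <- order(vapply(sets, function(s) min(match(s, treatments)), 1))
  sets <- sets[ord]
  letters_out <- setNames(rep("", length(treatments)), treatments)
  for (idx in seq_along(sets)) {
    lab <- letters[(idx - 1L) %% 26L + 1L]
    if (idx > 26L) lab <- paste0(lab, (idx - 1L) %/% 26L)
    for (tr in sets[[idx]]) {
      letters_out[tr] <- paste0(letters_out[tr], lab)
    }
  }
  letters_out
}

#' Exact all-pairs comparisons of Friedman-type ranked data
#'
#' Ranks responses within blocks, tests every unordered treatment pair
#' with the exact convolution null of [exact_pair_pvalue()] (no
#' multiplicity adjustment), and summarizes homogeneous subgroups as a
#' compact letter display at level `alpha`.  When any block contains tied
#' responses the exact tie-free null does not apply and a seeded
#' Monte-Carlo permutation p-value is used instead
#' (`method = "approximate"`).
#'
#' @param m Numeric matrix, rows = blocks (fields), columns = treatments.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param nsim Monte-Carlo resamples used for tied data.
#' @param seed Seed for the Monte-Carlo fallback (ignored for exact runs).
#' @return List with elements
#'   `pairs` (tibble: `treatment_i`, `treatment_j`, `D`, `p`, `method`),
#'   `letters` (tibble: `treatment`, `mean_rank`, `letters`),
#'   `n`, `k`, `alpha`, `tied`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(60), 15, 4,
#'             dimnames = list(NULL, c("DSSstd", "DSSred", "AdvLoc", "AdvSer")))
#' all_pairs_test(m)$letters
#' @export
all_pairs_test <- function(m, alpha = 0.05, nsim = 1e5, seed = 1L) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
  r <- friedman_ranks(m)
  n <- nrow(r); k <- ncol(r)
  if (n < 2L) stop("need at least 2 blocks for a pairwise test",
                   call. = FALSE)
  tied <- any(apply(m, 1L, anyDuplicated) > 0L)
  pairs <- utils::combn(k, 2L)
  D <- apply(pairs, 2L, function(ij) sum(r[, ij[1L]]) - sum(r[, ij[2L]]))
  if (tied) {
    p <- withr::with_seed(seed, mc_pair_pvalues(r, nsim = nsim))
    method <- "approximate"
  } else {
    p <- vapply(D, exact_pair_pvalue, numeric(1), n = n, k = k)
    method <- "exact"
  }
  trt <- colnames(m)
  mean_rank <- colMeans(r)
  # letter order follows decreasing mean rank
  ord_trt <- trt[order(-mean_rank)]
  sig <- cbind(trt[pairs[1L, ]], trt[pairs[2L, ]])[p <= alpha, ,
                                                   drop = FALSE]
  letter_str <- insert_absorb_letters(ord_trt, sig)
  list(
    pairs = tibble::tibble(
      treatment_i = trt[pairs[1L, ]],
      treatment_j = trt[pairs[2L, ]],
      D = unname(D), p = unname(p), method = method),
    letters = tibble::tibble(
      treatment = trt,
      mean_rank = unname(mean_rank),
      letters = unname(letter_str[trt])),
    n = n, k = k, alpha = alpha, tied = tied)
}
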