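# GC-composition-preserving pair correlation function
#   eta_ab(x) = (N_ab(x) - <N_ab(x)>_rand) / L
# where N_ab(x) counts pairs (position i of type a, position i+x of type b)
# and the null reshuffles each sequence, keeping its base composition (hence
# GC-content) intact. The default null averages over 100 random shuffles; an
# exact mode replaces sampling by the closed-form permutation expectation.

# counts of a->b pairs at each separation in x_values, N positions skipped
.pair_counts <- function(chars, alpha, beta, x_values) {
  L <- length(chars)
  vapply(x_values, function(x) {
    if (x < 1L || x > L - 1L) return(NA_real_)
    sum(chars[seq_len(L - x)] == alpha & chars[seq_len(L - x) + x] == beta)
  }, numeric(1))
}

# closed-form permutation expectation of N_ab(x): non-N letters are permuted
# uniformly over the non-N positions, N positions stay fixed.
.pair_expectation_exact <- function(chars, alpha, beta, x_values) {
  L <- length(chars)
  non_n <- chars != "N"
  m <- sum(non_n)
  n_a <- sum(chars == alpha)
  n_b <- sum(chars == beta)
  vapply(x_values, function(x) {
    if (x < 1L || x > L - 1L) return(NA_real_)
    v <- sum(non_n[seq_len(L - x)] & non_n[seq_len(L - x) + x])
    if (m < 2L || v == 0L) return(0)
    if (alpha == beta) v * n_a * (n_a - 1) / (m * (m - 1))
    else v * n_a * n_b / (m * (m - 1))
  }, numeric(1))
}

.pair_expectation_shuffle <- function(chars, alpha, beta, x_values, n_shuffles) {
  non_n <- which(chars != "N")
  letters <- chars[non_n]
  acc <- numeric(length(x_values))
  for (r in seq_len(n_shuffles)) {
    w <- chars
    w[non_n] <- letters[sample.int(length(non_n))]
    acc <- acc + .pair_counts(w, alpha, beta, x_values)
  }
  acc / n_shuffles
}

#' Count nucleotide pairs at a fixed separation
#'
#' Number of positions `i` with `seq[i] == alpha` and `seq[i + x] == beta`.
#' Positions holding `N` never match.
#'
#' @param seq A single nucleotide string.
#' @param alpha,beta Single nucleotides (`A`, `C`, `G`, or `T`).
#' @param x Separation(s) in bp, `1 <= x <= nchar(seq) - 1`.
#' @return Integer-valued count(s), one per element of `x`.
#' @export
pair_count <- function(seq, alpha, beta, x) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  stopifnot(all(x >= 1L), all(x <= length(chars) - 1L))
  .pair_counts(chars, alpha, beta, x)
}

#' Pair correlation of a single sequence against its shuffled null
#'
#' `eta_ab(x) = (N_ab(x) - <N_ab(x)>_rand) / L`, with the null obtained by
#' random reshuffling of the sequence (preserving its base composition; `N`
#' positions stay in place and only non-`N` letters are permuted). In
#' `"shuffle"` mode the null mean is estimated from `n_shuffles` random
#' realizations; `"exact"` mode uses the closed-form permutation expectation
#' `E[N_ab(x)] = V(x) n_a n_b / (M (M - 1))` (`n_a (n_a - 1)` when
#' `alpha == beta`), where `M` is the number of non-`N` positions and `V(x)`
#' the number of position pairs at separation `x` with both ends non-`N`.
#'
#' @inheritParams pair_count
#' @param n_shuffles Number of random shuffles for `"shuffle"` mode.
#' @param seed Optional integer seed for the shuffles.
#' @param method `"shuffle"` (literal randomization, the default) or
#'   `"exact"` (closed-form null mean).
#' @return Numeric vector of eta values, one per element of `x`.
#' @export
eta <- function(seq, alpha, beta, x, n_shuffles = 100L, seed = NULL,
                method = c("shuffle", "exact")) {
  method <- match.arg(method)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  stopifnot(all(x >= 1L), all(x <= L - 1L))
  obs <- .pair_counts(chars, alpha, beta, x)
  e <- if (method == "exact") {
    .pair_expectation_exact(chars, alpha, beta, x)
  } else {
    .with_seed(seed, .pair_expectation_shuffle(chars, alpha, beta, x, n_shuffles))
  }
  (obs - e) / L
}

#' Mean pair-correlation profile of a sequence set
#'
#' Computes per-sequence `eta_ab(x)` for `x = 1..x_max` and averages over the
#' set with equal per-sequence weight. The uncertainty is the standard
#' deviation across `n_subgroups` randomly assigned, equally sized subgroups
#' of sequences (error bars in figures span one standard deviation each
#' side). Each sequence uses its own RNG stream derived from `seed`, so the
#' result does not depend on sequence order.
#'
#' @param seqs Character vector of sequences (all the same length, typically
#'   100 bp); at least `n_subgroups` of them.
#' @param alpha,beta Single nucleotides.
#' @param x_max Maximum separation; profile covers `1..x_max`.
#' @param n_shuffles Shuffles per sequence in `"shuffle"` mode.
#' @param n_subgroups Number of subgroups for the error estimate.
#' @param seed Integer seed (shuffles and subgroup assignment).
#' @param method `"shuffle"` or `"exact"` (see [eta()]).
#' @return A `correlation_profile`: list with `alpha`, `beta`, `x`, `eta`,
#'   `stderr`, `n_sequences`, `n_shuffles`, `L`, `method`.
#' @export
mean_profile <- function(seqs, alpha, beta, x_max = 30L, n_shuffles = 100L,
                         n_subgroups = 10L, seed = 1L,
                         method = c("shuffle", "exact")) {
  method <- match.arg(method)
  n <- length(seqs)
  if (n < n_subgroups) stop("need at least n_subgroups sequences")
  x <- seq_len(x_max)
  per_seq <- vapply(seq_len(n), function(i) {
    eta(seqs[i], alpha, beta, x, n_shuffles = n_shuffles,
        seed = if (method == "shuffle") seed + i else NULL, method = method)
  }, numeric(x_max))
  per_seq <- matrix(per_seq, nrow = x_max)
  grp <- .with_seed(seed, sample(rep_len(seq_len(n_subgroups), n)))
  grp_means <- vapply(seq_len(n_subgroups), function(g) {
    rowMeans(per_seq[, grp == g, drop = FALSE])
  }, numeric(x_max))
  structure(
    list(alpha = alpha, beta = beta, x = x,
         eta = rowMeans(per_seq),
         stderr = apply(matrix(grp_means, nrow = x_max), 1L, stats::sd),
         n_sequences = n, n_shuffles = n_shuffles,
         L = nchar(seqs[1L]), method = method),
    class = "correlation_profile"
  )
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("correlation_profile: eta_%s%s(x), x=1..%d, %d sequences (%s null)\n",
              x$alpha, x$beta, max(x$x), x$n_sequences, x$method))
  peak_x <- x$x[which.max(abs(x$eta))]
  cat(sprintf("largest |eta| at x=%d: %.5f (stderr %.5f)\n",
              peak_x, x$eta[peak_x], x$stderr[peak_x]))
  invisible(x)
}

#' @export
as.data.frame.correlation_profile <- function(x, ...) {
  data.frame(alpha = x$alpha, beta = x$beta, x = x$x, eta = x$eta,
             stderr = x$stderr, stringsAsFactors = FALSE)
}

#' Homopolymer-tract enrichment panel
#'
#' Computes `eta_AA(1)`, `eta_TT(1)`, `eta_CC(1)`, `eta_GG(1)` (the
#' enrichment of poly(A), poly(T), poly(C), poly(G) tracts) on the 100-bp
#' centered windows of a deduplicated peak set, in four cells: GC-poor
#' (window GC `< gc_split`) versus GC-rich (`> gc_split`), crossed with
#' close-to-TSS (peak center within `tss_window` bp of the nearest TSS)
#' versus far-from-TSS. Peaks with GC exactly `gc_split` belong to neither
#' stratum.
#'
#' @param peaks A `peak_set`, deduplicated across stages
#'   ([deduplicate_across_stages()]).
#' @param genome Named character vector of chromosome sequences.
#' @param tss Data frame of TSS positions (`chrom`, `pos`), or a `peak_set`
#'   of 1-bp intervals.
#' @param gc_split GC boundary between the two strata.
#' @param tss_window Near-TSS distance threshold in bp (center-to-TSS).
#' @param n_shuffles,n_subgroups,seed,method As in [mean_profile()].
#' @return Data frame with columns `gc_stratum`, `tss_proximity`, `pair`,
#'   `eta`, `stderr`, `n_sequences`. Empty cells are absent from the table.
#' @export
poly_tract_panel <- function(peaks, genome, tss, gc_split = 0.5,
                             tss_window = 1000L, n_shuffles = 100L,
                             n_subgroups = 10L, seed = 1L,
                             method = c("shuffle", "exact")) {
  method <- match.arg(method)
  tss <- .as_tss(tss)
  seqs <- peak_sequences(peaks, genome, width = 100L)
  ok <- !is.na(seqs)
  gc <- rep(NA_real_, length(seqs))
  gc[ok] <- gc_content(seqs[ok])
  centers <- peak_centers(peaks)
  tss_ps <- peak_set(tss$chrom, tss$pos, tss$pos + 1)
  d <- nearest_peak_distance(peaks, tss_ps)
  near <- !is.na(d) & d <= tss_window
  cells <- expand.grid(gc_stratum = c("low", "high"),
                       tss_proximity = c("close", "far"),
                       stringsAsFactors = FALSE)
  pairs <- c("A", "T", "C", "G")
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    sel <- ok & !is.na(gc) &
      (if (cells$gc_stratum[ci] == "low") gc < gc_split else gc > gc_split) &
      (if (cells$tss_proximity[ci] == "close") near else !near)
    if (sum(sel) < n_subgroups) next
    for (nt in pairs) {
      prof <- mean_profile(seqs[sel], nt, nt, x_max = 1L,
                           n_shuffles = n_shuffles,
                           n_subgroups = n_subgroups,
                           seed = seed, method = method)
      out[[length(out) + 1L]] <- data.frame(
        gc_stratum = cells$gc_stratum[ci],
        tss_proximity = cells$tss_proximity[ci],
        pair = paste0(nt, nt), eta = prof$eta[1L],
        stderr = prof$stderr[1L], n_sequences = prof$n_sequences,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gc_stratum = character(), tss_proximity = character(),
                      pair = character(), eta = numeric(), stderr = numeric(),
                      n_sequences = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# normalize TSS input: data.frame(chrom, pos) or BED-like intervals
.as_tss <- function(tss) {
  if (!is.null(tss$pos)) {
    data.frame(chrom = as.character(tss$chrom), pos = as.numeric(tss$pos),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = as.character(tss$chrom),
               pos = floor((as.numeric(tss$start) + as.numeric(tss$end)) / 2),
               stringsAsFactors = FALSE)
  }
}
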