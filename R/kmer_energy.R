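# Peak-over-background statistical k-mer binding-energy model:
#   U_k(s) = -ln((<N_k(s)>_peak + 1) / (<N_k(s)>_background + 1))
# with <N> the mean per-sequence count of a k-mer plus its reverse complement
# (palindromes counted once), and sequence free energy
#   F_k = -ln sum_i exp(-U_k(s_i))
# over all k-windows of a sequence. Lower free energy = more peak-like.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.all_kmers <- function(k) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

# run code with a temporary RNG state seeded by `seed` (NULL = leave RNG alone)
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Canonical representative of a k-mer
#'
#' The lexicographic minimum of a k-mer and its reverse complement. A k-mer
#' and its reverse complement are counted together by the energy model, so
#' every energy is stored under the canonical representative.
#'
#' @param s Character vector of k-mers over `{A,C,G,T}`.
#' @return Character vector of canonical k-mers; `NA` for k-mers containing
#'   ambiguous bases.
#' @export
canonical_kmer <- function(s) {
  ok <- !is.na(s) & !grepl("[^ACGT]", s)
  out <- rep(NA_character_, length(s))
  if (any(ok)) {
    rc <- .revcomp(s[ok])
    out[ok] <- ifelse(s[ok] <= rc, s[ok], rc)
  }
  out
}

#' Mean per-sequence canonical k-mer counts
#'
#' For each canonical k-mer, the mean over sequences of the number of
#' occurrences of the k-mer plus its reverse complement in sliding windows
#' (step 1). Palindromic k-mers are counted once, not twice. Windows
#' containing `N` are skipped.
#'
#' @param seqs Character vector of sequences (typically 100 bp).
#' @param k K-mer length, `k <= min(nchar(seqs))`.
#' @return Named numeric vector over all canonical k-mers of length `k`.
#' @export
mean_kmer_counts <- function(seqs, k) {
  if (length(seqs) == 0L) stop("empty sequence list")
  stopifnot(k >= 1L, k <= min(nchar(seqs)))
  total <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k, simplify.as = "collapsed"
  )
  km <- names(total)
  rc <- .revcomp(km)
  canon <- km[km <= rc]
  rc_c <- .revcomp(canon)
  counts <- total[canon] + ifelse(canon == rc_c, 0, total[rc_c])
  counts / length(seqs)
}

#' Fit a peak-over-background k-mer energy table
#'
#' Binding energy (in units of kT) of every canonical k-mer:
#' `U = -ln((<N>_peak + 1) / (<N>_background + 1))`. The pseudocount of 1 in
#' numerator and denominator keeps all energies finite; k-mers unobserved in
#' both sets get `U = 0`.
#'
#' @param peak_seqs Character vector of peak-center sequences.
#' @param bg_seqs Character vector of background sequences.
#' @param k K-mer length.
#' @return A `kmer_energy_table`: list with `k`, `energy` (named numeric over
#'   canonical k-mers), `n_peak_mean`, `n_bg_mean`, `n_peak_seqs`,
#'   `n_bg_seqs`.
#' @export
fit_energy_table <- function(peak_seqs, bg_seqs, k) {
  if (length(peak_seqs) == 0L || length(bg_seqs) == 0L) {
    stop("both sequence sets must be non-empty")
  }
  np <- mean_kmer_counts(peak_seqs, k)
  nb <- mean_kmer_counts(bg_seqs, k)
  u <- -log((np + 1) / (nb + 1))
  structure(
    list(k = as.integer(k), energy = u, n_peak_mean = np, n_bg_mean = nb,
         n_peak_seqs = length(peak_seqs), n_bg_seqs = length(bg_seqs)),
    class = "kmer_energy_table"
  )
}

#' @export
print.kmer_energy_table <- function(x, ...) {
  cat(sprintf("kmer_energy_table: k=%d, %d canonical k-mers, fit on %d peak / %d background sequences\n",
              x$k, length(x$energy), x$n_peak_seqs, x$n_bg_seqs))
  lo <- sort(x$energy)[seq_len(min(5L, length(x$energy)))]
  cat("lowest energies (kT):\n")
  print(round(lo, 4))
  invisible(x)
}

#' @export
as.data.frame.kmer_energy_table <- function(x, ...) {
  data.frame(kmer = names(x$energy),
             n_peak_mean = unname(x$n_peak_mean),
             n_bg_mean = unname(x$n_bg_mean),
             energy = unname(x$energy),
             stringsAsFactors = FALSE)
}

#' Write / read an energy table as TSV
#'
#' Columns: `kmer`, `n_peak_mean`, `n_bg_mean`, `energy`.
#'
#' @param table A `kmer_energy_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Free energy of sequences under an energy table
#'
#' `F_k = -ln sum_{i=1..L-k+1} exp(-U(s_i))`, the log-sum-exp aggregate of
#' window energies over all k-windows of each sequence, computed
#' overflow-safely. Windows containing `N` are skipped; a sequence with no
#' valid window gets `NA`.
#'
#' @param seqs Character vector of sequences with `nchar >= k`.
#' @param table A [fit_energy_table()] result.
#' @return Numeric vector of free energies (kT), `NA` where undefined.
#' @export
free_energy <- function(seqs, table) {
  stopifnot(inherits(table, "kmer_energy_table"))
  k <- table$k
  if (any(nchar(seqs) < k)) stop("sequence shorter than k")
  all_km <- .all_kmers(k)
  full_u <- table$energy[canonical_kmer(all_km)]
  nw <- nchar(seqs) - k + 1L
  idx <- rep(seq_along(seqs), times = nw)
  starts <- sequence(nw)
  win <- substring(seqs[idx], starts, starts + k - 1L)
  a <- -unname(full_u[match(win, all_km)])   # NA for windows containing N
  out <- rep(NA_real_, length(seqs))
  valid <- !is.na(a)
  if (!any(valid)) return(out)
  g <- idx[valid]
  av <- a[valid]
  mx <- tapply(av, g, max)
  gid <- as.integer(names(mx))
  s <- rowsum(exp(av - mx[as.character(g)]), g)
  out[gid] <- -(mx + log(s[, 1L]))
  out
}

#' Split a peak set into training and test subsets
#'
#' Uniform random partition of peaks at the peak level (a peak's background
#' windows follow their source peak, preventing train/test leakage).
#'
#' @param peaks A `peak_set` with at least 10 peaks.
#' @param train_fraction Fraction of peaks assigned to training.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with `train` and `test` logical index vectors over the rows
#'   of `peaks`.
#' @export
split_train_test <- function(peaks, train_fraction = 0.8, seed = 1L) {
  n <- nrow(peaks)
  if (n < 10L) stop("need at least 10 peaks to split")
  n_train <- floor(n * train_fraction)
  idx <- .with_seed(seed, sample.int(n, n_train))
  train <- logical(n)
  train[idx] <- TRUE
  list(train = train, test = !train)
}

#' ROC curve and AUC for free-energy classification
#'
#' Lower free energy predicts "peak". AUC is the Mann-Whitney probability
#' `P(F_peak < F_bg) + 0.5 P(F_peak = F_bg)` (tie-corrected); the curve is
#' obtained by sweeping the threshold over the pooled scores, with TPR/FPR
#' the fractions of peak/background scores strictly below the threshold.
#'
#' @param peak_scores,bg_scores Numeric vectors of free energies (non-empty,
#'   `NA` dropped).
#' @return A `roc_result`: list with `auc`, `curve` (data frame `fpr`,
#'   `tpr`), `n_peak`, `n_bg`.
#' @export
roc_auc <- function(peak_scores, bg_scores) {
  p <- peak_scores[!is.na(peak_scores)]
  b <- bg_scores[!is.na(bg_scores)]
  if (length(p) == 0L || length(b) == 0L) stop("both score lists must be non-empty")
  np <- length(p)
  nb <- length(b)
  r <- rank(c(p, b))
  # sum of peak ranks - np(np+1)/2 = #(p > b) + 0.5 #(p == b)
  w_gt <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  auc <- 1 - w_gt / (np * nb)
  thr <- c(-Inf, sort(unique(c(p, b))), Inf)
  tpr <- findInterval(thr, sort(p), left.open = TRUE) / np
  fpr <- findInterval(thr, sort(b), left.open = TRUE) / nb
  structure(
    list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr),
         n_peak = np, n_bg = nb),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC=%.4f (%d peak vs %d background scores)\n",
              x$auc, x$n_peak, x$n_bg))
  invisible(x)
}

#' k-mer specificity statistic
#'
#' `dAUC = max_k AUC(k) - AUC(1)`. Subtracting `AUC(1)` normalizes away the
#' GC-content contribution, isolating specificity beyond mononucleotide
#' composition.
#'
#' @param auc_by_k Named numeric vector of AUC values, names are k-mer
#'   lengths; must contain `k = 1`.
#' @return The dAUC value.
#' @export
delta_auc <- function(auc_by_k) {
  if (!"1" %in% names(auc_by_k)) stop("auc_by_k must contain k = 1")
  max(auc_by_k) - auc_by_k[["1"]]
}

#' GC-stratified k-mer specificity
#'
#' Partitions peaks by the GC-content of their 100-bp centered window into a
#' low stratum (`GC < gc_low`) and a high stratum (`GC > gc_high`); peaks
#' with GC exactly at a boundary fall in neither. Each stratum is processed
#' independently: its own background regions, its own 80/20 train/test
#' split, its own energy tables (one per `k`), ROC evaluation, and dAUC.
#' Strata with fewer than `min_peaks` usable peaks are reported as absent.
#'
#' @param peaks A `peak_set`.
#' @param genome Named character vector of chromosome sequences.
#' @param background `"flanking"` (100-bp windows 100 bp off the peak edges)
#'   or `"atac"` (accessibility-matched; requires `atac`).
#' @param atac Open-chromatin `peak_set`, required for
#'   `background = "atac"`.
#' @param gc_low,gc_high GC-stratum boundaries (open intervals).
#' @param min_peaks Minimum usable peaks per stratum.
#' @param k_range Integer vector of k-mer lengths; must contain 1.
#' @param train_fraction Training fraction for the split.
#' @param seed Integer seed for the splits.
#' @return List with elements `low` and `high`; each is `NULL` (absent
#'   stratum) or a `specificity_summary` list with `tf_name`, `stage`,
#'   `stratum`, `n_peaks`, `n_bg`, `auc_by_k`, `delta_auc`.
#' @export
stratified_specificity <- function(peaks, genome,
                                   background = c("flanking", "atac"),
                                   atac = NULL,
                                   gc_low = 0.4, gc_high = 0.6,
                                   min_peaks = 1000L, k_range = 1:8,
                                   train_fraction = 0.8, seed = 1L) {
  background <- match.arg(background)
  if (!1L %in% k_range) stop("k_range must contain k = 1")
  seqs <- peak_sequences(peaks, genome, width = 100L)
  usable <- !is.na(seqs)
  gc <- rep(NA_real_, length(seqs))
  if (any(usable)) gc[usable] <- gc_content(seqs[usable])

  if (background == "flanking") {
    bg_all <- flanking_background(peaks, genome)
    bg_seq_all <- peak_sequences(
      data.frame(chrom = bg_all$chrom, start = bg_all$start, end = bg_all$end),
      genome, width = 100L)
  } else {
    if (is.null(atac)) stop("background = 'atac' requires an atac peak set")
    bg_all <- accessibility_matched_background(atac, peaks, genome,
                                               gc_lo = gc_low, gc_hi = gc_high)
    bg_seq_all <- peak_sequences(
      data.frame(chrom = bg_all$chrom, start = bg_all$start, end = bg_all$end),
      genome, width = 100L)
  }

  run_stratum <- function(stratum, sel) {
    idx <- which(sel)
    if (length(idx) < min_peaks) return(NULL)
    p_seqs <- seqs[idx]
    if (background == "flanking") {
      b_rows <- which(bg_all$source_peak %in% idx & !is.na(bg_seq_all))
      b_src <- bg_all$source_peak[b_rows]
    } else {
      b_rows <- which(bg_all$stratum == stratum & !is.na(bg_seq_all))
      b_src <- NULL
    }
    b_seqs <- bg_seq_all[b_rows]
    if (length(b_seqs) == 0L) return(NULL)
    sp <- split_train_test(data.frame(i = idx), train_fraction, seed)
    tr_peaks <- p_seqs[sp$train]
    te_peaks <- p_seqs[sp$test]
    if (!is.null(b_src)) {
      # backgrounds inherit their source peak's split side
      src_train <- idx[sp$train]
      tr_bg <- b_seqs[b_src %in% src_train]
      te_bg <- b_seqs[!(b_src %in% src_train)]
    } else {
      spb <- split_train_test(data.frame(i = seq_along(b_seqs)),
                              train_fraction, seed + 1L)
      tr_bg <- b_seqs[spb$train]
      te_bg <- b_seqs[spb$test]
    }
    if (length(tr_bg) == 0L || length(te_bg) == 0L) return(NULL)
    auc_by_k <- vapply(k_range, function(k) {
      tab <- fit_energy_table(tr_peaks, tr_bg, k)
      roc_auc(free_energy(te_peaks, tab), free_energy(te_bg, tab))$auc
    }, numeric(1))
    names(auc_by_k) <- as.character(k_range)
    structure(
      list(tf_name = attr(peaks, "tf_name"), stage = attr(peaks, "stage"),
           stratum = stratum, n_peaks = length(idx), n_bg = length(b_seqs),
           auc_by_k = auc_by_k, delta_auc = delta_auc(auc_by_k)),
      class = "specificity_summary"
    )
  }

  list(
    low = run_stratum("low", usable & !is.na(gc) & gc < gc_low),
    high = run_stratum("high", usable & !is.na(gc) & gc > gc_high)
  )
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat(sprintf("specificity_summary: %s/%s, %s-GC stratum, %d peaks, dAUC=%.4f\n",
              x$tf_name, x$stage, x$stratum, x$n_peaks, x$delta_auc))
  print(round(x$auc_by_k, 4))
  invisible(x)
}
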