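# TSS-aligned metaprofiles: local GC-content and binding intensity around
# anchors (with 10-subgroup error bars), bound/unbound TSS classification,
# joint GC x log-distance histograms, and CpG-count-normalized methylation
# metaprofiles around peak centers.

#' Classify TSSs as bound or unbound by a TF
#'
#' A TSS is bound iff at least one peak lies within `window` bp of it. In
#' `"center"` mode the peak center must fall within the window; in `"edge"`
#' mode the distance is measured from the peak's nearest edge (zero when the
#' TSS lies inside the peak).
#'
#' @param tss Data frame with `chrom`, `pos` (or BED-like `start`/`end`).
#' @param peaks A `peak_set`.
#' @param window Distance threshold in bp.
#' @param mode `"center"` or `"edge"`.
#' @return Logical vector, one per TSS.
#' @export
classify_tss <- function(tss, peaks, window = 1000L,
                         mode = c("center", "edge")) {
  mode <- match.arg(mode)
  tss <- .as_tss(tss)
  out <- logical(nrow(tss))
  for (ch in unique(tss$chrom)) {
    ti <- which(tss$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (length(pi) == 0L) next
    pos <- tss$pos[ti]
    if (mode == "center") {
      cen <- sort(peak_centers(peaks)[pi])
      j <- findInterval(pos, cen)
      d_lo <- ifelse(j >= 1L, pos - cen[pmax(j, 1L)], Inf)
      d_hi <- ifelse(j < length(cen), cen[pmin(j + 1L, length(cen))] - pos, Inf)
      out[ti] <- pmin(abs(d_lo), abs(d_hi)) <= window
    } else {
      o <- order(peaks$start[pi])
      ps <- peaks$start[pi][o]
      pe <- peaks$end[pi][o]
      last_base_max <- cummax(pe - 1)
      j <- findInterval(pos, ps)
      # distance to nearest peak on/left of pos (0 if inside one)
      d_left <- ifelse(j >= 1L, pmax(pos - last_base_max[pmax(j, 1L)], 0), Inf)
      d_right <- ifelse(j < length(ps), ps[pmin(j + 1L, length(ps))] - pos, Inf)
      out[ti] <- pmin(d_left, d_right) <= window
    }
  }
  out
}

.subgroup_stderr <- function(mat, n_subgroups, seed) {
  # mat: offsets x anchors; SD over subgroup means, random equal assignment
  n <- ncol(mat)
  grp <- .with_seed(seed, sample(rep_len(seq_len(n_subgroups), n)))
  gm <- vapply(seq_len(n_subgroups), function(g) {
    rowMeans(mat[, grp == g, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat)))
  apply(matrix(gm, nrow = nrow(mat)), 1L, stats::sd)
}

.meta_profile <- function(positions, values, stderr, n_anchors, window,
                          extra = NULL) {
  structure(c(list(positions = positions, values = values, stderr = stderr,
                   n_anchors = n_anchors, window = window), extra),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile: offsets %d..%d, %d anchors, window %d bp\n",
              min(x$positions), max(x$positions), x$n_anchors, x$window))
  invisible(x)
}

#' @export
as.data.frame.meta_profile <- function(x, ...) {
  data.frame(position = x$positions, value = x$values, stderr = x$stderr)
}

#' GC-content metaprofile around anchors
#'
#' For each offset in `[-half_span, half_span]` relative to each anchor, the
#' local GC-content within a `window`-bp sliding window (step 1 bp) centered
#' on that offset, averaged over anchors. Anchors whose full span (including
#' the window margin) exits the chromosome are dropped; their count is
#' reported in attribute `n_dropped`. The uncertainty is the SD across
#' `n_subgroups` random equally sized anchor subgroups.
#'
#' @param anchors Data frame with `chrom`, `pos` (e.g. TSS positions).
#' @param genome Named character vector of chromosome sequences.
#' @param half_span Profile half-width in bp.
#' @param window Sliding-window width in bp (even).
#' @param n_subgroups Number of subgroups for the error estimate.
#' @param seed Integer seed for subgroup assignment.
#' @return A `meta_profile` (positions, values, stderr, n_anchors, window).
#' @export
gc_metaprofile <- function(anchors, genome, half_span = 1000L, window = 50L,
                           n_subgroups = 10L, seed = 1L) {
  anchors <- .as_tss(anchors)
  stopifnot(window %% 2L == 0L, window >= 2L)
  w2 <- window %/% 2L
  lo <- anchors$pos - half_span - w2       # 0-based inclusive
  hi <- anchors$pos + half_span + w2       # 0-based exclusive (window right edge)
  chr_len <- nchar(genome)[anchors$chrom]
  ok <- lo >= 0 & hi <= chr_len & !is.na(chr_len)
  n_dropped <- sum(!ok)
  if (sum(ok) < n_subgroups) {
    stop("need at least ", n_subgroups, " anchors with full span in the genome")
  }
  offs <- seq(-half_span, half_span)
  span_seq <- substring(genome[anchors$chrom[ok]], lo[ok] + 1L, hi[ok])
  prof <- vapply(span_seq, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    is_gc <- cumsum(c(0, v == "G" | v == "C"))
    is_base <- cumsum(c(0, v != "N"))
    # window centered on offset o covers [o - w2, o + w2) within the span
    i0 <- seq_along(offs)                   # left edge (1-based in span)
    gcw <- is_gc[i0 + window] - is_gc[i0]
    bw <- is_base[i0 + window] - is_base[i0]
    ifelse(bw > 0, gcw / bw, NA_real_)
  }, numeric(length(offs)), USE.NAMES = FALSE)
  prof <- matrix(prof, nrow = length(offs))
  out <- .meta_profile(offs, rowMeans(prof, na.rm = TRUE),
                       .subgroup_stderr(prof, n_subgroups, seed),
                       n_anchors = sum(ok), window = window)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Binding-intensity metaprofile around anchors
#'
#' Mean binding intensity of peaks aligned around anchors. In `"footprint"`
#' mode (default) each peak contributes its intensity at every offset covered
#' by its interval; in `"point"` mode only at its center offset. Offsets not
#' covered by any peak contribute zero. The raw per-offset mean over anchors
#' is smoothed with a centered sliding mean of width `window`.
#'
#' @param peaks A `peak_set`.
#' @param anchors Data frame with `chrom`, `pos`.
#' @param half_span Profile half-width in bp.
#' @param window Smoothing window width in bp (1 = no smoothing).
#' @param mode `"footprint"` or `"point"`.
#' @param n_subgroups,seed Subgroup error estimate controls.
#' @return A `meta_profile`.
#' @export
intensity_metaprofile <- function(peaks, anchors, half_span = 1000L,
                                  window = 50L,
                                  mode = c("footprint", "point"),
                                  n_subgroups = 10L, seed = 1L) {
  mode <- match.arg(mode)
  anchors <- .as_tss(anchors)
  n <- nrow(anchors)
  if (n < n_subgroups) stop("need at least ", n_subgroups, " anchors")
  offs <- seq(-half_span, half_span)
  mat <- matrix(0, nrow = length(offs), ncol = n)
  centers <- peak_centers(peaks)
  for (ch in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (length(pi) == 0L) next
    for (a in ai) {
      pos <- anchors$pos[a]
      if (mode == "footprint") {
        hit <- pi[peaks$start[pi] < pos + half_span + 1 &
                  peaks$end[pi] > pos - half_span]
        for (p in hit) {
          o1 <- max(peaks$start[p] - pos, -half_span) + half_span + 1L
          o2 <- min(peaks$end[p] - 1 - pos, half_span) + half_span + 1L
          mat[o1:o2, a] <- mat[o1:o2, a] + peaks$intensity[p]
        }
      } else {
        hit <- pi[abs(centers[pi] - pos) <= half_span]
        for (p in hit) {
          o <- centers[p] - pos + half_span + 1L
          mat[o, a] <- mat[o, a] + peaks$intensity[p]
        }
      }
    }
  }
  smooth <- function(v) {
    if (window <= 1L) return(v)
    as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  }
  vals <- smooth(rowMeans(mat))
  se <- .subgroup_stderr(mat, n_subgroups, seed)
  .meta_profile(offs, vals, se, n_anchors = n, window = window,
                extra = list(mode = mode))
}

#' Pearson correlation between two metaprofiles
#'
#' Pearson R across offsets (the sample units are offsets, as in
#' profile-level correlations between GC and intensity), with the exact
#' t-distribution two-sided p-value. Offsets where either profile is `NA`
#' are dropped.
#'
#' @param p1,p2 `meta_profile` objects over identical positions.
#' @return List with `r`, `p_value`, `n` (offsets used).
#' @export
profile_pearson <- function(p1, p2) {
  if (!identical(p1$positions, p2$positions)) {
    stop("profiles must share identical positions")
  }
  ok <- !is.na(p1$values) & !is.na(p2$values)
  x <- p1$values[ok]
  y <- p2$values[ok]
  if (length(x) < 3L) stop("fewer than 3 shared offsets")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant profile")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Joint histogram of peak GC-content and log-distance
#'
#' Bins peak GC-content into 50 equal bins on `[0, 1]` and center-to-center
#' distances into 49 logarithmically spaced bins on `[1, 1e7]` bp. Distances
#' below 1 bp (e.g. exactly coincident centers) are clamped to 1; distances
#' above 1e7 fall in the top bin. Pairs with `NA` in either coordinate are
#' dropped.
#'
#' @param gc Numeric vector of GC fractions, one per peak.
#' @param distance Numeric vector of distances (bp), same length.
#' @param n_gc_bins,n_dist_bins Bin counts (defaults 50 and 49).
#' @param dist_range Distance range covered by the log bins.
#' @return A `joint_histogram`: list with `gc_breaks`, `dist_breaks`,
#'   `counts` (matrix `n_gc_bins` x `n_dist_bins`), `n`.
#' @export
joint_gc_distance <- function(gc, distance, n_gc_bins = 50L,
                              n_dist_bins = 49L, dist_range = c(1, 1e7)) {
  stopifnot(length(gc) == length(distance))
  ok <- is.finite(gc) & is.finite(distance)
  gc <- gc[ok]
  d <- pmin(pmax(distance[ok], dist_range[1L]), dist_range[2L])
  gc_breaks <- seq(0, 1, length.out = n_gc_bins + 1L)
  dist_breaks <- 10^seq(log10(dist_range[1L]), log10(dist_range[2L]),
                        length.out = n_dist_bins + 1L)
  # right-closed bins (lo, hi], matching the hist() convention
  gi <- findInterval(gc, gc_breaks, left.open = TRUE, all.inside = TRUE)
  di <- findInterval(d, dist_breaks, left.open = TRUE, all.inside = TRUE)
  counts <- matrix(0L, nrow = n_gc_bins, ncol = n_dist_bins)
  tab <- table(factor(gi, levels = seq_len(n_gc_bins)),
               factor(di, levels = seq_len(n_dist_bins)))
  counts[] <- as.integer(tab)
  structure(list(gc_breaks = gc_breaks, dist_breaks = dist_breaks,
                 counts = counts, n = length(gc)),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("joint_histogram: %d x %d bins, %d peaks\n",
              nrow(x$counts), ncol(x$counts), x$n))
  invisible(x)
}

#' CpG-normalized methylation metaprofile around peak centers
#'
#' Average methylation level within `2 * half_span`-wide regions aligned by
#' peak centers. At each offset the summed methylation fraction over all CpG
#' sites landing there is divided by the number of CpG sites at that offset
#' (not by the number of peaks); offsets with no CpG site are `NA`.
#'
#' @param peaks A `peak_set`.
#' @param methylation Data frame with `chrom`, `pos` (0-based site position),
#'   `fraction` (methylation level in `[0, 1]`).
#' @param half_span Half-width of the aligned region in bp (default 2 kb,
#'   i.e. a 4-kb window).
#' @return A `meta_profile` with offsets `-half_span .. half_span - 1`, plus
#'   element `cpg_counts` (sites per offset). `stderr` is `NA` (the
#'   CpG-count normalization pools sites across peaks).
#' @export
methylation_metaprofile <- function(peaks, methylation, half_span = 2000L) {
  stopifnot(all(methylation$fraction >= 0 & methylation$fraction <= 1))
  n_off <- 2L * half_span
  sums <- numeric(n_off)
  cnts <- numeric(n_off)
  centers <- peak_centers(peaks)
  for (ch in unique(peaks$chrom)) {
    mi <- which(methylation$chrom == ch)
    if (length(mi) == 0L) next
    o <- order(methylation$pos[mi])
    pos <- methylation$pos[mi][o]
    fr <- methylation$fraction[mi][o]
    for (cen in centers[peaks$chrom == ch]) {
      i1 <- findInterval(cen - half_span - 0.5, pos) + 1L
      i2 <- findInterval(cen + half_span - 0.5, pos)
      if (i2 < i1) next
      off <- pos[i1:i2] - cen + half_span + 1L   # 1..n_off
      sums[off] <- sums[off] + fr[i1:i2]
      cnts[off] <- cnts[off] + 1
    }
  }
  vals <- ifelse(cnts > 0, sums / cnts, NA_real_)
  .meta_profile(seq(-half_span, half_span - 1L), vals,
                stderr = rep(NA_real_, n_off), n_anchors = nrow(peaks),
                window = 1L, extra = list(cpg_counts = cnts))
}
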