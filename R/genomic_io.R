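#' Read a genome from a FASTA file
#'
#' Loads all records of a FASTA file into a named character vector of
#' uppercase nucleotide strings. Only the bases `A`, `C`, `G`, `T` and the
#' ambiguity code `N` are accepted; any other letter aborts with an error
#' naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record. Record
#'   names are truncated at the first whitespace.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicated chromosome names in '", path, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  freq <- Biostrings::alphabetFrequency(set)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE]) > 0
  if (any(bad)) {
    stop("record '", nm[which(bad)[1L]],
         "' contains letters outside {A,C,G,T,N}")
  }
  if (any(freq[, "N"] == rowSums(freq))) {
    # all-N records are technically loadable but carry no sequence signal;
    # keep them, downstream windows return NA
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  if (any(nchar(seqs) == 0L)) {
    stop("record '", nm[which(nchar(seqs) == 0L)[1L]], "' is empty")
  }
  seqs
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences (as from [read_genome()]).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a peak set
#'
#' A peak set is a data frame of genomic intervals in BED convention
#' (0-based start, exclusive end) carrying a non-negative binding intensity,
#' sorted by `(chrom, start, end)`, with the TF name and developmental stage
#' attached as attributes.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start coordinates.
#' @param end Exclusive end coordinates.
#' @param intensity Non-negative binding intensities (recycled).
#' @param name Optional region names (default `"."`).
#' @param tf_name Transcription factor label.
#' @param stage Developmental stage label (e.g. ESC, dEN).
#' @return A `peak_set`: data frame with columns `chrom`, `start`, `end`,
#'   `name`, `intensity`.
#' @export
peak_set <- function(chrom, start, end, intensity = 0, name = ".",
                     tf_name = "TF", stage = "ESC") {
  stopifnot(length(start) == length(end))
  chrom <- rep_len(as.character(chrom), length(start))
  if (!nzchar(tf_name) || !nzchar(stage)) {
    stop("tf_name and stage must be non-empty")
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0) || any(start >= end)) {
    stop("peak coordinates must satisfy 0 <= start < end")
  }
  intensity <- rep_len(as.numeric(intensity), length(chrom))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  df <- data.frame(
    chrom = chrom, start = start, end = end,
    name = rep_len(as.character(name), length(chrom)),
    intensity = intensity,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, tf_name = tf_name, stage = stage,
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks, TF=%s, stage=%s\n",
              nrow(x), attr(x, "tf_name"), attr(x, "stage")))
  NextMethod()
}

#' Peak centers
#'
#' Center of a BED interval, defined as `floor((start + end) / 2)`.
#'
#' @param peaks A `peak_set` or data frame with `start`/`end` columns.
#' @return Numeric vector of center coordinates.
#' @export
peak_centers <- function(peaks) {
  floor((peaks$start + peaks$end) / 2)
}

#' Read peaks from a BED file
#'
#' Coordinates are taken as BED 0-based half-open. With five or more columns,
#' column 4 is the name and column 5 the intensity (score); `score_col = 4`
#' selects the dialect where a 4-column file is `chrom start end score`.
#' Records with `start >= end` are rejected with a warning. Strand columns
#' are ignored (all analyses are strand-symmetric).
#'
#' @param path BED file path (>= 3 tab-separated columns, no header).
#' @param tf TF label for the resulting set.
#' @param stage Stage label.
#' @param score_col Column holding the intensity: 5 (default) or 4.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, tf = "TF", stage = "ESC", score_col = 5L) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 3L) stop("BED file '", path, "' has fewer than 3 columns")
  chrom <- as.character(df[[1L]])
  start <- as.numeric(df[[2L]])
  end <- as.numeric(df[[3L]])
  name <- if (ncol(df) >= 4L && score_col == 5L) as.character(df[[4L]]) else "."
  intensity <- if (ncol(df) >= score_col) {
    suppressWarnings(as.numeric(df[[score_col]]))
  } else {
    0
  }
  intensity[is.na(intensity)] <- 0
  bad <- !(start < end) | start < 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with start >= end or negative start ",
            "rejected from '", path, "'")
  }
  keep <- !bad
  peak_set(chrom[keep], start[keep], end[keep],
           intensity = rep_len(intensity, length(chrom))[keep],
           name = rep_len(name, length(chrom))[keep],
           tf_name = tf, stage = stage)
}

#' Write peaks to a BED file
#'
#' Writes BED5 (`chrom start end name score`), tab-separated, no header.
#' Round-trips coordinates and intensities with [read_peaks()].
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
                   format(peaks$end, scientific = FALSE, trim = TRUE),
                   peaks$name, peaks$intensity)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract fixed-width sequences centered on peaks
#'
#' Returns the `width`-bp window centered on each peak center. A window is
#' returned only when the peak itself is at least `width` bp long (shorter
#' peaks are omitted) and the window lies fully inside the chromosome;
#' otherwise `NA`.
#'
#' @param peaks A `peak_set` (or data frame with `chrom`, `start`, `end`).
#' @param genome Named character vector of chromosome sequences.
#' @param width Window width in bp; must be even and >= 2.
#' @return Character vector of sequences (length `nrow(peaks)`), `NA` where
#'   the window is unavailable.
#' @export
peak_sequences <- function(peaks, genome, width = 100L) {
  stopifnot(width >= 2L, width %% 2L == 0L)
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr) > 0L) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  centers <- peak_centers(peaks)
  half <- width %/% 2L
  s <- centers - half           # 0-based inclusive
  e <- centers + half           # 0-based exclusive
  chr_len <- nchar(genome)[peaks$chrom]
  ok <- (peaks$end - peaks$start) >= width & s >= 0 & e <= chr_len
  out <- rep(NA_character_, nrow(peaks))
  if (any(ok)) {
    out[ok] <- substring(genome[peaks$chrom[ok]], s[ok] + 1L, e[ok])
  }
  out
}

#' Sequence for a single peak
#'
#' Single-peak convenience wrapper around [peak_sequences()].
#'
#' @param peak One-row `peak_set` or list with `chrom`, `start`, `end`.
#' @inheritParams peak_sequences
#' @return A sequence string, or `NA` if the window is unavailable.
#' @export
centered_sequence <- function(peak, genome, width = 100L) {
  df <- data.frame(chrom = peak$chrom[1L], start = peak$start[1L],
                   end = peak$end[1L], stringsAsFactors = FALSE)
  peak_sequences(df, genome, width)[1L]
}

#' GC-content of nucleotide sequences
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T); `N` positions are excluded from
#' numerator and denominator. All-`N` sequences yield `NA`.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @return Numeric vector of fractions in `[0, 1]` (or `NA`).
#' @export
gc_content <- function(seq) {
  if (any(is.na(seq))) stop("NA sequence passed to gc_content")
  if (any(nchar(seq) == 0L)) stop("empty sequence passed to gc_content")
  set <- Biostrings::DNAStringSet(seq)
  freq <- Biostrings::letterFrequency(set, c("A", "C", "G", "T"))
  gc <- freq[, "G"] + freq[, "C"]
  denom <- rowSums(freq)
  out <- gc / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

# For each query interval, TRUE if it overlaps any subject interval on the
# same chromosome. Intervals are half-open [start, end).
.overlaps_any <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- logical(length(q_chrom))
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    si <- which(s_chrom == ch)
    if (length(si) == 0L) next
    o <- order(s_start[si])
    ss <- s_start[si][o]
    se_max <- cummax(s_end[si][o])
    # subjects with start < q_end: indices 1..j
    j <- findInterval(q_end[qi] - 0.5, ss)
    hit <- j > 0L
    hit[hit] <- se_max[j[hit]] > q_start[qi][hit]
    out[qi] <- hit
  }
  out
}

#' Flanking background regions for a peak set
#'
#' For each peak, two candidate 100-bp windows situated 100 bp away from the
#' peak edges: `[start - 200, start - 100)` and `[end + 100, end + 200)`.
#' A candidate is kept iff it lies fully inside the chromosome and overlaps
#' no peak of the set.
#'
#' @param peaks A `peak_set`.
#' @param genome Named character vector of chromosome sequences.
#' @return A `peak_set`-shaped data frame of 100-bp regions with
#'   `intensity = 0`, plus columns `source_peak` (row index of the generating
#'   peak) and `side` (`"left"`/`"right"`); attribute
#'   `provenance = "flanking"`.
#' @export
flanking_background <- function(peaks, genome) {
  n <- nrow(peaks)
  cand <- data.frame(
    chrom = rep(peaks$chrom, 2L),
    start = c(peaks$start - 200, peaks$end + 100),
    end = c(peaks$start - 100, peaks$end + 200),
    source_peak = rep(seq_len(n), 2L),
    side = rep(c("left", "right"), each = n),
    stringsAsFactors = FALSE
  )
  chr_len <- nchar(genome)[cand$chrom]
  inside <- cand$start >= 0 & cand$end <= chr_len & !is.na(chr_len)
  ov <- .overlaps_any(cand$chrom, cand$start, cand$end,
                      peaks$chrom, peaks$start, peaks$end)
  keep <- inside & !ov
  out <- cand[keep, , drop = FALSE]
  out$name <- "."
  out$intensity <- 0
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out[, c("chrom", "start", "end", "name", "intensity",
                    "source_peak", "side")],
            provenance = "flanking",
            tf_name = attr(peaks, "tf_name"), stage = attr(peaks, "stage"),
            class = c("peak_set", "data.frame"))
}

#' Accessibility-matched background regions
#'
#' Selects 100-bp windows centered on open-chromatin (e.g. ATAC-seq) peaks
#' whose window GC-content falls below `gc_lo` (low stratum) or above
#' `gc_hi` (high stratum), discarding ATAC peaks that overlap any ChIP peak.
#'
#' @param atac Open-chromatin `peak_set`.
#' @param chip ChIP `peak_set` on the same genome.
#' @param genome Named character vector of chromosome sequences.
#' @param gc_lo Upper bound (exclusive) of the low-GC stratum.
#' @param gc_hi Lower bound (exclusive) of the high-GC stratum.
#' @return A `peak_set`-shaped data frame of 100-bp regions with a `stratum`
#'   column (`"low"`/`"high"`); attribute
#'   `provenance = "accessibility-matched"`. Warns when empty.
#' @export
accessibility_matched_background <- function(atac, chip, genome,
                                             gc_lo = 0.4, gc_hi = 0.6) {
  seqs <- peak_sequences(atac, genome, width = 100L)
  gc <- rep(NA_real_, nrow(atac))
  has <- !is.na(seqs)
  if (any(has)) gc[has] <- gc_content(seqs[has])
  ov <- .overlaps_any(atac$chrom, atac$start, atac$end,
                      chip$chrom, chip$start, chip$end)
  stratum <- rep(NA_character_, nrow(atac))
  stratum[!is.na(gc) & gc < gc_lo] <- "low"
  stratum[!is.na(gc) & gc > gc_hi] <- "high"
  keep <- !is.na(stratum) & !ov
  centers <- peak_centers(atac)
  out <- data.frame(
    chrom = atac$chrom[keep],
    start = centers[keep] - 50,
    end = centers[keep] + 50,
    name = rep(".", sum(keep)),
    intensity = rep(0, sum(keep)),
    stratum = stratum[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) {
    warning("accessibility-matched background is empty")
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = "accessibility-matched",
            tf_name = attr(chip, "tf_name"), stage = attr(chip, "stage"),
            class = c("peak_set", "data.frame"))
}

#' Deduplicate peaks pooled across developmental stages
#'
#' Takes the union of several peak sets of one TF. Within every chain of
#' mutually overlapping peaks, only the peak with the leftmost start
#' coordinate is kept (ties broken by smallest end).
#'
#' @param peaksets List of `peak_set` objects for one TF.
#' @return A `peak_set` with no overlapping pairs; stage label `"pooled"`.
#' @export
deduplicate_across_stages <- function(peaksets) {
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  all <- do.call(rbind, lapply(peaksets, function(p) {
    as.data.frame(p)[, c("chrom", "start", "end", "name", "intensity")]
  }))
  all <- all[order(all$chrom, all$start, all$end), , drop = FALSE]
  keep <- logical(nrow(all))
  cur_chrom <- ""
  cur_end <- -Inf
  for (i in seq_len(nrow(all))) {
    if (all$chrom[i] != cur_chrom || all$start[i] >= cur_end) {
      keep[i] <- TRUE
      cur_chrom <- all$chrom[i]
      cur_end <- all$end[i]
    } else {
      # extend the overlap chain; the kept peak stays the leftmost one
      cur_end <- max(cur_end, all$end[i])
    }
  }
  out <- all[keep, , drop = FALSE]
  peak_set(out$chrom, out$start, out$end, intensity = out$intensity,
           name = out$name, tf_name = attr(peaksets[[1L]], "tf_name") %||% "TF",
           stage = "pooled")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Center-to-center distance to the nearest peak of another set
#'
#' For each peak of `a`, the minimum over peaks of `b` (same chromosome) of
#' the absolute center-to-center distance. Peaks of `a` on chromosomes
#' absent from `b` get `NA`.
#'
#' @param a,b `peak_set` objects; `b` must be non-empty.
#' @return Numeric vector of distances, one per peak of `a`.
#' @export
nearest_peak_distance <- function(a, b) {
  if (nrow(b) == 0L) stop("peak set 'b' is empty")
  ca <- peak_centers(a)
  cb <- peak_centers(b)
  out <- rep(NA_real_, nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (length(bi) == 0L) next
    sb <- sort(cb[bi])
    j <- findInterval(ca[ai], sb)
    d_lo <- ifelse(j >= 1L, ca[ai] - sb[pmax(j, 1L)], Inf)
    d_hi <- ifelse(j < length(sb), sb[pmin(j + 1L, length(sb))] - ca[ai], Inf)
    out[ai] <- pmin(abs(d_lo), abs(d_hi))
  }
  out
}
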