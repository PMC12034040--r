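# Synthetic genomes, TSS annotations, peak sets, methylation tracks and
# expression tables carrying the statistical structure the analysis assumes:
# bimodal peak GC-content, a consensus motif planted only in low-GC peaks,
# poly(A) tracts in low-GC peaks and CNNNNNC periodicity in high-GC peaks,
# TSS-centered GC bumps with high-GC peaks biased toward TSSs, intensity
# proportional to local GC, and CpG methylation valleys at peak centers.
# Fully deterministic given the spec seed.

#' Specification for the synthetic data generator
#'
#' Bundles all generative parameters with validated defaults. The default
#' configuration emulates, at desk scale, the data structure the analyses
#' assume: two GC modes (0.30 and 0.70, sd 0.05) in equal proportion so each
#' GC stratum clears a 1000-peak threshold on 3000 peaks; the consensus
#' motif `GGATTA` planted with probability 0.8 in low-GC peaks only;
#' poly(A)/poly(T) tracts in low-GC peaks and a C-every-6-bp periodic
#' element in high-GC peaks; 500 TSSs with local GC bumps and high-GC peaks
#' preferentially placed near them; peak intensity affine in window
#' GC-content; and a CpG methylation valley centered on peaks.
#'
#' @param seed Integer master seed; all outputs are byte-reproducible
#'   functions of it.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param background_gc Baseline genome GC fraction.
#' @param peak_modes List of mode lists, each with `weight`, `gc_mean`,
#'   `gc_sd`, `motif` (k-mer string or `NULL`), `motif_prob`, `str_pattern`
#'   (`"none"`, `"poly_A"`, `"periodic_C6"`), `str_strength` (probability a
#'   peak of the mode carries the repeat element), `tss_prob` (probability
#'   the peak is placed within 1 kb of a TSS).
#' @param n_peaks,peak_length Peak count and width (bp).
#' @param domain_pad Width (bp) of the local GC domain extending each side
#'   of a peak. The whole domain is rewritten to the peak's GC target,
#'   emulating the local GC autocorrelation (isochore structure) of real
#'   genomes; it covers the flanking background windows, so backgrounds are
#'   approximately GC-matched to their source peak. Peak placement keeps
#'   padded domains disjoint.
#' @param n_tss Number of TSSs.
#' @param tss_gc_bump List with `amplitude` (added GC fraction at the TSS)
#'   and `half_width` (Gaussian scale, bp).
#' @param intensity_model List with `gc_slope` and `noise_sd`; intensity =
#'   `gc_slope * windowGC + N(0, noise_sd)`, truncated at 0.
#' @param methylation_model List with `baseline`, `valley_depth`,
#'   `valley_halfwidth` (bp), `cpg_rate` (site probability per position).
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_chromosomes = 4L,
                           chrom_length = 2.5e6,
                           background_gc = 0.45,
                           peak_modes = list(
                             low = list(weight = 0.5, gc_mean = 0.30,
                                        gc_sd = 0.05, motif = "GGATTA",
                                        motif_prob = 0.8,
                                        str_pattern = "poly_A",
                                        str_strength = 0.6, tss_prob = 0.1),
                             high = list(weight = 0.5, gc_mean = 0.70,
                                         gc_sd = 0.05, motif = NULL,
                                         motif_prob = 0,
                                         str_pattern = "periodic_C6",
                                         str_strength = 0.6, tss_prob = 0.6)
                           ),
                           n_peaks = 3000L,
                           peak_length = 200L,
                           domain_pad = 300L,
                           n_tss = 500L,
                           tss_gc_bump = list(amplitude = 0.15,
                                              half_width = 300),
                           intensity_model = list(gc_slope = 10,
                                                  noise_sd = 1),
                           methylation_model = list(baseline = 0.8,
                                                    valley_depth = 0.5,
                                                    valley_halfwidth = 500,
                                                    cpg_rate = 0.02)) {
  w <- vapply(peak_modes, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("peak mode weights must sum to 1")
  for (m in peak_modes) {
    stopifnot(m$gc_mean >= 0, m$gc_mean <= 1, m$gc_sd >= 0,
              m$motif_prob >= 0, m$motif_prob <= 1,
              m$str_pattern %in% c("none", "poly_A", "periodic_C6"))
    if (!is.null(m$motif) && nchar(m$motif) > peak_length) {
      stop("motif longer than peak_length")
    }
  }
  stopifnot(background_gc >= 0, background_gc <= 1,
            methylation_model$baseline >= 0, methylation_model$baseline <= 1,
            methylation_model$cpg_rate >= 0, methylation_model$cpg_rate < 1,
            n_peaks >= 1, peak_length >= 100, n_tss >= 1)  # central 100-bp
  # window must fit inside every peak (shorter peaks are omitted downstream)
  structure(
    list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
         chrom_length = chrom_length, background_gc = background_gc,
         peak_modes = peak_modes, n_peaks = as.integer(n_peaks),
         peak_length = as.integer(peak_length),
         domain_pad = as.integer(domain_pad), n_tss = as.integer(n_tss),
         tss_gc_bump = tss_gc_bump, intensity_model = intensity_model,
         methylation_model = methylation_model),
    class = "synthetic_spec"
  )
}

# deterministic per-component sub-seed, kept inside 32-bit integer range
.sub_seed <- function(seed, component, index = 0L) {
  (as.numeric(seed) * 7919 + component * 104729 + index * 31) %% 2147483647
}

.sample_bases <- function(p_gc) {
  is_gc <- stats::runif(length(p_gc)) < p_gc
  strong <- stats::runif(length(p_gc)) < 0.5
  out <- character(length(p_gc))
  out[is_gc & strong] <- "G"
  out[is_gc & !strong] <- "C"
  out[!is_gc & strong] <- "A"
  out[!is_gc & !strong] <- "T"
  out
}

#' Generate a synthetic genome with TSS annotations
#'
#' Each chromosome is drawn i.i.d. at `background_gc` with Gaussian GC bumps
#' of the configured amplitude and half-width centered at TSS positions
#' (placed uniformly with a 10-kb edge margin). Chromosomes use independent
#' seeded RNG streams, so each chromosome's content is invariant to the
#' presence of the others.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_genome`: list with `sequences` (named character
#'   vector, as [read_genome()] returns) and `tss` (data frame `chrom`,
#'   `pos`).
#' @export
generate_genome <- function(spec) {
  n_chr <- spec$n_chromosomes
  len <- spec$chrom_length
  margin <- min(1e4, len / 10)
  n_tss_chr <- diff(round(seq(0, spec$n_tss, length.out = n_chr + 1L)))
  seqs <- character(n_chr)
  tss_list <- list()
  bump <- spec$tss_gc_bump
  for (i in seq_len(n_chr)) {
    .with_seed(.sub_seed(spec$seed, 1L, i), {
      pos <- sort(round(stats::runif(n_tss_chr[i], margin, len - margin)))
      p_gc <- rep(spec$background_gc, len)
      if (bump$amplitude != 0) {
        reach <- ceiling(4 * bump$half_width)
        for (t in pos) {
          j <- max(1, t - reach):min(len, t + reach)
          p_gc[j] <- p_gc[j] +
            bump$amplitude * exp(-((j - t)^2) / (2 * bump$half_width^2))
        }
      }
      p_gc <- pmin(pmax(p_gc, 0), 1)
      seqs[i] <- paste(.sample_bases(p_gc), collapse = "")
      tss_list[[i]] <- data.frame(chrom = paste0("chr", i), pos = pos,
                                  stringsAsFactors = FALSE)
    })
  }
  names(seqs) <- paste0("chr", seq_len(n_chr))
  structure(list(sequences = seqs, tss = do.call(rbind, tss_list)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d chromosome(s), %.3g bp total, %d TSS\n",
              length(x$sequences), sum(nchar(x$sequences)), nrow(x$tss)))
  invisible(x)
}

.plant <- function(chars, at, what) {
  chars[at:(at + length(what) - 1L)] <- what
  chars
}

#' Generate a synthetic peak set
#'
#' Each peak is assigned to a GC mode by the mode weights and placed without
#' overlap of its padded local GC domain (rejection sampling; near a random
#' TSS with the mode's `tss_prob`, else uniformly). The peak's whole domain
#' (peak plus `domain_pad` bp each side, covering the flanking background
#' windows) is rewritten in place by per-base resampling toward a per-peak
#' GC target drawn from the mode, emulating local GC autocorrelation so
#' flanking backgrounds are GC-matched to their peak (motif positions are
#' masked so planting stays intact); with probability
#' `motif_prob` one motif copy is planted on a random strand at a uniform
#' offset within the central 100 bp; repeat elements are planted per mode
#' (`poly_A`: A or T runs of length 5-8; `periodic_C6`: C (or G) at every
#' 6th position over a 30-bp stretch). Intensity is affine in the GC of the
#' 100-bp centered window with Gaussian noise, truncated at 0.
#'
#' Note: the genome sequences inside `genome` are modified (peak windows
#' rewritten); use the returned `genome` element downstream.
#'
#' @param spec A [synthetic_spec()].
#' @param genome A `synthetic_genome` from [generate_genome()].
#' @return List with `peaks` (a [peak_set()] with a `mode` column) and
#'   `genome` (the rewritten `synthetic_genome`).
#' @export
generate_peaks <- function(spec, genome) {
  stopifnot(inherits(genome, "synthetic_genome"))
  seqs <- genome$sequences
  chroms <- names(seqs)
  chr_len <- nchar(seqs)
  plen <- spec$peak_length
  pad <- spec$domain_pad
  modes <- spec$peak_modes
  w <- vapply(modes, function(m) m$weight, numeric(1))

  .with_seed(.sub_seed(spec$seed, 2L), {
    mode_id <- sample(seq_along(modes), spec$n_peaks, replace = TRUE, prob = w)
    occupied <- lapply(chroms, function(ch) {
      matrix(numeric(0), ncol = 2)
    })
    names(occupied) <- chroms
    chrom_out <- character(spec$n_peaks)
    start_out <- numeric(spec$n_peaks)
    max_tries <- 200L
    for (i in seq_len(spec$n_peaks)) {
      m <- modes[[mode_id[i]]]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        if (stats::runif(1) < m$tss_prob && nrow(genome$tss) > 0L) {
          # near-TSS placement concentrates at the TSS (as promoter-bound
          # peaks do), on the same scale as the TSS GC bump
          t <- genome$tss[sample.int(nrow(genome$tss), 1L), ]
          ch <- t$chrom
          cen <- t$pos + round(stats::rnorm(1, 0, 300))
          st <- cen - plen %/% 2L
        } else {
          ch <- sample(chroms, 1L, prob = chr_len)
          st <- round(stats::runif(1, pad, chr_len[ch] - plen - pad))
        }
        if (st < pad || st + plen > chr_len[ch] - pad) next
        occ <- occupied[[ch]]
        # padded domains must stay disjoint
        if (nrow(occ) > 0L &&
            any(occ[, 1L] < st + plen + pad & occ[, 2L] > st - pad)) next
        occupied[[ch]] <- rbind(occ, c(st - pad, st + plen + pad))
        chrom_out[i] <- ch
        start_out[i] <- st
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place peak ", i, " without overlap; ",
                        "genome too crowded")
    }

    # rewrite peak sequences mode by mode
    char_seqs <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
    gc_target <- numeric(spec$n_peaks)
    for (i in seq_len(spec$n_peaks)) {
      m <- modes[[mode_id[i]]]
      ch <- chrom_out[i]
      st <- start_out[i]          # 0-based
      dlen <- plen + 2L * pad
      idx <- (st - pad + 1L):(st + plen + pad)   # whole domain, 1-based
      gc_t <- min(max(stats::rnorm(1, m$gc_mean, m$gc_sd), 0.05), 0.95)
      gc_target[i] <- gc_t
      local <- .sample_bases(rep(gc_t, dlen))
      # central 100-bp window bounds within the domain (1-based, local)
      c_lo <- pad + plen %/% 2L - 50L + 1L
      mask <- logical(dlen)
      if (!is.null(m$motif) && stats::runif(1) < m$motif_prob) {
        mot <- strsplit(m$motif, "", fixed = TRUE)[[1L]]
        if (stats::runif(1) < 0.5) mot <- rev(chartr("ACGT", "TGCA", mot))
        at <- c_lo + sample.int(100L - length(mot) + 1L, 1L) - 1L
        local <- .plant(local, at, mot)
        mask[at:(at + length(mot) - 1L)] <- TRUE
      }
      if (m$str_pattern != "none" && stats::runif(1) < m$str_strength) {
        if (m$str_pattern == "poly_A") {
          for (r in seq_len(2L)) {
            run_len <- sample(5:8, 1L)
            base <- sample(c("A", "T"), 1L)
            at <- c_lo + sample.int(100L - run_len + 1L, 1L) - 1L
            if (any(mask[at:(at + run_len - 1L)])) next
            local <- .plant(local, at, rep(base, run_len))
          }
        } else {  # periodic_C6: C at every 6th position over 30 bp
          base <- sample(c("C", "G"), 1L)
          at <- c_lo + sample.int(100L - 30L + 1L, 1L) - 1L
          ppos <- at + seq(0L, 24L, by = 6L)
          if (!any(mask[ppos])) {
            local[ppos] <- base
          }
        }
      }
      char_seqs[[ch]][idx] <- local
    }
    seqs_new <- vapply(char_seqs, paste, character(1), collapse = "")
    names(seqs_new) <- chroms
    genome$sequences <- seqs_new

    # intensity from the realized 100-bp window GC
    tmp <- data.frame(chrom = chrom_out, start = start_out,
                      end = start_out + plen, stringsAsFactors = FALSE)
    win <- peak_sequences(tmp, seqs_new, width = 100L)
    gc_win <- gc_content(win)
    im <- spec$intensity_model
    intensity <- pmax(im$gc_slope * gc_win +
                        stats::rnorm(spec$n_peaks, 0, im$noise_sd), 0)

    peaks <- peak_set(chrom_out, start_out, start_out + plen,
                      intensity = intensity,
                      name = paste0("peak", seq_len(spec$n_peaks)),
                      tf_name = "synthTF", stage = "ESC")
    # reattach generator metadata in sorted order
    o <- order(chrom_out, start_out, start_out + plen)
    peaks$mode <- names(modes)[mode_id][o]
    list(peaks = peaks, genome = genome)
  })
}

#' Generate a synthetic CpG methylation track
#'
#' CpG sites are placed independently at probability `cpg_rate` per genomic
#' position; the methylation fraction at a site is
#' `baseline - valley_depth * exp(-|d| / valley_halfwidth)` (clipped to
#' `[0, 1]`), where `d` is the distance to the nearest peak center.
#'
#' @param spec A [synthetic_spec()].
#' @param genome A `synthetic_genome`.
#' @param peaks A `peak_set`.
#' @return Data frame with `chrom`, `pos`, `fraction`, sorted by position
#'   within chromosome.
#' @export
generate_methylation <- function(spec, genome, peaks) {
  mm <- spec$methylation_model
  centers <- peak_centers(peaks)
  out <- list()
  for (i in seq_along(genome$sequences)) {
    ch <- names(genome$sequences)[i]
    len <- nchar(genome$sequences[[i]])
    .with_seed(.sub_seed(spec$seed, 3L, i), {
      pos <- if (mm$cpg_rate <= 0) integer(0) else
        which(stats::runif(len - 1L) < mm$cpg_rate)
      if (length(pos) > 0L) {
        cen <- sort(centers[peaks$chrom == ch])
        if (length(cen) == 0L) {
          d <- rep(Inf, length(pos))
        } else {
          j <- findInterval(pos, cen)
          d_lo <- ifelse(j >= 1L, pos - cen[pmax(j, 1L)], Inf)
          d_hi <- ifelse(j < length(cen), cen[pmin(j + 1L, length(cen))] - pos, Inf)
          d <- pmin(abs(d_lo), abs(d_hi))
        }
        frac <- pmin(pmax(
          mm$baseline - mm$valley_depth * exp(-d / mm$valley_halfwidth), 0), 1)
        out[[ch]] <- data.frame(chrom = ch, pos = pos, fraction = frac,
                                stringsAsFactors = FALSE)
      }
    })
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), pos = numeric(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a two-stage expression table
#'
#' Emulates the measured expression pattern driving the competition model: a
#' configurable Myc ratio between an undifferentiated and a differentiated
#' stage (default 4), with Smad constant across stages.
#'
#' @param spec A [synthetic_spec()] (only the seed is used, for API
#'   symmetry; the table is deterministic).
#' @param myc_ratio Ratio of Myc level in ESC to dEN.
#' @param stages Character vector of the two stage labels.
#' @return Data frame with `gene`, `stage`, `level`.
#' @export
generate_expression_table <- function(spec, myc_ratio = 4,
                                      stages = c("ESC", "dEN")) {
  data.frame(
    gene = rep(c("MYC", "SMAD1"), each = 2L),
    stage = rep(stages, times = 2L),
    level = c(myc_ratio, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}
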