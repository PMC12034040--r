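# End-to-end orchestration: synthetic (or user-supplied) inputs -> GC
# distributions -> GC-stratified k-mer specificity -> repeat correlations ->
# TSS profiles -> methylation metaprofile -> equilibrium sweep, with a
# reproducibility manifest. Deterministic given the config.

#' Default pipeline configuration
#'
#' Returns a complete configuration list for [run_pipeline()] running on
#' synthetic data. Every stochastic stage has an explicit seed derived from
#' `seed`. Supply `genome_fasta` / `peaks_bed` / `tss_bed` /
#' `methylation_tsv` paths to run on real data instead of the synthetic
#' generator.
#'
#' @param seed Master integer seed.
#' @param outdir Output directory.
#' @return Named list; see [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, outdir = "bimodal_out") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    genome_fasta = NULL, peaks_bed = NULL, tss_bed = NULL,
    methylation_tsv = NULL, atac_bed = NULL,
    synthetic = list(),            # overrides for synthetic_spec()
    kmer = list(k_range = 1:8, gc_low = 0.4, gc_high = 0.6,
                min_peaks = 1000L, train_fraction = 0.8,
                background = "flanking"),
    correlation = list(x_max = 30L, n_shuffles = 100L, n_subgroups = 10L,
                       method = "exact", gc_split = 0.5, tss_window = 1000L),
    tss = list(half_span = 1000L, window = 50L, bound_window = 1000L,
               bound_mode = "center", n_subgroups = 10L),
    methylation = list(half_span = 2000L),
    equilibrium = list(dna_tot = 0.5e-6,
                       grid_from = 1e-8, grid_to = 1e-5, grid_n = 200L)
  )
}

#' Validate a pipeline configuration
#'
#' Checks referenced files exist and seeds are present before any compute.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   YAML file path.
#' @return The normalized configuration list, invisibly on success; errors
#'   otherwise.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must carry an explicit seed")
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  for (f in c("genome_fasta", "peaks_bed", "tss_bed", "methylation_tsv",
              "atac_bed")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("configured file does not exist: ", f, " = ", config[[f]])
    }
  }
  if (!is.null(config$genome_fasta) && is.null(config$peaks_bed)) {
    stop("a real genome requires peaks_bed")
  }
  invisible(config)
}

.stage <- function(name, code) {
  message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(code, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] %s done (%.1f s)", format(Sys.time(), "%H:%M:%S"),
                  name, proc.time()[["elapsed"]] - t0))
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes all stages on synthetic or user-supplied inputs and writes TSV
#' outputs plus a JSON manifest (seeds, parameters, package and R versions)
#' into the output directory. Reruns with the same config are bit-identical.
#'
#' @param config Configuration list or YAML path
#'   (see [default_pipeline_config()]).
#' @return The output directory path, invisibly. Side effects: files
#'   `peak_gc_histogram.tsv`, `kmer_specificity.tsv`, `poly_tract_panel.tsv`,
#'   `tss_gc_profile.tsv`, `tss_intensity_profile.tsv`,
#'   `methylation_profile.tsv`, `equilibrium_sweep_on.tsv`,
#'   `equilibrium_sweep_off.tsv`, `expression_table.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  config <- validate_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  inputs <- .stage("inputs", {
    if (is.null(config$genome_fasta)) {
      spec <- do.call(synthetic_spec,
                      c(list(seed = config$seed), config$synthetic))
      g <- generate_genome(spec)
      gp <- generate_peaks(spec, g)
      meth <- generate_methylation(spec, gp$genome, gp$peaks)
      list(genome = gp$genome$sequences, peaks = gp$peaks,
           tss = gp$genome$tss, methylation = meth, spec = spec)
    } else {
      genome <- read_genome(config$genome_fasta)
      peaks <- read_peaks(config$peaks_bed)
      tss_bed <- read_peaks(config$tss_bed)
      meth <- if (is.null(config$methylation_tsv)) NULL else {
        m <- utils::read.table(config$methylation_tsv, sep = "\t",
                               header = FALSE, stringsAsFactors = FALSE)
        data.frame(chrom = m[[1L]], pos = m[[2L]], fraction = m[[3L]])
      }
      list(genome = genome, peaks = peaks, tss = .as_tss(tss_bed),
           methylation = meth, spec = NULL)
    }
  })
  genome <- inputs$genome
  peaks <- inputs$peaks
  tss <- inputs$tss

  .stage("gc_distribution", {
    seqs <- peak_sequences(peaks, genome, 100L)
    gc <- gc_content(seqs[!is.na(seqs)])
    breaks <- seq(0, 1, length.out = 101L)
    bin <- findInterval(gc, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    .write_tsv(data.frame(gc_bin_left = breaks[-length(breaks)],
                          gc_bin_right = breaks[-1L],
                          count = tabulate(bin, nbins = 100L)),
               file.path(outdir, "peak_gc_histogram.tsv"))
  })

  spec_res <- .stage("kmer_specificity", {
    k <- config$kmer
    res <- stratified_specificity(
      peaks, genome, background = k$background,
      atac = if (is.null(config$atac_bed)) NULL else
        read_peaks(config$atac_bed),
      gc_low = k$gc_low, gc_high = k$gc_high, min_peaks = k$min_peaks,
      k_range = k$k_range, train_fraction = k$train_fraction,
      seed = config$seed)
    rows <- lapply(res[!vapply(res, is.null, logical(1))], function(s) {
      data.frame(stratum = s$stratum, n_peaks = s$n_peaks,
                 k = as.integer(names(s$auc_by_k)), auc = unname(s$auc_by_k),
                 delta_auc = s$delta_auc, stringsAsFactors = FALSE)
    })
    tab <- if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(stratum = character(), n_peaks = integer(), k = integer(),
                 auc = numeric(), delta_auc = numeric())
    rownames(tab) <- NULL
    .write_tsv(tab, file.path(outdir, "kmer_specificity.tsv"))
    res
  })

  .stage("repeat_correlations", {
    cc <- config$correlation
    panel <- poly_tract_panel(peaks, genome, tss, gc_split = cc$gc_split,
                              tss_window = cc$tss_window,
                              n_shuffles = cc$n_shuffles,
                              n_subgroups = cc$n_subgroups,
                              seed = config$seed, method = cc$method)
    .write_tsv(panel, file.path(outdir, "poly_tract_panel.tsv"))
  })

  .stage("tss_profiles", {
    tc <- config$tss
    bound <- classify_tss(tss, peaks, window = tc$bound_window,
                          mode = tc$bound_mode)
    if (sum(bound) >= tc$n_subgroups) {
      gcp <- gc_metaprofile(tss[bound, , drop = FALSE], genome,
                            half_span = tc$half_span, window = tc$window,
                            n_subgroups = tc$n_subgroups, seed = config$seed)
      ip <- intensity_metaprofile(peaks, tss[bound, , drop = FALSE],
                                  half_span = tc$half_span,
                                  window = tc$window,
                                  n_subgroups = tc$n_subgroups,
                                  seed = config$seed)
      .write_tsv(as.data.frame(gcp), file.path(outdir, "tss_gc_profile.tsv"))
      .write_tsv(as.data.frame(ip),
                 file.path(outdir, "tss_intensity_profile.tsv"))
    } else {
      message("too few bound TSSs; TSS profiles skipped")
    }
  })

  .stage("methylation_profile", {
    if (!is.null(inputs$methylation) && nrow(inputs$methylation) > 0L) {
      mp <- methylation_metaprofile(peaks, inputs$methylation,
                                    half_span = config$methylation$half_span)
      .write_tsv(cbind(as.data.frame(mp), cpg_count = mp$cpg_counts),
                 file.path(outdir, "methylation_profile.tsv"))
    } else {
      message("no methylation track; stage skipped")
    }
  })

  .stage("equilibrium", {
    e <- config$equilibrium
    grid <- 10^seq(log10(e$grid_from), log10(e$grid_to),
                   length.out = e$grid_n)
    p_on <- equilibrium_parameters(DNAH_tot = e$dna_tot,
                                   DNAL_tot = e$dna_tot, tetramer = TRUE)
    p_off <- p_on
    p_off$tetramer <- FALSE
    write_sweep(sweep_myc_total(p_on, grid),
                file.path(outdir, "equilibrium_sweep_on.tsv"))
    write_sweep(sweep_myc_total(p_off, grid),
                file.path(outdir, "equilibrium_sweep_off.tsv"))
  })

  .stage("expression_table", {
    spec <- inputs$spec %||% synthetic_spec(seed = config$seed)
    .write_tsv(generate_expression_table(spec),
               file.path(outdir, "expression_table.tsv"))
  })

  .stage("manifest", {
    manifest <- list(
      package = "bimodalTF",
      package_version = as.character(utils::packageVersion("bimodalTF")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config = config[setdiff(names(config), "outdir")]
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(outdir)
}
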