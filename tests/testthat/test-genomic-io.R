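test_that("read_genome loads, uppercases, and validates FASTA records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr2 some description", "acgtn"), f)
  g <- read_genome(f)
  expect_identical(g, c(chr1 = "ACGT", chr2 = "ACGTN"))

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrR", "ACGR"), bad)  # IUPAC R is parseable but not allowed
  expect_error(read_genome(bad), "chrR")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c", "AC", ">c", "GT"), dup)
  expect_error(read_genome(dup), "duplicated")

  expect_error(read_genome(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("genome FASTA round-trips", {
  g <- c(chr1 = "ACGTACGTNNACGT", chr2 = "GGGGCCCCAAAATTTT")
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, f)
  expect_identical(read_genome(f), g)
})

test_that("read_peaks parses BED dialects and rejects bad records", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t110\tp1\t5.0", "chr1\t200\t300\tp2\t1.5"), f)
  p <- read_peaks(f, tf = "Otx2", stage = "ESC")
  expect_equal(p$start, c(10, 200))
  expect_equal(p$intensity, c(5, 1.5))
  expect_identical(attr(p, "tf_name"), "Otx2")

  # 3-column BED: intensity defaults to 0
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t110", f3)
  expect_equal(read_peaks(f3)$intensity, 0)

  # 4-column score dialect
  f4 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t110\t7.5", f4)
  expect_equal(read_peaks(f4, score_col = 4)$intensity, 7.5)

  # overlapping records are both retained (dedup is separate)
  fo <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t110\tp\t1", "chr1\t50\t150\tq\t2"), fo)
  expect_equal(nrow(read_peaks(fo)), 2)

  # start >= end rejected with a warning
  fb <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t50\tp\t1", "chr1\t10\t20\tq\t2"), fb)
  expect_warning(pb <- read_peaks(fb), "rejected")
  expect_equal(nrow(pb), 1)
})

test_that("peaks round-trip through BED bit-exactly", {
  p <- peak_set(c("chr2", "chr1", "chr1"), c(1000000, 10, 500),
                c(1000100, 110, 700), intensity = c(3.25, 5, 0),
                name = c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_peaks(p, f)
  p2 <- read_peaks(f)
  expect_identical(p2$chrom, p$chrom)
  expect_identical(p2$start, p$start)
  expect_identical(p2$end, p$end)
  expect_identical(p2$intensity, p$intensity)
})

test_that("centered_sequence returns exact windows or NA at boundaries", {
  genome <- c(chr1 = paste(rep("ACGT", 50), collapse = ""))  # 200 bp
  p <- peak_set("chr1", 10, 110)
  expect_identical(centered_sequence(p, genome, 100),
                   substr(genome[["chr1"]], 11, 110))
  # peak shorter than the window is omitted
  expect_true(is.na(centered_sequence(peak_set("chr1", 10, 90), genome, 100)))
  # window exits the chromosome
  expect_true(is.na(centered_sequence(peak_set("chr1", 110, 210), genome, 100)))
  expect_error(centered_sequence(peak_set("chrX", 10, 110), genome, 100),
               "absent")
  expect_error(peak_sequences(p, genome, width = 99), "width")
})

test_that("gc_content handles N exclusion and degenerate inputs", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("ANGC"), 2 / 3)
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content(""), "empty")
  expect_equal(gc_content(c("GGCC", "ATAT")), c(1, 0))
})

test_that("flanking_background places 100-bp windows off peak edges", {
  genome <- c(chr1 = strrep("A", 5000))
  p <- peak_set("chr1", 1000, 1100)
  bg <- flanking_background(p, genome)
  expect_equal(bg$start, c(800, 1200))
  expect_equal(bg$end, c(900, 1300))
  expect_true(all(bg$end - bg$start == 100))

  # two peaks 150 bp apart: the inter-peak candidates overlap a peak
  p2 <- peak_set("chr1", c(1000, 1250), c(1100, 1350))
  bg2 <- flanking_background(p2, genome)
  expect_equal(sort(bg2$start), c(800, 1450))

  # peak at chromosome start: only the right-side background survives
  p3 <- peak_set("chr1", 0, 100)
  bg3 <- flanking_background(p3, genome)
  expect_equal(bg3$start, 200)
})

test_that("flanking backgrounds never overlap any source peak", {
  set.seed(42)
  genome <- c(chr1 = strrep("C", 20000), chr2 = strrep("G", 8000))
  for (rep in 1:5) {
    n <- 30
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    start <- ifelse(chrom == "chr1", sample(0:19000, n), sample(0:7000, n))
    p <- peak_set(chrom, start, start + sample(100:600, n, replace = TRUE))
    bg <- flanking_background(p, genome)
    if (nrow(bg) == 0) next
    # exhaustive pairwise overlap check
    for (i in seq_len(nrow(bg))) {
      same <- p$chrom == bg$chrom[i]
      expect_false(any(p$start[same] < bg$end[i] & p$end[same] > bg$start[i]))
    }
  }
})

test_that("accessibility-matched background applies GC strata and overlap rules", {
  # chromosome with a known GC layout: AT block then GC block
  genome <- c(chr1 = paste0(strrep("AT", 1000), strrep("GC", 1000)))
  chip <- peak_set("chr1", 100, 200)
  atac <- peak_set("chr1", c(120, 500, 2500, 1950), c(220, 600, 2600, 2050))
  bg <- accessibility_matched_background(atac, chip, genome)
  # 120-220 overlaps chip -> out; 500-600 pure AT -> low; 2500-2600 pure GC
  # -> high; 1950-2050 straddles (GC 0.5) -> neither stratum
  expect_equal(nrow(bg), 2)
  expect_setequal(bg$stratum, c("low", "high"))
  expect_true(all(bg$end - bg$start == 100))
  expect_warning(
    accessibility_matched_background(peak_set("chr1", 1950, 2050), chip, genome),
    "empty")
})

test_that("deduplication keeps the leftmost peak of every overlap chain", {
  a <- peak_set("chr1", 10, 110, stage = "ESC")
  b <- peak_set("chr1", 50, 150, stage = "dEN")
  d <- deduplicate_across_stages(list(a, b))
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 10)
  expect_equal(d$end, 110)

  disj <- deduplicate_across_stages(list(peak_set("chr1", c(10, 300), c(110, 400))))
  expect_equal(nrow(disj), 2)

  # chain of three mutually-linked peaks -> single leftmost survivor
  chain <- peak_set("chr1", c(10, 80, 160), c(100, 170, 260))
  dc <- deduplicate_across_stages(list(chain))
  expect_equal(dc$start, 10)

  # brute-force comparison on random sets: connected overlap components
  set.seed(7)
  for (rep in 1:5) {
    st <- sample(0:2000, 25)
    ps <- peak_set("chr1", st, st + sample(50:300, 25, replace = TRUE))
    dd <- deduplicate_across_stages(list(ps))
    # brute force: union-find over all overlapping pairs
    n <- nrow(ps)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j && ps$start[i] < ps$end[j] && ps$end[i] > ps$start[j] &&
            comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    expected <- do.call(rbind, lapply(unique(comp), function(cc) {
      sub <- ps[comp == cc, ]
      sub[order(sub$start, sub$end), ][1, c("start", "end")]
    }))
    expected <- expected[order(expected$start), ]
    expect_equal(dd$start, expected$start)
    expect_equal(dd$end, expected$end)
    # no overlapping pairs remain
    expect_true(all(dd$start[-1] >= dd$end[-nrow(dd)]))
  }
})

test_that("nearest_peak_distance matches exhaustive pairwise minimum", {
  a <- peak_set("chr1", 90, 110)           # center 100
  b <- peak_set("chr1", c(290, 4990), c(310, 5010))  # centers 300, 5000
  expect_equal(nearest_peak_distance(a, b), 200)
  expect_equal(nearest_peak_distance(a, a), 0)
  expect_true(is.na(nearest_peak_distance(peak_set("chr9", 0, 10), b)))
  expect_error(nearest_peak_distance(a, b[0, ]), "empty")

  set.seed(3)
  for (rep in 1:5) {
    sa <- sample(0:100000, 40); sb <- sample(0:100000, 25)
    pa <- peak_set("chr1", sa, sa + 100)
    pb <- peak_set("chr1", sb, sb + 100)
    got <- nearest_peak_distance(pa, pb)
    brute <- vapply(peak_centers(pa), function(ca) {
      min(abs(ca - peak_centers(pb)))
    }, numeric(1))
    expect_equal(got, brute)
  }
})
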