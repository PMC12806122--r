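test_that("BED parsing maps fields, auto-names, and round-trips", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1", "chr2\t0\t50", "chr1\t300\t400\tp3\t7.5"), f)
  ps <- read_bed(f)
  expect_s3_class(ps, "PeakSet")
  expect_equal(ps$intervals$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(ps$intervals$start, c(100L, 0L, 300L))
  expect_equal(ps$intervals$end, c(200L, 50L, 400L))
  expect_equal(ps$intervals$name, c("p1", "peak_2", "p3"))

  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, out)
  back <- read_bed(out)
  expect_equal(back$intervals[c("chrom", "start", "end", "name")],
               ps$intervals[c("chrom", "start", "end", "name")])
})

test_that("BED parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t10", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\tx\t10"), f)
  expect_error(read_bed(f), "line 1.*non-integer")
  writeLines("chr1\t5", f)
  expect_error(read_bed(f), "line 1")
  writeLines(character(0), f)
  expect_length(read_bed(f), 0)
})

test_that("attach_sequences extracts, uppercases, and maps non-ACGT to N", {
  genome <- c(chr1 = "acgtRcgt")
  ps <- peak_set(data.frame(chrom = "chr1", start = 0L, end = 8L, name = "p1"))
  got <- attach_sequences(ps, genome)
  expect_equal(unname(got$sequences), "ACGTNCGT")
  expect_error(attach_sequences(
    peak_set(data.frame(chrom = "chr2", start = 0L, end = 4L, name = "p1")),
    genome), "chr2")
  expect_error(attach_sequences(
    peak_set(data.frame(chrom = "chr1", start = 0L, end = 40L, name = "p1")),
    genome), "exceeds")
})

test_that("JASPAR counts are pseudocounted and duplicate ids suffixed", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001 TFX",
    "A [ 8 0 0 0 ]", "C [ 0 8 0 0 ]", "G [ 0 0 8 0 ]", "T [ 0 0 0 8 ]",
    ">MA0001 TFX",
    "A [ 4 4 4 4 ]", "C [ 4 4 4 4 ]", "G [ 4 4 4 4 ]", "T [ 4 4 4 4 ]"), f)
  lib <- read_motifs(f, "jaspar", pseudocount = 1)
  expect_named(lib, c("MA0001", "MA0001_2"))
  # (c + 1) / (colsum + 4): counts (8,0,0,0) -> (9/12, 1/12, 1/12, 1/12)
  expect_equal(unname(lib$MA0001$prob[, 1]), c(9, 1, 1, 1) / 12)
  expect_equal(unname(lib$MA0001_2$prob[, 1]), rep(0.25, 4))
})

test_that("JASPAR dialect is closed under write/read", {
  set.seed(42)
  lib <- lapply(1:3, function(i) random_pwm(sprintf("R%d", i), width = 4 + i,
                                            seed = 100 + i, dominance = 0.8))
  lib <- unique_motif_ids(lib)
  f <- withr::local_tempfile(fileext = ".jaspar")
  write_motifs_jaspar(lib, f)
  back <- read_motifs(f, "jaspar", pseudocount = 0)
  for (id in names(lib))
    expect_equal(back[[id]]$prob, lib[[id]]$prob, tolerance = 1e-9)
})

test_that("Homer probability rows survive up to renormalization", {
  f <- withr::local_tempfile(fileext = ".motif")
  writeLines(c(">ACGT BATF(bZIP)/x 6.5",
               "0.7\t0.1\t0.1\t0.1",
               "0.1\t0.7\t0.1\t0.1",
               "0.1\t0.1\t0.7\t0.1",
               "0.1\t0.1\t0.1\t0.7"), f)
  lib <- read_motifs(f, "homer")
  expect_equal(names(lib), "BATF(bZIP)/x")
  expect_equal(lib[[1]]$tf_name, "BATF")
  expect_equal(unname(lib[[1]]$prob[, 1]), c(0.7, 0.1, 0.1, 0.1))
})

test_that("malformed motif files raise parse errors", {
  f <- withr::local_tempfile()
  writeLines(c(">M1", "A [ 0 0 ]", "C [ 0 0 ]", "G [ 0 0 ]", "T [ 0 0 ]"), f)
  expect_error(read_motifs(f, "jaspar", pseudocount = 0), "zero-sum|width|columns")
  writeLines(c(">M1", "A [ -1 2 3 4 ]", "C [ 1 1 1 1 ]",
               "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]"), f)
  expect_error(read_motifs(f, "jaspar"), "negative")
  writeLines(c(">ACGT name", "0.25 0.25 0.25", "0.25 0.25 0.25 0.25",
               "0.25 0.25 0.25 0.25", "0.25 0.25 0.25 0.25"), f)
  expect_error(read_motifs(f, "homer"), "need 4")
})

test_that("GenBank output lays out features 1-based inclusive and round-trips", {
  lib <- toy_library()
  cfg <- design_config(target_site_bp = 16, core_promoter_seq = strrep("C", 60))
  d <- build_promoter(lib$TFA, lib, cfg)           # 8-mer site, 2 repeats
  expect_equal(d$repeats, 2L)
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(d, f)
  gb <- read_genbank(f)
  expect_equal(nchar(gb$sequence), 2 * 8 + 3 + 60)
  expect_equal(gb$sequence, d$full_seq)
  expect_equal(nrow(gb$features), 4)   # 2 sites + 1 spacer + 1 promoter
  sites <- gb$features[gb$features$key == "misc_binding", ]
  for (i in seq_len(nrow(sites)))
    expect_equal(substr(gb$sequence, sites$start[i] + 1, sites$end[i]), d$site_seq)
  expect_equal(gb$features$key[nrow(gb$features)], "promoter")
})

test_that("writing an empty design is refused", {
  lib <- toy_library()
  d <- build_promoter(lib$TFA, lib, design_config(target_site_bp = 16,
                                                  core_promoter_seq = strrep("C", 20)))
  d$repeats <- 0L
  expect_error(write_genbank(d, withr::local_tempfile()), "empty design")
})

test_that("count matrix TSVs round-trip with condition labels", {
  m <- matrix(c(10L, 0L, 3L, 40L, 2L, 1L, 9L, 8L), 4, 2,
              dimnames = list(paste0("pk", 1:4), c("s1", "s2")))
  cm <- count_matrix(m, c(s1 = "target", s2 = "reference"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, f1, f2)
  back <- read_count_matrix(f1, f2)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$condition, cm$condition)
  expect_error(count_matrix(m, c(s1 = "target", s2 = "target")),
               "per condition")
})
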