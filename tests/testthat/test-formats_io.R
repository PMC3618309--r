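test_that("signal table round-trips and skips non-autosomal probes", {
  map <- flat_map(3)
  samples <- list(
    list(sample_id = "S1", breed = "A", lrr = c(0.1, -0.2, 0.30001),
         baf = c(0, 0.5, NA)),
    list(sample_id = "S2", breed = "B", lrr = c(-0.5, 0, 0.25),
         baf = c(1, 0.5, 0)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signal_table(map, samples, f)
  rt <- read_signal_table(f)
  expect_equal(nrow(rt$map), 3)
  expect_length(rt$samples, 2)
  expect_equal(rt$samples[[1]]$lrr, samples[[1]]$lrr, tolerance = 1e-6)
  expect_equal(rt$samples[[2]]$baf, samples[[2]]$baf, tolerance = 1e-6)
  expect_identical(rt$samples[[1]]$sample_id, "S1")

  # a sex-chromosome probe is excluded and counted
  lines <- readLines(f)
  lines <- append(lines, sub("^S1\tp001\t1", "S1\tpX\tX", lines[2]), after = 1)
  writeLines(lines, f)
  expect_message(rt2 <- read_signal_table(f), "skipped 1")
  expect_equal(rt2$n_skipped, 1)
  expect_equal(nrow(rt2$map), 3)
})

test_that("inconsistent probe sets across samples are reported", {
  map <- flat_map(2)
  samples <- list(list(sample_id = "S1", breed = "A", lrr = c(0, 0),
                       baf = c(0, 1)),
                  list(sample_id = "S2", breed = "A", lrr = c(0, 0),
                       baf = c(0, 1)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signal_table(map, samples, f)
  lines <- readLines(f)
  lines[5] <- sub("p002", "p999", lines[5])  # S2's second probe renamed
  writeLines(lines, f)
  expect_error(read_signal_table(f), "divergent probe: p002")
})

test_that("caller dialects parse, reject cn=2 and round-trip", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1:1000-2000 numsnp=10 length=1001 state2,cn=1 S1 startsnp=rs1 endsnp=rs2 conf=20.5",
    "chr2:500-900 numsnp=4 length=401 state5,cn=3 S1 startsnp=rs3 endsnp=rs4 conf=8.25",
    "chr3:100-200 numsnp=3 length=101 state3,cn=2 S2 startsnp=rs5 endsnp=rs6 conf=5.0"),
    f)
  expect_warning(calls <- read_caller_calls(f, "penncnv"), "cn=2")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$cn, c(1L, 3L))
  expect_equal(calls$bf, c(20.5, 8.25))
  expect_true(all(calls$source == "A"))

  fq <- withr::local_tempfile()
  df <- data.frame(`Sample Name` = "S1", Chromosome = 7,
                   `Start Position (bp)` = 100, `End Position (bp)` = 5000,
                   `Copy Number` = 3, `No. Probes` = 6,
                   `Log Bayes Factor` = 15, check.names = FALSE)
  write.table(df, fq, sep = "\t", quote = FALSE, row.names = FALSE)
  q <- read_caller_calls(fq, "quantisnp")
  expect_equal(q$cn, 3L)
  expect_equal(q$bf, 15)
  expect_identical(q$source, "B")

  # writer -> reader round trip, both dialects
  for (d in c("penncnv", "quantisnp")) {
    fd <- withr::local_tempfile()
    write_caller_calls(calls, fd, d)
    back <- read_caller_calls(fd, d)
    expect_equal(back[, c("chrom", "start_bp", "end_bp", "cn", "n_probes")],
                 calls[, c("chrom", "start_bp", "end_bp", "cn", "n_probes")],
                 ignore_attr = TRUE)
    expect_equal(back$bf, calls$bf, tolerance = 1e-3)
  }

  # empty file -> empty call list; negative conf -> error
  fe <- withr::local_tempfile(); file.create(fe)
  expect_equal(nrow(read_caller_calls(fe, "penncnv")), 0)
  writeLines("chr1:1-9 numsnp=3 length=9 state2,cn=1 S1 startsnp=a endsnp=b conf=-3",
             fe)
  expect_error(read_caller_calls(fe, "penncnv"), "negative")
})

test_that("BED and GFF3 features normalize to 1-based inclusive", {
  fb <- withr::local_tempfile()
  writeLines(c("1\t99\t200", "2\t0\t50", "2\t0\t50"), fb)
  feats <- read_features(fb, "bed", "SD")
  expect_equal(feats$start_bp, c(100, 1, 1))
  expect_equal(feats$end_bp, c(200, 50, 50))
  expect_equal(nrow(feats), 3)  # duplicates retained
  # BED length is preserved by the convention shift
  expect_equal(feats$end_bp - feats$start_bp + 1, c(101, 50, 50) + c(0, 0, 0))

  fg <- withr::local_tempfile()
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t100\t200\t.\t+\t.\tID=G1;biotype=miRNA",
               "1\tsrc\tgene\t300\t400\t.\t+\t.\tID=G2"), fg)
  g <- read_features(fg, "gff3", "gene")
  expect_equal(g$start_bp, c(100, 300))
  expect_equal(g$biotype, c("miRNA", "other"))
  expect_equal(g$gene_id, c("G1", "G2"))

  writeLines("1\t50\t20", fb)
  expect_error(read_features(fb, "bed", "SD"), "line 1")
})

test_that("CNV and CNVR tables round-trip field-for-field", {
  calls <- cnv_calls(sample_id = c("S2", "S1"), chrom = c(2L, 1L),
                     start_bp = c(100, 5000), end_bp = c(900, 9000),
                     cn = c(1L, 4L), n_probes = c(5L, 7L),
                     bf = c(18.5, 31.25), source = "consensus")
  f <- withr::local_tempfile()
  write_cnv_table(calls, f)
  back <- read_cnv_table(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$chrom, c(1L, 2L))  # sorted by chrom, start
  expect_setequal(back$bf, calls$bf)

  regions <- build_cnvrs(calls, cohort_n = 4L)
  fr <- withr::local_tempfile()
  write_cnvr_table(regions, fr)
  rback <- read_cnvr_table(fr)
  expect_equal(rback$start_bp, regions$start_bp)
  expect_equal(rback$category, regions$category)

  # empty input -> header only
  write_cnv_table(cnv_calls(), f)
  expect_equal(nrow(read_cnv_table(f)), 0)
})
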