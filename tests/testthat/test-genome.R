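test_that("probe grids tile the genome at the stated period", {
  g <- genome_spec(1050)
  grid <- build_probe_grid(g)
  expect_equal(grid$count, 10)
  expect_equal(grid$starts, seq(0, 945, by = 105))

  ## a 43,450-feature array geometry: count = floor(length / period)
  big <- build_probe_grid(genome_spec(43450 * 105))
  expect_equal(big$count, 43450)

  ## non-circular axis shorter than two periods holds a single probe
  tiny <- build_probe_grid(genome_spec(104, circular = FALSE))
  expect_equal(tiny$count, 1)
  expect_equal(tiny$starts, 0)

  expect_error(build_probe_grid(genome_spec(50), probe_length = 60),
               "probe_length")
  expect_equal(probe_coverage(grid), 60 / 105, tolerance = 1e-12)
})

test_that("minimum fragment-probe overlap matches exhaustive enumeration", {
  grid <- build_probe_grid(genome_spec(1e5))
  ## a ~250-bp ChIP fragment always touches >= 2 probes; a probe-sized
  ## fragment can land on exactly one; a 1-bp fragment fits in the gap
  expect_equal(min_probes_overlapped(250, grid), 2)
  expect_equal(min_probes_overlapped(60, grid), 1)
  expect_equal(min_probes_overlapped(1, grid), 0)
  for (len in c(1, 44, 45, 46, 60, 104, 105, 150, 250, 251, 500)) {
    expect_equal(min_probes_overlapped(len, grid),
                 oracle_min_overlap(len),
                 info = paste("fragment length", len))
  }
  ## denser custom geometry
  g2 <- build_probe_grid(genome_spec(1e4), probe_length = 25, period = 50)
  for (len in c(1, 26, 75, 130)) {
    expect_equal(min_probes_overlapped(len, g2),
                 oracle_min_overlap(len, 25, 50))
  }
})

test_that("wrap-around intervals split at the origin of circular genomes", {
  g <- genome_spec(1000)
  norm <- occutile:::normalize_interval(900, 1100, g)
  expect_equal(norm$start, c(900, 0))
  expect_equal(norm$end, c(1000, 100))
  plain <- occutile:::normalize_interval(100, 400, g)
  expect_equal(nrow(plain), 1)
  expect_error(
    occutile:::normalize_interval(900, 1100, genome_spec(1000, FALSE)),
    "linear")
})

test_that("genes link to prophages by overlap, with containment flagged", {
  g <- genome_spec(5000)
  genes <- data.frame(name = c("inA", "outB", "edgeC"),
                      start = c(100, 1500, 950), end = c(400, 1800, 1200))
  pp <- data.frame(name = "e14", start = 0, end = 1000)
  ann <- genome_annotation(genes, pp, g)
  expect_equal(ann$genes$prophage, c("e14", NA, "e14"))
  expect_equal(ann$genes$contained, c(TRUE, FALSE, FALSE))
})

test_that("annotation validation rejects bad input", {
  g <- genome_spec(1000)
  expect_error(genome_annotation(
    data.frame(name = c("a", "a"), start = c(0, 10), end = c(5, 20)),
    data.frame(name = character(), start = numeric(), end = numeric()),
    g), "duplicate gene")
  expect_error(genome_annotation(
    data.frame(name = "a", start = 900, end = 1100),
    data.frame(name = character(), start = numeric(), end = numeric()),
    g), "bounds")
  expect_error(genome_annotation(
    data.frame(name = "a", start = 0, end = 10),
    data.frame(name = c("p", "q"), start = c(0, 50), end = c(100, 120)),
    g), "overlap")
})

test_that("annotation round-trips bit-exactly through every dialect", {
  g <- genome_spec(10000)
  genes <- data.frame(name = c("gA", "gB"), start = c(100, 1500),
                      end = c(400, 1800), strand = c("+", "-"))
  pp <- data.frame(name = c("e14", "Rac"), start = c(0, 5000),
                   end = c(1000, 7000))
  ann <- genome_annotation(genes, pp, g)

  tsv_g <- withr::local_tempfile(fileext = ".tsv")
  tsv_p <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, tsv_g, tsv_p)
  back <- read_annotation(tsv_g, tsv_p, g)
  expect_equal(back$genes[c("name", "start", "end", "strand")],
               ann$genes[c("name", "start", "end", "strand")])
  expect_equal(back$prophages, ann$prophages)

  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_annotation(ann, gff, bed)
  back2 <- read_annotation(gff, bed, g)
  expect_equal(back2$genes[c("name", "start", "end", "strand")],
               ann$genes[c("name", "start", "end", "strand")])
  expect_equal(back2$prophages, ann$prophages)

  ## GFF3 is 1-based inclusive on disk: [100, 400) must be written 101..400
  raw <- readLines(gff)
  rec <- grep("\tgene\t", raw, value = TRUE)[1]
  expect_match(rec, "\t101\t400\t")
})

test_that("site tracks read from BED and validate scores", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("genome\t10\t50\ts1\t3", "genome\t100\t140\ts2\t7"), bed)
  tr <- read_sites(bed, label = "promoter")
  expect_equal(tr$sites$start, c(10, 100))
  expect_equal(tr$sites$end, c(50, 140))
  expect_error(site_track("x", data.frame(start = 1, end = 5, score = -1)),
               "score")
  expect_error(site_track("x", data.frame(start = 5, end = 5)), "start")
})
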