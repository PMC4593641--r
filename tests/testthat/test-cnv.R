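bed2gr <- function(chrom, start, end, ...)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), ...)

writeCNVLines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("chromosome\tstart\tend\ttype\tphenotype\tclassification",
               lines), path)
  path
}

test_that("the CNV table reader types, validates and measures records", {
  gr <- readCNVTable(writeCNVLines(
    "chr1\t1000\t5000\tDEL\tdevelopmental delay\tBENIGN"))
  expect_length(gr, 1L)
  expect_equal(BiocGenerics::width(gr), 4000L)        # length = end - start
  expect_identical(gr$type, "DEL")
  expect_identical(gr$label, "BENIGN")
  expect_true(is.na(gr$patient))

  # optional 7th patient column; empty classification for inference mode
  gr7 <- readCNVTable(writeCNVLines(
    c("chr1\t10\t20\tDUP\tseizures\t\tP01",
      "chr2\t10\t30\tDEL\tautism\tHARMFUL\tP02")))
  expect_identical(gr7$patient, c("P01", "P02"))
  expect_identical(gr7$label, c(NA, "HARMFUL"))

  # empty file with header
  expect_length(readCNVTable(writeCNVLines(character(0))), 0L)

  # malformed rows are rejected with their line number
  expect_error(readCNVTable(writeCNVLines(
    c("chr1\t10\t20\tDEL\tx\tBENIGN", "chr1\tten\t20\tDEL\tx\tBENIGN"))),
    "line 3")
  expect_error(readCNVTable(writeCNVLines("chr1\t50\t20\tDEL\tx\tBENIGN")),
    "end must exceed start")
  expect_error(readCNVTable(writeCNVLines("chr1\t10\t20\tLOSS\tx\tBENIGN")),
    "DUP or DEL")
  expect_error(readCNVTable(writeCNVLines("chr1\t10\t20\tDEL\tx\tMAYBE")),
    "classification")
})

test_that("CNV-gene assignment uses any 1-bp overlap, in positional order", {
  genes <- bed2gr(c("chr1", "chr1", "chr1"), c(100L, 300L, 150L),
                  c(200L, 400L, 260L),
                  gene_id = c("gA", "gB", "gC"))
  # gene fully inside the CNV is included (gC overlaps partially)
  expect_identical(mapCNVGenes(bed2gr("chr1", 90L, 210L), genes),
                   c("gA", "gC"))
  expect_identical(mapCNVGenes(bed2gr("chr1", 90L, 145L), genes), "gA")
  # exactly 1 bp of overlap is included; touching is not
  expect_identical(mapCNVGenes(bed2gr("chr1", 199L, 300L), genes), c("gA", "gC"))
  expect_identical(mapCNVGenes(bed2gr("chr1", 200L, 250L), genes), "gC")
  # positional order
  expect_identical(mapCNVGenes(bed2gr("chr1", 0L, 1000L), genes),
                   c("gA", "gC", "gB"))
  expect_warning(out <- mapCNVGenes(bed2gr("chrZ", 0L, 10L), genes),
                 "chrZ")
  expect_identical(out, character(0))

  # random fixtures vs the quadratic oracle
  set.seed(21)
  for (i in 1:12) {
    gdf <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                      start = sample(0:900, 20))
    gdf$end <- gdf$start + sample(10:120, 20, TRUE)
    gdf$gene_id <- sprintf("g%02d", 1:20)
    ggr <- bed2gr(gdf$chrom, gdf$start, gdf$end, gene_id = gdf$gene_id)
    cnv <- list(chrom = sample(c("chr1", "chr2"), 1),
                start = sample(0:800, 1))
    cnv$end <- cnv$start + sample(50:400, 1)
    expect_identical(
      mapCNVGenes(bed2gr(cnv$chrom, cnv$start, cnv$end), ggr),
      as.character(oracleCNVGenes(cnv, gdf)))
  }
})

test_that("study-region merging unions touching intervals and is idempotent", {
  m <- mergeStudyRegions(bed2gr(c("chr1", "chr1"), c(10L, 15L), c(20L, 30L)))
  expect_equal(BiocGenerics::start(m) - 1L, 10L)
  expect_equal(BiocGenerics::end(m), 30L)
  # touching half-open intervals merge; disjoint stay apart
  m2 <- mergeStudyRegions(bed2gr(c("chr1", "chr1", "chr1"),
                                 c(10L, 20L, 40L), c(20L, 30L, 50L)))
  expect_length(m2, 2L)
  expect_identical(mergeStudyRegions(m2), m2)

  set.seed(33)
  for (i in 1:10) {
    df <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                     start = sample(0:500, 50, TRUE))
    df$end <- df$start + sample(5:80, 50, TRUE)
    m <- mergeStudyRegions(bed2gr(df$chrom, df$start, df$end))
    got <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(m)),
                      start = BiocGenerics::start(m) - 1L,
                      end = BiocGenerics::end(m))
    got <- got[order(got$chrom, got$start), ]
    o <- oracleMerge(df)
    o <- o[order(o$chrom, o$start), ]
    expect_equal(got, o, ignore_attr = TRUE)
    # total covered bases preserved by merging
    expect_equal(sum(BiocGenerics::width(m)), sum(o$end - o$start))
  }
})

test_that("benign-overlap frequency gates at half the CNV length and sums", {
  cnv <- bed2gr("chr1", 1000L, 2000L, type = "DEL")
  asSet <- function(...) {
    studies <- list(...)
    out <- GenomicRanges::GRangesList(lapply(studies, function(s)
      mergeStudyRegions(bed2gr(s$chrom, s$start, s$end))))
    names(out) <- sprintf("s%d", seq_along(studies))
    out
  }
  # identical region: exactly 1
  expect_equal(dgvFrequency(cnv, asSet(
    data.frame(chrom = "chr1", start = 1000L, end = 2000L))), 1.0)
  # 40% overlap is below the gate
  expect_equal(dgvFrequency(cnv, asSet(
    data.frame(chrom = "chr1", start = 1000L, end = 1400L))), 0.0)
  # exactly 50% counts (ties included)
  expect_equal(dgvFrequency(cnv, asSet(
    data.frame(chrom = "chr1", start = 1000L, end = 1500L))), 0.5)
  # two studies at 60% each sum to 1.2
  two <- asSet(data.frame(chrom = "chr1", start = 1000L, end = 1600L),
               data.frame(chrom = "chr1", start = 1400L, end = 2000L))
  expect_equal(dgvFrequency(cnv, two), 1.2)
  # monotone in added studies
  expect_gte(dgvFrequency(cnv, two),
             dgvFrequency(cnv, two[1]))

  # random fixtures vs the quadratic oracle
  set.seed(8)
  for (i in 1:10) {
    studies <- lapply(1:3, function(s) {
      df <- data.frame(chrom = "chr1", start = sample(0:1500, 8))
      df$end <- df$start + sample(100:900, 8, TRUE)
      df
    })
    sset <- do.call(asSet, studies)
    q <- list(chrom = "chr1", start = sample(0:1200, 1))
    q$end <- q$start + sample(200:800, 1)
    expect_equal(
      dgvFrequency(bed2gr(q$chrom, q$start, q$end), sset),
      oracleDGVFreq(q, studies))
  }
})
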