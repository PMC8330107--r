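test_that("BED domains are parsed, sorted and validated", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100000\t200000\tB",
               "chr1\t0\t100000\tA",
               "chr2\t0\t50000\tC"), bed)
  d <- readDomains(bed)
  expect_s4_class(d, "GRanges")
  expect_equal(names(d), c("A", "B", "C"))  # sorted genome order
  expect_equal(GenomicRanges::start(d["A"]), 1)   # 0-based BED -> 1-based
  expect_equal(GenomicRanges::end(d["A"]), 100000)

  over <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50\t150"), over)
  expect_error(readDomains(over), "overlapping",
               class = "chromda_validation_error")

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_length(readDomains(empty), 0)
})

test_that("gene TSS follows the strand convention and duplicates are rejected", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\tstart\tend",
               "gplus\tchr1\t+\t1000\t2000",
               "gminus\tchr1\t-\t1000\t2000"), tsv)
  g <- readGenes(tsv)
  # 0-based TSS: 1000 for + (interval start), 1999 for - (end - 1)
  expect_equal(g["gplus"]$tss - 1, 1000)
  expect_equal(g["gminus"]$tss - 1, 1999)
  expect_equal(g["gplus"]$gene_end, 2000)   # 3' end of a + gene
  expect_equal(g["gminus"]$gene_end - 1, 1000)

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\tstart\tend",
               "g1\tchr1\t+\t0\t10", "g1\tchr1\t+\t20\t30"), dup)
  expect_error(readGenes(dup), "duplicated",
               class = "chromda_validation_error")

  nostrand <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\tstart\tend",
               "g1\tchr1\t.\t0\t10"), nostrand)
  expect_error(readGenes(nostrand), "strand",
               class = "chromda_validation_error")
})

test_that("gene-to-domain assignment: TSS rule, 3' fallback, boundaries", {
  domains <- domainsFromBed("chr1", c(0, 200), c(100, 300), c("d1", "d2"))
  genes <- genesFromBed(
    c("inD1", "gapRescue", "lost", "atStart", "atEnd"),
    rep("chr1", 5), rep("+", 5),
    start0 = c(50, 150, 120, 0, 100),
    end0   = c(80, 250, 180, 30, 140))
  map <- assignGenesToDomains(genes, domains)
  expect_equal(map[["d1"]], c("atStart", "inD1"))   # TSS at domain start stays
  expect_true("gapRescue" %in% map[["d2"]])          # 3' end inside d2
  expect_true("lost" %in% attr(map, "unassigned"))   # fully in the gap
  expect_false("atEnd" %in% unlist(map))             # TSS at end-exclusive bound
  # order invariance and idempotence
  map2 <- assignGenesToDomains(genes[sample(length(genes))], domains)
  expect_equal(lapply(map, identity), lapply(map2, identity))
})

test_that("domain size filter keeps [minGenes, 99th percentile]", {
  map <- list(a = paste0("g", 1:2), b = paste0("h", 1:3), c = paste0("k", 1:5))
  out <- filterDomains(map, minGenes = 3)
  expect_setequal(names(out), c("b", "c"))

  # 100 domains, one extreme count above the interpolated 99th percentile
  set.seed(1)
  counts <- c(sample(3:8, 99, replace = TRUE), 60)
  big <- lapply(seq_along(counts), function(i)
    sprintf("d%d_g%d", i, seq_len(counts[i])))
  names(big) <- sprintf("dom%03d", seq_along(big))
  cap <- quantile(counts, 0.99, type = 1)  # brute-force empirical oracle
  kept <- filterDomains(big)
  expect_setequal(names(kept),
                  names(big)[counts >= 3 & counts <= cap])
  expect_false("dom100" %in% names(kept))

  all3 <- list(x = paste0("a", 1:3), y = paste0("b", 1:3))
  expect_length(filterDomains(all3), 2)
  expect_error(filterDomains(list(z = "g1")), "no testable",
               class = "chromda_validation_error")
})

test_that("coverage filter implements the 5-read/80%-of-samples rule", {
  m <- rbind(
    keep9of10 = c(rep(10, 9), 0),
    drop7of10 = c(rep(10, 7), 0, 0, 0),
    allzero   = rep(0, 10),
    boundary  = c(rep(5, 8), 4, 4)   # exactly 80% at exactly 5 reads
  )
  colnames(m) <- paste0("s", 1:10)
  ds <- ExpressionData(m, rep(c("A", "B"), each = 5))
  out <- filterGenesByCoverage(ds)
  expect_setequal(rownames(out), c("keep9of10", "boundary"))
  # idempotence
  expect_equal(rownames(filterGenesByCoverage(out)), rownames(out))
})

test_that("quantile normalization equalizes distributions and matches oracles", {
  # permuted columns become identical after normalization
  set.seed(3)
  a <- rnorm(25)
  x <- cbind(s1 = a, s2 = sample(a), s3 = sample(a))
  qn <- quantileNormalize(x)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]))
  expect_equal(qn[, 1][order(x[, 1])], qn[, 2][order(x[, 2])])

  # identical columns are unchanged
  const <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(quantileNormalize(const), const)

  # 3x3 toy vs the brute-force rank-mean oracle (with a tie)
  toy <- matrix(c(5, 2, 3,
                  4, 1, 4,
                  3, 4, 6), nrow = 3, byrow = FALSE)
  expect_equal(quantileNormalize(toy), qnormOracle(toy), tolerance = 1e-12)

  # property: column-sorted vectors pairwise equal to machine precision
  for (i in 1:5) {
    set.seed(i)
    r <- matrix(rexp(60), 12, 5)
    q <- quantileNormalize(r)
    srt <- apply(q, 2, sort)
    expect_lt(max(abs(srt - srt[, 1])), 1e-12)
  }

  # independent cross-check against limma on tie-free input
  skip_if_not_installed("limma")
  set.seed(9)
  z <- matrix(rnorm(40), 10, 4)
  expect_equal(unname(quantileNormalize(z)),
               unname(limma::normalizeQuantiles(z)), tolerance = 1e-10)
})
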