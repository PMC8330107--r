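test_that("artificial partitions span midpoint-to-midpoint and straddle one boundary", {
  d <- domainsFromBed("chr1", c(0, 100, 200), c(100, 200, 300))
  art <- artificialPartition(d)
  expect_length(art, 2)  # 3 real domains -> 2 artificial
  # [0,100)+[100,200) -> artificial [50,150) in BED coordinates
  expect_equal(GenomicRanges::start(art)[1] - 1, 50)
  expect_equal(GenomicRanges::end(art)[1], 150)
  # each artificial domain straddles exactly one real boundary
  bounds <- GenomicRanges::end(d)[-length(d)]  # internal boundaries
  for (i in seq_along(art)) {
    inside <- bounds > GenomicRanges::start(art)[i] &
      bounds < GenomicRanges::end(art)[i]
    expect_equal(sum(inside), 1)
  }
  # a single-domain chromosome contributes none
  d2 <- suppressWarnings(c(d, domainsFromBed("chr2", 0, 100, "solo")))
  expect_length(artificialPartition(d2), 2)
})

test_that("artificial domains with single-origin genes are excluded", {
  d <- domainsFromBed("chr1", c(0, 100), c(100, 200), c("r1", "r2"))
  # all genes sit left of the real boundary (inside r1's half)
  gLeft <- genesFromBed(paste0("g", 1:3), rep("chr1", 3), rep("+", 3),
                        c(55, 65, 75), c(60, 70, 80))
  expect_length(artificialPartition(d, gLeft), 0)
  # genes on both sides of the boundary keep the artificial domain
  gBoth <- genesFromBed(paste0("h", 1:2), rep("chr1", 2), rep("+", 2),
                        c(60, 120), c(70, 130))
  expect_length(artificialPartition(d, gBoth), 1)
})

test_that("shared boundary ratio applies the tolerance-radius rule", {
  a <- domainsFromBed("chr1", c(0, 400000, 800000),
                      c(400000, 800000, 1200000))
  expect_equal(sharedBoundaryRatio(a, a), 1)
  shift3 <- GenomicRanges::shift(a, 3 * 40000)
  expect_equal(sharedBoundaryRatio(a, shift3), 0)
  shift2 <- GenomicRanges::shift(a, 2 * 40000)   # exactly at the radius
  expect_equal(sharedBoundaryRatio(a, shift2), 1)
  expect_error(sharedBoundaryRatio(a, a[0]), class = "chromda_validation_error")
})

test_that("immune domains are flagged at the reference 0.05-quantile", {
  set.seed(61)
  nS <- 40
  purity <- runif(nS, 0.3, 0.9)
  names(purity) <- sprintf("s%02d", 1:nS)
  # 40 domains x 3 genes; one domain's genes are exact negatives of purity
  nDom <- 40
  gid <- sprintf("g%03d", 1:(3 * nDom))
  m <- matrix(10^rnorm(3 * nDom * nS, 2, 0.3), nrow = 3 * nDom,
              dimnames = list(gid, names(purity)))
  m[1:3, ] <- matrix(rep(10^(3 - 2 * purity), each = 3), nrow = 3)
  map <- split(gid, rep(sprintf("d%02d", 1:nDom), each = 3))
  ds <- ExpressionData(m, rep(c("A", "B"), each = nS / 2))
  fl <- flagImmuneDomains(ds, map, purity)
  expect_true(fl$immune[fl$domain_id == "d01"])
  expect_equal(fl$purity_cor[fl$domain_id == "d01"], -1, tolerance = 1e-3)
  # with continuous untied correlations, ~5% of reference domains flagged
  expect_lte(sum(fl$immune), ceiling(0.05 * nDom) + 1)
  expect_gte(sum(fl$immune), 1)
  # flagged domains are exactly those at or below the threshold
  thr <- attr(fl, "threshold")
  expect_equal(fl$immune, fl$purity_cor <= thr)
  expect_error(flagImmuneDomains(ds, map, purity[1:10]),
               class = "chromda_validation_error")
})

test_that("family networks count co-domain edges and beat a dispersed null", {
  # 4 domains x 4 genes on one chromosome
  gid <- sprintf("g%02d", 1:16)
  genes <- genesFromBed(gid, rep("chr1", 16), rep("+", 16),
                        seq(0, by = 100, length.out = 16) + 10,
                        seq(0, by = 100, length.out = 16) + 60)
  domains <- domainsFromBed("chr1", seq(0, 1200, by = 400),
                            seq(400, 1600, by = 400))
  map <- assignGenesToDomains(genes, domains)
  # clustered family: 3 of the 4 genes of domain 1
  families <- structure(c(rep("clustered", 3), rep("spread", 4),
                          rep("other", 9)),
                        names = c(gid[1:3], gid[c(4, 8, 12, 16)], gid[c(5:7, 9:11, 13:15)]))
  fe <- familyNetworkEnrichment(map, genes, families, nPerm = 50, seed = 3)
  clus <- fe[fe$family == "clustered", ]
  expect_equal(clus$observed_edges, 3)  # C(3,2) in one qualifying domain
  # spread family: one gene per domain, never >= 50% of a domain
  expect_equal(fe$observed_edges[fe$family == "spread"], 0)
  expect_gt(clus$observed_edges, clus$expected_edges)
  # brute-force pair enumeration oracle for the observed count
  members <- names(families)[families == "clustered"]
  oracle <- 0
  for (d in names(map)) {
    k <- sum(map[[d]] %in% members)
    if (k >= 2 && k / length(map[[d]]) >= 0.5) oracle <- oracle + choose(k, 2)
  }
  expect_equal(clus$observed_edges, oracle)
})

test_that("conserved regions require reciprocal overlap and shared genes", {
  genes <- genesFromBed(sprintf("g%02d", 1:8), rep("chr1", 8), rep("+", 8),
                        seq(100, by = 100, length.out = 8),
                        seq(150, by = 100, length.out = 8))
  domA <- domainsFromBed("chr1", 0, 900, "a1")
  domB <- domainsFromBed("chr1", 50, 950, "b1")   # ~89% reciprocal overlap
  domC <- domainsFromBed("chr1", 500, 1400, "c1") # < 80% overlap with A
  r2 <- conservedRegions(list(ds1 = domA, ds2 = domB), genes)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_datasets, 2)
  expect_gte(r2$n_genes, 3)
  expect_equal(r2$start, 1)     # smallest start of the matched domains
  expect_equal(r2$end, 950)     # largest end
  none <- conservedRegions(list(ds1 = domA, ds2 = domC), genes)
  expect_equal(nrow(none), 0)
  # five datasets sharing one domain -> support 5
  sets <- lapply(1:5, function(i) domainsFromBed("chr1", 0, 900, "x"))
  names(sets) <- paste0("ds", 1:5)
  r5 <- conservedRegions(sets, genes)
  expect_equal(nrow(r5), 1)
  expect_equal(r5$n_datasets, 5)
  # hand-enumerated intersect genes: TSS within [0, 900) in every dataset
  expect_equal(r5$n_genes, sum(genes$tss <= 900))
})
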