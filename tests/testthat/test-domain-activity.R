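test_that("domain mFC is the mean of member fold-changes", {
  lfc <- c(a = 1, b = 1, c = 1, d = 2, e = -2, f = 0.4, g = -1.1, h = 3)
  map <- list(d1 = c("a", "b", "c"), d2 = c("d", "e"),
              d3 = c("f", "g", "h"))
  mfc <- domainMFC(lfc, map)
  expect_equal(unname(mfc["d1"]), 1)
  expect_equal(unname(mfc["d2"]), 0)
  expect_equal(unname(mfc["d3"]), mean(c(0.4, -1.1, 3)))
  expect_warning(domainMFC(lfc, c(map, list(d4 = "missing"))), "excluded")
})

test_that("domain mCor averages all unordered pairwise correlations", {
  s <- 8
  set.seed(12)
  base <- rnorm(s)
  m <- rbind(g1 = base, g2 = 2 * base + 3, g3 = -0.5 * base + 1,
             g4 = rnorm(s), g5 = rnorm(s), g6 = rep(2, s))
  map <- list(ident = c("g1", "g2"), mixed = c("g1", "g4", "g5"),
              withConst = c("g1", "g2", "g6"))
  mcor <- domainMCor(m, map)
  expect_equal(unname(mcor["ident"]), 1, tolerance = 1e-12)
  # brute-force oracle on the 3-gene domain
  oracle <- mean(c(cor(m["g1", ], m["g4", ]), cor(m["g1", ], m["g5", ]),
                   cor(m["g4", ], m["g5", ])))
  expect_equal(unname(mcor["mixed"]), oracle, tolerance = 1e-12)
  # zero-variance gene: its pairs are skipped, not imputed
  expect_equal(unname(mcor["withConst"]), 1, tolerance = 1e-12)
  # perfectly anti/uncorrelated trio centers near 0
  m2 <- rbind(x = c(1, 0, -1, 0), y = c(0, 1, 0, -1), z = c(1, 0, 1, -2))
  expect_lt(abs(domainMCor(m2, list(d = c("x", "y")))["d"]), 1e-12)
})

test_that("empirical mFC p values sit on the pseudo-count grid, never 0", {
  set.seed(33)
  gid <- paste0("g", 1:12)
  lfc <- structure(rnorm(12), names = gid)
  cls <- structure(runif(12, 1, 100), names = gid)
  map <- list(d1 = gid[1:4], d2 = gid[5:8], d3 = gid[9:12])
  mfc <- domainMFC(lfc, map)
  nPerm <- 9
  p <- suppressWarnings(
    empiricalPMfc(mfc, lfc, map, cls, nPerm = nPerm, seed = 2))
  expect_true(all(p > 0 & p <= 1))
  grid <- (1:(nPerm + 1)) / (nPerm + 1)
  expect_true(all(vapply(p, function(x)
    any(abs(x - grid) < 1e-12), logical(1))))
  # two-sided: an observed mFC of 0 can never beat any permutation
  p0 <- suppressWarnings(
    empiricalPMfc(c(d1 = 0, d2 = 0, d3 = 0), lfc, map, cls,
                  nPerm = nPerm, seed = 2))
  expect_equal(unname(p0), rep(1, 3))
  # an observed |mFC| above anything achievable gives the resolution floor
  pBig <- suppressWarnings(
    empiricalPMfc(c(d1 = 99, d2 = 99, d3 = 99), lfc, map, cls,
                  nPerm = 999, seed = 2))
  expect_equal(unname(pBig), rep(1 / 1000, 3))
})

test_that("cross-boundary null selects flanking genes closest-first", {
  # one chromosome, three domains in a row; profiles constructed by hand
  nS <- 10
  set.seed(44)
  m <- matrix(rnorm(9 * nS), nrow = 9,
              dimnames = list(paste0("g", 1:9), paste0("s", 1:nS)))
  domains <- domainsFromBed("chr1", c(0, 300, 600), c(300, 600, 900),
                            c("L", "M", "R"))
  map <- list(L = c("g1", "g2", "g3"), M = c("g4", "g5", "g6"),
              R = c("g7", "g8", "g9"))
  null <- buildCrossBoundaryNull(m, map, domains)
  expect_named(null, c("L", "M", "R"))
  # brute-force oracle for the middle domain: k = 3, 2 from the left
  # (closest first: g3, g2) and 1 from the right (g7)
  flank <- c("g3", "g2", "g7")
  oracle <- mean(cor(t(m[c("g4", "g5", "g6"), ]), t(m[flank, ])))
  expect_equal(unname(null["M"]), oracle, tolerance = 1e-12)
  # edge domain L: no left side, all 3 from the right (g4, g5, g6)
  oracleL <- mean(cor(t(m[map$L, ]), t(m[c("g4", "g5", "g6"), ])))
  expect_equal(unname(null["L"]), oracleL, tolerance = 1e-12)
  # a single-domain chromosome contributes nothing
  soloDom <- domainsFromBed("chr9", 0, 300, "solo")
  expect_length(buildCrossBoundaryNull(m, list(solo = c("g1", "g2")),
                                       soloDom), 0)
  # flank genes identical in profile to the domain genes: the cross-boundary
  # mean equals the within-domain mcor (here all profiles equal, so 1)
  prof <- m["g4", ]
  mId <- matrix(rep(prof, 6), nrow = 6, byrow = TRUE,
                dimnames = list(c("f1", "f2", "f3", "gA", "gB", "gC"),
                                names(prof)))
  nullId <- buildCrossBoundaryNull(
    mId, list(L = c("f1", "f2", "f3"), M = c("gA", "gB", "gC")),
    domainsFromBed("chr1", c(0, 300), c(300, 600), c("L", "M")))
  expect_equal(unname(nullId["M"]), 1, tolerance = 1e-12)
})

test_that("empirical mCor p values are one-sided against the pooled null", {
  null <- seq(-0.9, 0.9, length.out = 999)
  expect_equal(empiricalPMcor(-1, null), 1)
  expect_equal(empiricalPMcor(0.95, null), 1 / 1000)
  expect_equal(empiricalPMcor(median(null), null), 0.5, tolerance = 0.01)
  # grid membership and never zero
  set.seed(5)
  p <- empiricalPMcor(runif(20, -1, 1), null)
  expect_true(all(p > 0 & p <= 1))
  expect_true(all(abs(p * 1000 - round(p * 1000)) < 1e-9))
})

test_that("Stouffer combination follows the closed form", {
  expect_equal(stoufferCombine(0.5, 0.5), 0.5, tolerance = 1e-12)
  expect_equal(stoufferCombine(0.05, 0.05),
               1 - pnorm(sqrt(2) * qnorm(0.95)), tolerance = 1e-12)
  expect_lt(stoufferCombine(0.02, 0.02), 0.02)
  expect_gt(stoufferCombine(0.9, 0.9), 0.9)
  expect_equal(stoufferCombine(1, 0.01), 1)  # a p of 1 dominates (z = -Inf)
  expect_error(stoufferCombine(0, 0.5), class = "chromda_validation_error")
})

test_that("full pipeline recovers planted domains and respects label swap", {
  sim <- simulateDataset(simConfig(nChrom = 2, domainsPerChrom = 25,
                                   samplesPerCondition = 20,
                                   plantedActiveDomains = 4,
                                   effectLfc = 1, intraDomainRho = 0.5,
                                   seed = 101))
  res <- runDomainActivity(sim$ds, sim$domains, sim$genes,
                           nPerm = 1000, seed = 3)
  tab <- domainTable(res)
  planted <- sim$truth$domain_id[sim$truth$type != "null"]
  hits <- significantDomains(res)
  expect_gte(sum(planted %in% hits), 3)           # recall
  expect_lte(sum(!hits %in% planted), 1)          # precision
  # direction matches the planted sign
  up <- sim$truth$domain_id[sim$truth$type == "active_up"]
  expect_true(all(tab$direction[tab$domain_id %in% intersect(up, hits)] == 1))

  # label swap: mfc flips sign, two-sided p_mfc unchanged
  resFlip <- runDomainActivity(sim$ds, sim$domains, sim$genes,
                               nPerm = 1000, seed = 3,
                               flipConditions = TRUE)
  tf <- domainTable(resFlip)
  ord <- match(tab$domain_id, tf$domain_id)
  expect_equal(tf$mfc[ord], -tab$mfc, tolerance = 1e-10)
  expect_equal(tf$p_mfc[ord], tab$p_mfc, tolerance = 1e-12)

  # BH on the combined p matches the oracle
  expect_equal(tab$p_adj, bhOracle(tab$p_comb), tolerance = 1e-12)
  # p-value columns respect their ranges
  for (cn in c("p_mfc", "p_mcor", "p_comb", "p_adj")) {
    expect_true(all(tab[[cn]] > 0 & tab[[cn]] <= 1))
  }
  expect_true(all(tab$p_adj >= tab$p_comb - 1e-15))
  # determinism
  res2 <- runDomainActivity(sim$ds, sim$domains, sim$genes,
                            nPerm = 1000, seed = 3)
  expect_equal(as.data.frame(domainTable(res2)), as.data.frame(tab))
})
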