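test_that("bulk selection keeps exactly the argmax samples, in input order", {
  # cells built as noisy copies of sample 1 so every argmax vote goes to it
  withr::with_seed(5, {
    s1 <- runif(20, 0, 5); s2 <- runif(20, 0, 5)
    cells <- sapply(1:4, function(i) s1 + rnorm(20, 0, 0.05))
  })
  x <- em(cells, layer = "normalized")
  bulk <- BulkPanel(cbind(a = s1, b = s2), cellTypes = c("A", "B"),
                    geneIds = paste0("g", 1:20))
  rownames(cells) <- paste0("g", 1:20)
  x <- em(cells, layer = "normalized", genes = paste0("g", 1:20))
  rp <- selectBulkReferences(x, bulk, bulkLog = "none")
  expect_identical(sampleIds(rp), "a")
  expect_identical(cellTypes(rp), "A")
  expect_identical(provenance(rp), "bulk-selected")
})

test_that("bulk selection retains all samples when each wins a cell", {
  withr::with_seed(6, {
    refs <- matrix(runif(60, 0, 4), 20, 3)
    cells <- refs[, c(1, 2, 3, 1, 2)] + rnorm(100, 0, 0.02)
  })
  x <- em(cells, layer = "normalized")
  bulk <- BulkPanel(refs, cellTypes = c("A", "B", "C"),
                    geneIds = geneIds(x), sampleIds = paste0("s", 1:3))
  rp <- selectBulkReferences(x, bulk, bulkLog = "none")
  expect_identical(sampleIds(rp), paste0("s", 1:3))
})

test_that("zero-variance cells cast no argmax vote", {
  withr::with_seed(8, {
    s1 <- runif(10, 0, 3); s2 <- runif(10, 0, 3)
    good <- s1 + rnorm(10, 0, 0.01)
  })
  cells <- cbind(good, flat = rep(2, 10))
  x <- em(cells, layer = "normalized")
  bulk <- BulkPanel(cbind(s1, s2), cellTypes = c("A", "B"),
                    geneIds = geneIds(x), sampleIds = c("s1", "s2"))
  rp <- selectBulkReferences(x, bulk, bulkLog = "none")
  expect_identical(sampleIds(rp), "s1")   # flat cell would have tied at 0
})

test_that("bulk selection is idempotent on its own output", {
  sim <- standardSim(seed = 13, nCells = 90, nGenes = 120)
  xn <- logNormalize(sim$counts)
  bulk <- makeBulkFromTruth(sim, nDecoys = 3, seed = 2)
  rp1 <- selectBulkReferences(xn, bulk, bulkLog = "none")
  asBulk <- BulkPanel(exprValues(rp1), cellTypes = cellTypes(rp1),
                      sampleIds = sampleIds(rp1))
  rp2 <- selectBulkReferences(xn, asBulk, bulkLog = "none")
  expect_identical(sampleIds(rp2), sampleIds(rp1))
  expect_equal(exprValues(rp2), exprValues(rp1), ignore_attr = TRUE)
})

test_that("labeled-cell references are exact class means at ratio 1", {
  x <- em(cbind(c(1, 3), c(3, 5)), layer = "normalized")
  rp <- buildSCReferences(x, c("T", "T"), ratio = 1)
  expect_equal(as.numeric(exprValues(rp)), c(2, 4))

  # seed-independent at ratio 1
  rpA <- buildSCReferences(x, c("T", "T"), ratio = 1, seed = 1)
  rpB <- buildSCReferences(x, c("T", "T"), ratio = 1, seed = 99)
  expect_equal(exprValues(rpA), exprValues(rpB))
})

test_that("class-mean conservation: type means weighted by size reproduce totals", {
  sim <- standardSim(seed = 3, nCells = 60, nGenes = 40)
  xn <- logNormalize(sim$counts)
  lab <- as.character(sim$trueLabels)
  rp <- buildSCReferences(xn, lab, ratio = 1)
  sizes <- table(lab)[unique(lab)]
  recon <- as.matrix(exprValues(rp)) %*% as.numeric(sizes)
  expect_equal(as.numeric(recon),
               as.numeric(Matrix::rowSums(exprValues(xn))), tolerance = 1e-10)
})

test_that("subsampled references are seed-reproducible and differ across seeds", {
  sim <- standardSim(seed = 5, nCells = 80, nGenes = 60)
  xn <- logNormalize(sim$counts)
  lab <- as.character(sim$trueLabels)
  r1 <- buildSCReferences(xn, lab, ratio = 0.5, seed = 7)
  r2 <- buildSCReferences(xn, lab, ratio = 0.5, seed = 7)
  r3 <- buildSCReferences(xn, lab, ratio = 0.5, seed = 8)
  expect_equal(exprValues(r1), exprValues(r2))
  expect_false(isTRUE(all.equal(exprValues(r1), exprValues(r3))))
  expect_error(buildSCReferences(xn, rep(NA_character_, ncol(xn))),
               "unknown label")
})

test_that("kmeans anchors recover well-separated cloud means", {
  withr::with_seed(10, {
    cloud1 <- matrix(rnorm(25 * 5, 0, 0.1), 5, 25)
    cloud2 <- matrix(rnorm(25 * 5, 10, 0.1), 5, 25)
  })
  x <- em(cbind(cloud1, cloud2), layer = "normalized")
  rp <- kmeansAnchors(x, dPrime = 2, seed = 1)
  centers <- as.matrix(exprValues(rp))
  means <- cbind(rowMeans(cloud1), rowMeans(cloud2))
  ord <- order(centers[1, ]); mord <- order(means[1, ])
  expect_equal(centers[, ord], means[, mord], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(provenance(rp), "kmeans")
  expect_null(cellTypes(rp))

  rpA <- kmeansAnchors(x, dPrime = 2, seed = 3)
  rpB <- kmeansAnchors(x, dPrime = 2, seed = 3)
  expect_equal(exprValues(rpA), exprValues(rpB))
  expect_error(kmeansAnchors(x, dPrime = 51), "between 1 and")
})

test_that("d' = n anchors reproduce the distinct cells themselves", {
  withr::with_seed(2, vals <- matrix(runif(24, 0, 3), 4, 6))
  x <- em(vals, layer = "normalized")
  rp <- kmeansAnchors(x, dPrime = 6, seed = 1)
  centers <- as.matrix(exprValues(rp))
  ord <- order(centers[1, ]); vord <- order(vals[1, ])
  expect_equal(centers[, ord], vals[, vord], tolerance = 1e-8,
               ignore_attr = TRUE)
})
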