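test_that("coiled-coil segments are maximal runs above the score threshold", {
  hits <- detectCC(rep(0.9, 30), "p", threshold = 0.5, min_len = 8)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$start, hits$end), c(1, 30))
  expect_equal(hits$domain_class, "C")

  expect_equal(nrow(detectCC(rep(0.4, 50))), 0)

  sc <- c(rep(0.9, 10), rep(0.1, 10), rep(0.9, 10))
  two <- detectCC(sc, "p")
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(1, 21))
  expect_equal(two$end, c(10, 30))

  # runs shorter than min_len are ignored
  expect_equal(nrow(detectCC(c(rep(0.9, 5), rep(0, 20)), min_len = 8)), 0)
})

test_that("same-class hits merge by gap while classes stay separate", {
  mk <- function(cls, s, e) data.frame(domain_class = cls, start = s,
                                       end = e)
  # clustered LRR repeats collapse to one L
  l3 <- mk(rep("L", 3), c(500, 535, 580), c(520, 560, 600))
  m <- mergeHits(l3, gap_max = 150)
  expect_equal(m$letter, "L")
  expect_equal(c(m$start, m$end), c(500, 600))

  # distant same-class hits stay separate (gap 349 > 150)
  nn <- mk(c("N", "N"), c(100, 600), c(250, 750))
  expect_equal(mergeHits(nn, 150)$letter, c("N", "N"))

  # different classes never merge even when adjacent
  cn <- mk(c("C", "N"), c(1, 35), c(30, 200))
  expect_equal(mergeHits(cn, 150)$letter, c("C", "N"))

  expect_equal(nrow(mergeHits(mk(character(), integer(), integer()))), 0)
})

test_that("merging is idempotent and matches the brute-force oracle", {
  set.seed(42)
  for (i in 1:50) {
    hits <- randomHitSet(sample.int(12, 1))
    m1 <- mergeHits(hits, 150)
    # idempotence: re-merging merged units changes nothing
    again <- data.frame(domain_class = m1$letter, start = m1$start,
                        end = m1$end)
    expect_equal(mergeHits(again, 150), m1)
    # oracle agreement
    o <- bruteMerge(hits, 150)
    expect_equal(m1$letter, o$letter)
    expect_equal(m1$start, o$start)
    expect_equal(m1$end, o$end)
  }
})

test_that("architecture types and subclasses follow the letter content", {
  a <- classifyArchitecture(c("C", "N", "L"))
  expect_equal(a$type_name, "CNL")
  expect_equal(a$subclass, "NBS-LRR")
  expect_true(a$is_nbs)

  expect_equal(classifyArchitecture(c("T", "N", "C"))$subclass,
               "non-NBS-LRR")
  b <- classifyArchitecture(c("C", "N", "L", "C", "N"))
  expect_equal(b$type_name, "CNLCN")
  expect_equal(b$subclass, "NBS-LRR")

  n <- classifyArchitecture("N")
  expect_equal(n$type_name, "N")
  expect_equal(n$subclass, "non-NBS-LRR")

  l <- classifyArchitecture(c("L", "L"))
  expect_false(l$is_nbs)

  expect_error(classifyArchitecture(character()), "empty")
})

test_that("every gene lands in exactly one type and one subclass", {
  set.seed(3)
  types <- c("CNL", "NL", "CN", "N", "TNC", "RN", "NN", "CNLCN")
  tab <- data.frame(
    gene_id = sprintf("g%03d", 1:120),
    species = sample(c("s1", "s2"), 120, replace = TRUE),
    type_name = sample(types, 120, replace = TRUE),
    stringsAsFactors = FALSE)
  tab$subclass <- ifelse(grepl("N", tab$type_name) &
                           grepl("L", tab$type_name),
                         "NBS-LRR", "non-NBS-LRR")
  tab$is_nbs <- grepl("N", tab$type_name)
  aset <- new("ArchitectureSet", table = tab)
  tt <- typeCountTable(aset)
  # subclass subtotals sum to species totals, which sum to the grand total
  expect_equal(colSums(tt$subclass_totals), tt$species_totals)
  expect_equal(sum(tt$counts), tt$grand_total)
  expect_equal(sum(tt$species_totals), 120)
  # each type row is assigned to exactly one subclass band
  expect_equal(sum(colSums(tt$counts)), sum(tt$subclass_totals))
})

test_that("type table handles empty input and excludes non-NBS genes", {
  empty <- new("ArchitectureSet",
               table = data.frame(gene_id = character(),
                                  species = character(),
                                  type_name = character(),
                                  subclass = character(),
                                  is_nbs = logical()))
  tt <- typeCountTable(empty)
  expect_equal(tt$grand_total, 0)

  tab <- data.frame(gene_id = c("a", "b"), species = "s",
                    type_name = c("CNL", "LL"),
                    subclass = c("NBS-LRR", "non-NBS-LRR"),
                    is_nbs = c(TRUE, FALSE), stringsAsFactors = FALSE)
  tt2 <- typeCountTable(new("ArchitectureSet", table = tab))
  expect_equal(tt2$grand_total, 1)
  expect_equal(tt2$non_nbs$gene_id, "b")
})

test_that("pearsonR matches hand values and the brute-force oracle", {
  expect_equal(pearsonR(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearsonR(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(pearsonR(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearsonR(1:2, 1:2), "at least 3")

  set.seed(99)
  for (i in 1:50) {
    n <- sample(3:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearsonR(x, y)$r, brutePearson(x, y), tolerance = 1e-12)
  }
})

test_that("motif order conservation is a subsequence test", {
  canon <- c(6, 5, 3, 1, 7, 2, 8, 4)
  expect_true(motifOrderConserved(canon, canon))
  expect_false(motifOrderConserved(rev(canon), canon))
  expect_true(motifOrderConserved(c(6, 3, 7, 8), canon))
  expect_false(motifOrderConserved(c(3, 6), canon))
  expect_true(motifOrderConserved(integer(), canon))
  # motifs outside the canonical set are ignored
  expect_true(motifOrderConserved(c(6, 99, 3), canon))
  expect_error(motifOrderConserved(c(1, 2), c(1, 1, 2)), "distinct")
})
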