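test_that("domain-hit parsing maps accessions, filters by e-value and keeps order", {
  path <- writeHitFile(list(
    c("p1", "PF00931", 100, 250, "1e-30"),
    c("p1", "PF13855", 400, 430, "1e-20"),
    c("p2", "PF01582", 10, 150, "1e-5"),
    c("p3", "PF05659", 5, 120, "1e-15"),
    c("p4", "C", 1, 40, "1e-40")))
  hits <- parseDomainHits(path, evalue_max = 1e-10)
  expect_equal(hits$protein_id, c("p1", "p1", "p3", "p4"))
  expect_equal(hits$domain_class, c("N", "L", "R", "C"))
  expect_equal(hits$start[1], 100)
  expect_equal(hits$end[1], 250)

  # empty file
  empty <- tempfile()
  file.create(empty)
  expect_equal(nrow(parseDomainHits(empty)), 0)

  # filter applied: only the 1e-30 hit survives a 1e-10 cutoff
  path2 <- writeHitFile(list(c("p1", "PF00931", 1, 50, "1e-30"),
                             c("p1", "PF00931", 60, 90, "1e-5")))
  expect_equal(nrow(parseDomainHits(path2, 1e-10)), 1)

  # unknown accession: warn and skip
  path3 <- writeHitFile(list(c("p1", "PF99999", 1, 50, "1e-30"),
                             c("p1", "PF00931", 1, 50, "1e-30")))
  expect_warning(h3 <- parseDomainHits(path3), "PF99999")
  expect_equal(nrow(h3), 1)

  # malformed row names its line
  path4 <- writeHitFile(list(c("p1", "PF00931", 1, 50, "1e-30"),
                             c("p1", "PF00931")))
  expect_error(parseDomainHits(path4), "line 2")
})

test_that("shrinking the e-value cutoff never increases the hit count", {
  set.seed(11)
  rows <- lapply(1:40, function(i)
    c(paste0("p", i %% 5), "PF00931", i, i + 100,
      format(10^(-runif(1, 1, 40)), scientific = TRUE)))
  path <- writeHitFile(rows)
  cuts <- 10^seq(-2, -30, by = -2)
  ns <- vapply(cuts, function(cc) nrow(parseDomainHits(path, cc)), 0)
  expect_true(all(diff(ns) <= 0))
})

test_that("collinearity parsing handles blocks, empty blocks and bad lines", {
  path <- tempfile()
  writeLines(c(
    "# comment",
    "## Alignment 0: score=500 e_value=0 N=3 spA_chr01&spB_chr02 plus",
    "0-  0:\tspA_g1\tspB_g1\t 0",
    "0-  1:\tspA_g2\tspB_g2\t 0",
    "0-  2:\tspA_g3\tspB_g3\t 0",
    "## Alignment 1: score=200 e_value=0 N=1 spA_chr02&spB_chr05 plus",
    "1-  0:\tspA_g9\tspB_g9\t 0"), path)
  blk <- parseCollinearity(path)
  expect_equal(length(unique(blk$block_id)), 2)
  expect_equal(sum(blk$block_id == "block_0"), 3)
  expect_equal(blk$species_a[1], "spA")
  expect_equal(blk$chr_b[1], "spB_chr02")
  expect_equal(blk$gene_a[blk$block_id == "block_0"],
               c("spA_g1", "spA_g2", "spA_g3"))

  # empty block dropped with a warning
  path2 <- tempfile()
  writeLines(c(
    "## Alignment 0: score=0 e_value=0 N=0 spA_chr01&spB_chr01 plus",
    "## Alignment 1: score=0 e_value=0 N=1 spA_chr01&spB_chr01 plus",
    "1-  0:\tspA_g1\tspB_g1\t 0"), path2)
  expect_warning(blk2 <- parseCollinearity(path2), "zero gene pairs")
  expect_equal(unique(blk2$block_id), "block_1")

  # pair line before any header is an error
  path3 <- tempfile()
  writeLines("0-  0:\tspA_g1\tspB_g1\t 0", path3)
  expect_error(parseCollinearity(path3), "header")
})

test_that("gene models parse spans, exon counts and the no-exon fallback", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t5000\t.\t+\t.\tID=g1;species=spA",
    "chr1\tsrc\texon\t1000\t1500\t.\t+\t.\tParent=g1",
    "chr1\tsrc\texon\t2000\t2500\t.\t+\t.\tParent=g1",
    "chr1\tsrc\texon\t4500\t5000\t.\t+\t.\tParent=g1",
    "chr2\tsrc\tgene\t100\t400\t.\t-\t.\tID=g2;species=spA"), path)
  expect_warning(gm <- parseGeneModels(path), "exon_count = 1")
  expect_equal(gm$exon_count[gm$gene_id == "g1"], 3)
  expect_equal(gm$gene_length[gm$gene_id == "g1"], 4001)
  expect_equal(gm$exon_count[gm$gene_id == "g2"], 1)
  expect_equal(gm$chromosome, c("chr1", "chr2"))
  expect_equal(gm$strand, c("+", "-"))
})

test_that("writers round-trip through their parsers", {
  set.seed(7)
  g <- generateGenomes(genomeConfig(n_lineages_complete = 3,
                                    n_lineages_incomplete = 1,
                                    n_type_changed = 1, n_nbarc_deleted = 0,
                                    n_chromosome_lineages = 3,
                                    type_counts = c(CNL = 4, NL = 3, N = 5,
                                                    CN = 3)),
                      seed = 5, out_dir = tempfile())
  gm1 <- parseGeneModels(g$files[["gff"]])
  tmp <- tempfile(fileext = ".gff3")
  writeGeneModels(gm1, tmp)
  gm2 <- parseGeneModels(tmp)
  expect_equal(gm1, gm2)

  hits1 <- parseDomainHits(g$files[["domain_hits"]])
  tmp2 <- tempfile()
  writeDomainHits(hits1, tmp2)
  hits2 <- parseDomainHits(tmp2)
  expect_equal(hits1$start, hits2$start)
  expect_equal(hits1$domain_class, hits2$domain_class)

  blk1 <- parseCollinearity(g$files[["collinearity"]])
  tmp3 <- tempfile()
  writeCollinearity(blk1, tmp3)
  expect_equal(parseCollinearity(tmp3), blk1)

  tr1 <- parseCoilTracks(g$files[["coil_tracks"]])
  tmp4 <- tempfile()
  writeCoilTracks(tr1, tmp4)
  expect_equal(parseCoilTracks(tmp4), tr1)

  sim1 <- parseSimilarityHits(g$files[["similarity"]])
  tmp5 <- tempfile()
  writeSimilarityHits(sim1, tmp5)
  sim2 <- parseSimilarityHits(tmp5)
  expect_equal(sim1$query_id, sim2$query_id)
  expect_equal(sim1$bitscore, sim2$bitscore)
})

test_that("coil tracks validate range and positions", {
  path <- tempfile()
  writeLines(c("protein_id\tposition\tscore",
               "p1\t1\t0.2", "p1\t2\t0.9", "p1\t3\t1.5"), path)
  expect_error(parseCoilTracks(path), "\\[0, 1\\]")
})

test_that("species chain comes from the Newick tip order", {
  path <- tempfile(fileext = ".nwk")
  writeLines("(spcA,(spcB,spcC));", path)
  expect_equal(speciesChainFromTree(path), c("spcA", "spcB", "spcC"))
})
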