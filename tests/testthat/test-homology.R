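gm_row <- function(id, sp, chr) data.frame(gene_id = id, species = sp,
                                           chromosome = chr)

test_that("pairs are typed by species, block membership and chromosome", {
  a <- gm_row("a1", "spA", "spA_chr03")
  b <- gm_row("b1", "spB", "spB_chr03")
  expect_equal(classifyPair(a, b, in_block = TRUE), "ortholog")
  expect_true(is.na(classifyPair(a, b, in_block = FALSE)))

  c1 <- gm_row("a2", "spA", "spA_chr03")
  expect_equal(classifyPair(a, c1, in_block = FALSE),
               "homochromosomal_duplication")
  c2 <- gm_row("a3", "spA", "spA_chr05")
  expect_equal(classifyPair(a, c2, in_block = FALSE),
               "heterochromosomal_duplication")
  expect_error(classifyPair(a, a, FALSE), "self")
})

test_that("best-hit selection keeps max bitscore, drops self hits, enforces RBH", {
  genes <- data.frame(gene_id = c("a1", "a2", "b1", "b2"),
                      species = c("spA", "spA", "spB", "spB"),
                      chromosome = "c1", stringsAsFactors = FALSE)
  hits <- data.frame(
    query_id   = c("a1", "a1", "a1", "b1", "a1", "b2", "a2"),
    subject_id = c("b1", "b1", "a1", "a1", "b2", "a2", "a1"),
    percent_identity = 90, alignment_length = 100L, evalue = 1e-50,
    bitscore   = c(200, 150, 999, 210, 120, 140, 100),
    stringsAsFactors = FALSE)
  best <- selectBestHits(hits, genes)
  # self hit gone
  expect_false(any(best$query_id == best$subject_id))
  # duplicate a1->b1 resolved to the higher bitscore
  expect_equal(best$bitscore[best$query_id == "a1" &
                               best$subject_id == "b1"], 200)
  # a1<->b1 reciprocal best retained; a1->b2 (non-reciprocal) dropped
  expect_true(any(best$query_id == "a1" & best$subject_id == "b1"))
  expect_false(any(best$query_id == "a1" & best$subject_id == "b2"))
  # same-species best hits pass through (a2 -> a1)
  expect_true(any(best$query_id == "a2" & best$subject_id == "a1"))
})

test_that("the census counts distinct genes once per relation", {
  p <- data.frame(
    gene_a = c("a1", "a1", "a2"), gene_b = c("b1", "a2", "a3"),
    species_a = c("spA", "spA", "spA"), species_b = c("spB", "spA", "spA"),
    relation = c("ortholog", "homochromosomal_duplication",
                 "heterochromosomal_duplication"),
    evidence = "x", same_type = TRUE, stringsAsFactors = FALSE)
  h <- new("HomologySet", pairs = p)
  cen <- pairCensus(h)
  expect_equal(unname(cen["ortholog"]), 2)
  expect_equal(unname(cen["homochromosomal_duplication"]), 2)
  expect_equal(unname(cen["heterochromosomal_duplication"]), 2)
  # a gene in two relations is counted in both; within one relation once
  expect_equal(sum(cen), 6)

  empty <- new("HomologySet", pairs = p[0, ])
  expect_equal(unname(pairCensus(empty)), c(0L, 0L, 0L))
})

mk_pairs <- function(df) {
  df$evidence <- "block_x"
  df$same_type <- NA
  new("HomologySet", pairs = df)
}

test_that("lineages chain ortholog pairs across adjacent species", {
  genes <- data.frame(
    gene_id = c("a1", "b1", "c1", "a2", "b2", "a3", "b3", "c3"),
    species = c("spA", "spB", "spC", "spA", "spB", "spA", "spB", "spC"),
    chromosome = paste0(c("spA", "spB", "spC", "spA", "spB", "spA", "spB",
                          "spC"), "_chr01"),
    stringsAsFactors = FALSE)
  arch <- new("ArchitectureSet", table = data.frame(
    gene_id = genes$gene_id, species = genes$species,
    type_name = c("CNL", "CNL", "CNL", "NL", "NL", "CNL", "NL", "NL"),
    subclass = c("NBS-LRR", "NBS-LRR", "NBS-LRR", "NBS-LRR", "NBS-LRR",
                 "NBS-LRR", "NBS-LRR", "NBS-LRR"),
    is_nbs = TRUE, stringsAsFactors = FALSE))
  pairs <- data.frame(
    gene_a = c("a1", "b1", "a2", "a3", "b3"),
    gene_b = c("b1", "c1", "b2", "b3", "c3"),
    species_a = c("spA", "spB", "spA", "spA", "spB"),
    species_b = c("spB", "spC", "spB", "spB", "spC"),
    relation = "ortholog", stringsAsFactors = FALSE)
  lin <- assembleLineages(mk_pairs(pairs), genes, c("spA", "spB", "spC"),
                          arch)
  f <- lineageFlags(lin)
  expect_equal(nrow(f), 3)
  expect_equal(sum(f$complete), 2)
  expect_equal(sum(!f$complete), 1)
  # a1-b1-c1 all CNL: conserved; a3-b3-c3 mixes CNL/NL: changed
  m <- lineageMembers(lin)
  lid_a1 <- m$lineage_id[m$gene_id == "a1"]
  lid_a3 <- m$lineage_id[m$gene_id == "a3"]
  expect_true(f$type_conserved[f$lineage_id == lid_a1])
  expect_false(f$type_conserved[f$lineage_id == lid_a3])

  st <- lineageStats(lin)
  expect_equal(unname(st["total"]), 3)
  expect_equal(unname(st["incomplete_count"]), 1)
  expect_equal(unname(st["type_changed_count"]), 1)
})

test_that("a gene pairing into one species twice is a conflict", {
  genes <- data.frame(gene_id = c("a1", "b1", "b2"),
                      species = c("spA", "spB", "spB"),
                      chromosome = "c", stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = c("a1", "a1"), gene_b = c("b1", "b2"),
                      species_a = "spA", species_b = "spB",
                      relation = "ortholog", stringsAsFactors = FALSE)
  expect_error(assembleLineages(mk_pairs(pairs), genes, c("spA", "spB")),
               "conflicting")
})

test_that("lineage assembly is invariant to pair order", {
  set.seed(21)
  g <- generateGenomes(genomeConfig(), seed = 9, out_dir = tempfile())
  genes <- parseGeneModels(g$files[["gff"]])
  sims <- parseSimilarityHits(g$files[["similarity"]])
  blocks <- parseCollinearity(g$files[["collinearity"]])
  h <- buildHomologs(sims, genes, blocks)
  lin1 <- assembleLineages(h, genes, c("spcA", "spcB", "spcC"))
  perm <- sample(nrow(pairTable(h)))
  h2 <- new("HomologySet", pairs = pairTable(h)[perm, ])
  lin2 <- assembleLineages(h2, genes, c("spcA", "spcB", "spcC"))
  expect_equal(lineageMembers(lin1), lineageMembers(lin2))
  expect_equal(lineageFlags(lin1), lineageFlags(lin2))
})

test_that("every lineage member connects to a neighbor by an ortholog pair", {
  g <- generateGenomes(genomeConfig(n_lineages_complete = 6,
                                    n_lineages_incomplete = 2,
                                    n_type_changed = 2,
                                    n_nbarc_deleted = 0,
                                    n_chromosome_lineages = 5),
                       seed = 4, out_dir = tempfile())
  genes <- parseGeneModels(g$files[["gff"]])
  sims <- parseSimilarityHits(g$files[["similarity"]])
  blocks <- parseCollinearity(g$files[["collinearity"]])
  h <- buildHomologs(sims, genes, blocks)
  lin <- assembleLineages(h, genes, c("spcA", "spcB", "spcC"))
  p <- pairTable(h)
  orth <- p[p$relation == "ortholog", ]
  key <- c(paste(orth$gene_a, orth$gene_b), paste(orth$gene_b, orth$gene_a))
  m <- lineageMembers(lin)
  for (lid in unique(m$lineage_id)) {
    mem <- m[m$lineage_id == lid, ]
    for (i in seq_len(nrow(mem) - 1))
      expect_true(paste(mem$gene_id[i], mem$gene_id[i + 1]) %in% key)
  }
})

test_that("chromosome correspondence recovers the planted permutation", {
  g <- generateGenomes(genomeConfig(), seed = 13, out_dir = tempfile())
  blocks <- parseCollinearity(g$files[["collinearity"]])
  maps <- chromosomeCorrespondence(blocks, c("spcA", "spcB", "spcC"))
  # every mapped chromosome agrees with the lineage truth: members of one
  # lineage all map back to the same reference chromosome
  genes <- parseGeneModels(g$files[["gff"]])
  chrom <- setNames(genes$chromosome, genes$gene_id)
  tm <- g$truth$lineage_members
  tf <- g$truth$lineage_flags
  for (lid in tf$lineage_id) {
    mem <- tm[tm$lineage_id == lid, ]
    mapped <- vapply(seq_len(nrow(mem)), function(i) {
      ch <- unname(chrom[mem$gene_id[i]])
      si <- match(mem$species[i], c("spcA", "spcB", "spcC"))
      while (si > 1) {
        ch <- unname(maps[[si - 1]][ch])
        si <- si - 1
      }
      ch
    }, character(1))
    expect_equal(unique(mapped),
                 tf$chromosome_lineage[tf$lineage_id == lid])
  }
})
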