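test_that("the genome generator is deterministic and round-trips losslessly", {
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- generateGenomes(orchidPresetConfig(), seed = 7, out_dir = d1)
  g2 <- generateGenomes(orchidPresetConfig(), seed = 7, out_dir = d2)
  for (k in names(g1$files))
    expect_identical(readLines(g1$files[[k]]), readLines(g2$files[[k]]))
  g3 <- generateGenomes(orchidPresetConfig(), seed = 8,
                        out_dir = tempfile())
  expect_false(identical(readLines(g1$files[["domain_hits"]]),
                         readLines(g3$files[["domain_hits"]])))

  gm <- parseGeneModels(g1$files[["gff"]])
  expect_setequal(gm$gene_id, g1$tables$gene_models$gene_id)
  expect_equal(nrow(parseCollinearity(g1$files[["collinearity"]])),
               nrow(g1$tables$blocks))
})

test_that("noiseless recovery: classification and homology reproduce the truth", {
  cfg <- genomeConfig(noise_frac = 0)
  g <- generateGenomes(cfg, seed = 3, out_dir = tempfile())
  genes <- parseGeneModels(g$files[["gff"]])
  hits <- parseDomainHits(g$files[["domain_hits"]])
  tracks <- parseCoilTracks(g$files[["coil_tracks"]])
  aset <- buildArchitectures(hits, tracks,
                             species = setNames(genes$species,
                                                genes$gene_id))
  at <- archTable(aset)
  tr <- g$truth$architectures
  m <- merge(at, tr, by = "gene_id")
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$type_name.x, m$type_name.y)
  expect_equal(m$subclass.x, m$subclass.y)

  sims <- parseSimilarityHits(g$files[["similarity"]])
  blocks <- parseCollinearity(g$files[["collinearity"]])
  h <- buildHomologs(sims, genes, blocks, aset)
  cen <- pairCensus(h)
  truth_cen <- vapply(
    c("ortholog", "homochromosomal_duplication",
      "heterochromosomal_duplication"),
    function(r) {
      sel <- g$truth$relations$relation == r
      length(unique(c(g$truth$relations$gene_a[sel],
                      g$truth$relations$gene_b[sel])))
    }, integer(1))
  expect_equal(cen, truth_cen)

  lin <- assembleLineages(h, genes, cfg$species, aset, blocks)
  st <- lineageStats(lin)
  tf <- g$truth$lineage_flags
  expect_equal(unname(st["total"]), nrow(tf))
  expect_equal(unname(st["incomplete_count"]), sum(!tf$complete))
  expect_equal(unname(st["type_changed_count"]), sum(!tf$type_conserved))
  expect_equal(unname(st["chromosome_lineage_count"]),
               length(unique(tf$chromosome_lineage)))
})

test_that("infeasible genome configs are rejected", {
  expect_error(genomeConfig(n_lineages_complete = 60,
                            n_lineages_incomplete = 40),
               "infeasible")
  expect_error(genomeConfig(n_type_changed = 11))
})

test_that("the expression generator is deterministic with planted truth", {
  e1 <- generateExpression(exprConfig(), seed = 4, out_dir = tempfile())
  e2 <- generateExpression(exprConfig(), seed = 4)
  expect_identical(e1$counts, e2$counts)
  expect_equal(length(e1$truth$up_genes), 20)
  expect_true(all(e1$truth$up_genes %in% rownames(e1$counts)))
  # written counts round-trip
  cm <- parseCountMatrix(e1$files[["counts"]])
  expect_identical(cm$counts, e1$counts)
  expect_equal(unname(cm$gene_lengths), unname(e1$gene_lengths))

  # planted effect is visible in the raw means
  trt <- e1$design$condition == "treated"
  up <- rownames(e1$counts) %in% e1$truth$up_genes
  ratio <- rowMeans(e1$counts[up, trt]) / rowMeans(e1$counts[up, !trt])
  expect_gt(median(ratio), 2)
})

test_that("a null effect leaves the planted set indistinguishable from noise", {
  fp <- 0; n_tests <- 0
  for (s in 1:10) {
    e <- generateExpression(exprConfig(effect = 1,
                                       module_sizes = integer(0)),
                            seed = s)
    fpkm <- computeFpkm(e$counts, e$gene_lengths)
    d <- callDegs(fpkm, e$design$condition)
    fp <- fp + sum(d$status != "ns")
    n_tests <- n_tests + nrow(d)
  }
  # BH controls FDR; under the global null the expected number of calls at
  # adjusted p < 0.05 is far below 5% of tests
  expect_lt(fp / n_tests, 0.05)
})

test_that("small and zero-gene configs still write well-formed files", {
  cfg <- genomeConfig(type_counts = c(CNL = 2, NL = 1, N = 1, CN = 2),
                      n_lineages_complete = 2, n_lineages_incomplete = 0,
                      n_type_changed = 0, n_nbarc_deleted = 0,
                      n_chromosome_lineages = 2, n_dup_homo = 1,
                      n_dup_hetero = 0, block_fill = 2)
  g <- generateGenomes(cfg, seed = 2, out_dir = tempfile())
  expect_true(all(file.exists(g$files)))
  expect_gt(nrow(parseGeneModels(g$files[["gff"]])), 0)

  cfg0 <- genomeConfig(type_counts = c(CNL = 0),
                       n_lineages_complete = 0, n_lineages_incomplete = 0,
                       n_type_changed = 0, n_nbarc_deleted = 0,
                       n_chromosome_lineages = 1, n_dup_homo = 0,
                       n_dup_hetero = 0, block_fill = 0)
  g0 <- generateGenomes(cfg0, seed = 2, out_dir = tempfile())
  expect_true(all(file.exists(g0$files)))
  expect_equal(nrow(parseGeneModels(g0$files[["gff"]])), 0)
  expect_equal(nrow(parseDomainHits(g0$files[["domain_hits"]])), 0)
  expect_equal(nrow(parseSimilarityHits(g0$files[["similarity"]])), 0)
})
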