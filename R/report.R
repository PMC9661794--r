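# End-to-end pipeline: read every input, run classification, homology and
# lineage assembly, cis-element categorization and (optionally) the
# expression workflow, and assemble the survey-style summary tables plus a
# machine-readable run manifest.

#' Run the full NBS-gene evolution pipeline
#'
#' @param config a named list with input paths and parameters:
#'   \describe{
#'     \item{gff}{gene models (GFF3, with a \code{species} attribute).}
#'     \item{domain_hits}{tab-separated domain-hit table.}
#'     \item{coil_tracks}{per-residue coiled-coil scores (optional).}
#'     \item{similarity}{12-column BLAST tabular hits.}
#'     \item{collinearity}{MCScanX-style collinearity text.}
#'     \item{species_chain}{ordered species vector, or \code{species_tree}
#'       (Newick path) whose tip order is used.}
#'     \item{cis_elements}{PlantCARE-style export (optional).}
#'     \item{category_map}{cis category map path (optional).}
#'     \item{counts, design}{count matrix with lengths + design table
#'       (optional; enables the expression stage).}
#'     \item{params}{optional list: \code{evalue_max}, \code{gap_max},
#'       \code{cc_threshold}, \code{cc_min_len}, \code{beta},
#'       \code{min_module_size}, \code{cut_height}, \code{fc_min},
#'       \code{alpha}.}
#'     \item{seed}{recorded in the manifest (the pipeline itself is
#'       deterministic).}
#'   }
#' @return a report bundle: list with \code{architectures},
#'   \code{type_table}, \code{structure_stats}, \code{homologs},
#'   \code{census}, \code{lineages}, \code{lineage_stats}, \code{cis}
#'   (optional), \code{expression} (optional) and \code{manifest}.
#' @export
runPipeline <- function(config) {
  p <- config$params
  getp <- function(name, default)
    if (!is.null(p[[name]])) p[[name]] else default
  for (f in c("gff", "domain_hits", "similarity", "collinearity")) {
    if (is.null(config[[f]])) stop("config is missing input: ", f)
    if (!file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ", config[[f]])
  }
  genes <- parseGeneModels(config$gff)
  hits <- parseDomainHits(config$domain_hits,
                          evalue_max = getp("evalue_max", 1e-10))
  tracks <- if (!is.null(config$coil_tracks))
    parseCoilTracks(config$coil_tracks) else list()
  sims <- parseSimilarityHits(config$similarity,
                              evalue_max = getp("evalue_max", 1e-10))
  blocks <- parseCollinearity(config$collinearity)
  chain <- if (!is.null(config$species_chain)) config$species_chain else
    speciesChainFromTree(config$species_tree)

  species_of <- stats::setNames(genes$species, genes$gene_id)
  archset <- buildArchitectures(
    hits, tracks, species = species_of,
    gap_max = getp("gap_max", 150),
    cc_threshold = getp("cc_threshold", 0.5),
    cc_min_len = getp("cc_min_len", 8))
  type_table <- typeCountTable(archset)
  nbs_genes <- archTable(archset)$gene_id[archTable(archset)$is_nbs]
  struct <- structureCorrelation(
    genes[genes$gene_id %in% nbs_genes, , drop = FALSE])

  homologs <- buildHomologs(sims, genes, blocks, archset)
  census <- pairCensus(homologs)
  lineages <- assembleLineages(homologs, genes, chain, archset, blocks)
  lstats <- lineageStats(lineages)

  cis <- NULL
  if (!is.null(config$cis_elements)) {
    map <- if (!is.null(config$category_map))
      loadCisCategoryMap(config$category_map) else loadCisCategoryMap()
    elements <- parseCisElements(config$cis_elements)
    cis <- list(categories = categorizeElements(elements, map),
                stress_breakdown = subcategoryBreakdown(elements, map))
  }

  expression <- NULL
  if (!is.null(config$counts) && !is.null(config$design)) {
    cm <- parseCountMatrix(config$counts)
    design <- utils::read.table(config$design, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    se <- makeExpressionSet(cm$counts[, design$sample, drop = FALSE],
                            cm$gene_lengths, design$condition)
    degs <- callDegs(se, fc_min = getp("fc_min", 1.5),
                     alpha = getp("alpha", 0.05))
    fpkm <- SummarizedExperiment::assay(se, "fpkm")
    mods <- coexpressionModules(
      log2(fpkm + 1), as.numeric(design$condition == "treated"),
      beta = getp("beta", 6),
      min_module_size = getp("min_module_size", 30),
      cut_height = getp("cut_height", 0.8))
    expression <- list(se = se, degs = degs, modules = mods)
  }

  manifest <- list(
    package = "nbslineage",
    version = as.character(utils::packageVersion("nbslineage")),
    inputs = config[intersect(names(config),
                              c("gff", "domain_hits", "coil_tracks",
                                "similarity", "collinearity",
                                "cis_elements", "category_map", "counts",
                                "design"))],
    species_chain = chain,
    params = list(evalue_max = getp("evalue_max", 1e-10),
                  gap_max = getp("gap_max", 150),
                  cc_threshold = getp("cc_threshold", 0.5),
                  cc_min_len = getp("cc_min_len", 8),
                  beta = getp("beta", 6),
                  min_module_size = getp("min_module_size", 30),
                  cut_height = getp("cut_height", 0.8),
                  fc_min = getp("fc_min", 1.5),
                  alpha = getp("alpha", 0.05)),
    seed = config$seed)

  list(architectures = archset, type_table = type_table,
       structure_stats = struct, homologs = homologs, census = census,
       lineages = lineages, lineage_stats = lstats, cis = cis,
       expression = expression, manifest = manifest)
}

#' Write a report bundle as tab-separated tables plus a JSON manifest
#'
#' @param bundle list from [runPipeline()].
#' @param dir output directory (created).
#' @return invisibly, the named vector of written paths.
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(
    architectures = wt(archTable(bundle$architectures), "architectures"),
    type_counts = wt(data.frame(type = rownames(bundle$type_table$counts),
                                bundle$type_table$counts,
                                check.names = FALSE), "type_counts"),
    homolog_pairs = wt(pairTable(bundle$homologs), "homolog_pairs"),
    lineage_members = wt(lineageMembers(bundle$lineages),
                         "lineage_members"),
    lineage_flags = wt(lineageFlags(bundle$lineages), "lineage_flags"))
  if (!is.null(bundle$cis))
    paths <- c(paths,
               cis_categories = wt(bundle$cis$categories, "cis_categories"))
  if (!is.null(bundle$expression)) {
    paths <- c(paths, degs = wt(bundle$expression$degs, "degs"))
    mods <- bundle$expression$modules
    paths <- c(paths,
               modules = wt(data.frame(gene_id = names(mods$labels),
                                       module = unname(mods$labels)),
                            "modules"),
               module_trait = wt(mods$trait, "module_trait"))
  }
  summary <- list(
    species_totals = as.list(bundle$type_table$species_totals),
    grand_total = bundle$type_table$grand_total,
    census = as.list(bundle$census),
    lineage_stats = as.list(bundle$lineage_stats),
    structure_r = bundle$structure_stats$r,
    manifest = bundle$manifest)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(summary, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, manifest = manifest_path))
}
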