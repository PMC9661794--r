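# Homolog-pair typing and cross-species lineage assembly. Cross-species
# ortholog candidates are reciprocal best hits that fall inside a collinear
# block; within-species duplications come from best similarity hits and are
# split by chromosome.

#' Filter similarity hits to best and reciprocal-best hits
#'
#' Removes self hits, keeps only the highest-bitscore hit per ordered
#' query-subject pair, and restricts cross-species pairs to reciprocal best
#' hits (each gene's single best partner in the other species, mutually).
#' When \code{blocks} is supplied, cross-species pairs must additionally
#' appear in a collinear block.
#'
#' @param hits data.frame of similarity hits (as from
#'   [parseSimilarityHits()]).
#' @param genes data.frame of gene models giving each gene's species.
#' @param blocks optional data.frame of collinear pairs (as from
#'   [parseCollinearity()]).
#' @return data.frame of retained hits with \code{species_q},
#'   \code{species_s} columns added.
#' @export
selectBestHits <- function(hits, genes, blocks = NULL) {
  sp <- stats::setNames(genes$species, genes$gene_id)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(hits) == 0) {
    hits$species_q <- character(0); hits$species_s <- character(0)
    return(hits)
  }
  # best hit per ordered pair
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  ord <- order(key, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(key[ord]), , drop = FALSE]
  hits$species_q <- unname(sp[hits$query_id])
  hits$species_s <- unname(sp[hits$subject_id])
  cross <- !is.na(hits$species_q) & !is.na(hits$species_s) &
    hits$species_q != hits$species_s
  hc <- hits[cross, , drop = FALSE]
  if (nrow(hc) > 0) {
    # single best partner per (query, other species)
    qkey <- paste(hc$query_id, hc$species_s, sep = "\r")
    ord2 <- order(qkey, -hc$bitscore, hc$subject_id)
    hc <- hc[ord2, , drop = FALSE]
    hc <- hc[!duplicated(paste(hc$query_id, hc$species_s, sep = "\r")), ,
             drop = FALSE]
    fwd <- paste(hc$query_id, hc$subject_id, sep = "\r")
    rev <- paste(hc$subject_id, hc$query_id, sep = "\r")
    hc <- hc[fwd %in% rev, , drop = FALSE]  # reciprocal best
    if (!is.null(blocks) && nrow(hc) > 0) {
      bk <- unique(c(paste(blocks$gene_a, blocks$gene_b, sep = "\r"),
                     paste(blocks$gene_b, blocks$gene_a, sep = "\r")))
      hc <- hc[paste(hc$query_id, hc$subject_id, sep = "\r") %in% bk, ,
               drop = FALSE]
    }
  }
  out <- rbind(hits[!cross, , drop = FALSE], hc)
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}

#' Classify one similarity-linked gene pair into its homology relation
#'
#' Different species inside a collinear block: ortholog. Same species,
#' same chromosome: homochromosomal duplication. Same species, different
#' chromosomes: heterochromosomal duplication. Different species outside
#' any collinear block: no relation (NA).
#'
#' @param a,b single-row gene-model data.frames (need \code{gene_id},
#'   \code{species}, \code{chromosome}).
#' @param in_block logical: does the pair lie in a collinear block?
#' @return relation string, or \code{NA_character_} when excluded.
#' @export
classifyPair <- function(a, b, in_block) {
  if (a$gene_id == b$gene_id) stop("self pair: ", a$gene_id)
  if (a$species != b$species) {
    if (isTRUE(in_block)) "ortholog" else NA_character_
  } else if (a$chromosome == b$chromosome) {
    "homochromosomal_duplication"
  } else {
    "heterochromosomal_duplication"
  }
}

#' Build a HomologySet from similarity hits, gene models and collinearity
#'
#' Applies [selectBestHits()], classifies every retained unordered pair
#' with [classifyPair()], and attaches block evidence and the same-type
#' flag. Cross-species pairs outside collinear blocks are excluded.
#'
#' @param hits similarity hits (as from [parseSimilarityHits()]).
#' @param genes gene models (as from [parseGeneModels()]).
#' @param blocks collinear pairs (as from [parseCollinearity()]).
#' @param archset optional [ArchitectureSet-class] used to set
#'   \code{same_type}.
#' @return a [HomologySet-class].
#' @export
buildHomologs <- function(hits, genes, blocks, archset = NULL) {
  best <- selectBestHits(hits, genes, blocks)
  if (nrow(best) > 0) {
    a_first <- pmin(best$query_id, best$subject_id)
    b_second <- pmax(best$query_id, best$subject_id)
    pk <- paste(a_first, b_second, sep = "\r")
    keep <- !duplicated(pk)
    pairs <- data.frame(gene_a = a_first[keep], gene_b = b_second[keep],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(gene_a = character(), gene_b = character())
  }
  gm <- genes
  rownames(gm) <- gm$gene_id
  block_of <- stats::setNames(
    blocks$block_id, paste(pmin(blocks$gene_a, blocks$gene_b),
                           pmax(blocks$gene_a, blocks$gene_b), sep = "\r"))
  types <- if (is.null(archset)) character(0) else
    stats::setNames(archTable(archset)$type_name, archTable(archset)$gene_id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!(ga %in% rownames(gm)) || !(gb %in% rownames(gm))) return(NULL)
    a <- gm[ga, ]; b <- gm[gb, ]
    bid <- unname(block_of[paste(ga, gb, sep = "\r")])
    rel <- classifyPair(a, b, in_block = !is.na(bid))
    if (is.na(rel)) return(NULL)
    st <- if (ga %in% names(types) && gb %in% names(types))
      unname(types[ga]) == unname(types[gb]) else NA
    data.frame(gene_a = ga, gene_b = gb, species_a = a$species,
               species_b = b$species, relation = rel,
               evidence = if (!is.na(bid)) bid else "similarity",
               same_type = st, stringsAsFactors = FALSE)
  })
  ptab <- do.call(rbind, rows)
  if (is.null(ptab))
    ptab <- data.frame(gene_a = character(), gene_b = character(),
                       species_a = character(), species_b = character(),
                       relation = character(), evidence = character(),
                       same_type = logical(), stringsAsFactors = FALSE)
  rownames(ptab) <- NULL
  new("HomologySet", pairs = ptab)
}

#' Census of genes per homology relation
#'
#' Counts the distinct genes participating in at least one pair of each
#' relation type. A gene involved in both an ortholog pair and a
#' duplication pair is counted once in each category.
#'
#' @param homologs a [HomologySet-class].
#' @return named integer vector over the three relation types.
#' @export
pairCensus <- function(homologs) {
  p <- pairTable(homologs)
  vapply(RELATION_LEVELS, function(r) {
    sel <- p$relation == r
    length(unique(c(p$gene_a[sel], p$gene_b[sel])))
  }, integer(1))
}

#' Majority-vote chromosome correspondence between adjacent species
#'
#' For each adjacent species pair in the chain, maps each chromosome of the
#' later species to the chromosome of the earlier species with which it
#' shares the most collinear gene pairs (ties broken by total paired-gene
#' count, then lexicographically).
#'
#' @param blocks collinear pairs with \code{chr_a}/\code{chr_b} and species
#'   columns (as from [parseCollinearity()]).
#' @param species_chain ordered species vector.
#' @return list of named character vectors, one per adjacent pair, mapping
#'   later-species chromosome -> earlier-species chromosome.
#' @export
chromosomeCorrespondence <- function(blocks, species_chain) {
  maps <- list()
  for (i in seq_len(length(species_chain) - 1L)) {
    s1 <- species_chain[i]; s2 <- species_chain[i + 1L]
    fwd <- blocks[blocks$species_a == s1 & blocks$species_b == s2,
                  c("chr_a", "chr_b")]
    bwd <- blocks[blocks$species_a == s2 & blocks$species_b == s1,
                  c("chr_b", "chr_a")]
    names(bwd) <- c("chr_a", "chr_b")
    bb <- rbind(fwd, bwd)  # chr_a in s1, chr_b in s2
    m <- character(0)
    if (nrow(bb) > 0) {
      tt <- as.data.frame(table(bb$chr_b, bb$chr_a),
                          stringsAsFactors = FALSE)
      names(tt) <- c("chr2", "chr1", "n")
      tt <- tt[tt$n > 0, , drop = FALSE]
      tot <- tapply(tt$n, tt$chr1, sum)
      tt$tot <- as.integer(tot[tt$chr1])
      tt <- tt[order(tt$chr2, -tt$n, -tt$tot, tt$chr1), , drop = FALSE]
      tt <- tt[!duplicated(tt$chr2), , drop = FALSE]
      m <- stats::setNames(tt$chr1, tt$chr2)
    }
    maps[[paste(s1, s2, sep = "->")]] <- m
  }
  maps
}

#' Assemble cross-species orthologous lineages
#'
#' Connects genes through ortholog pairs between adjacent species of the
#' chain; each connected chain becomes one lineage. A lineage is complete
#' when every species contributes a member and type-conserved when all
#' member architecture types are identical. The chromosome lineage is the
#' members' chromosomes mapped back to the first species through the
#' collinearity-derived chromosome correspondence.
#'
#' @param homologs a [HomologySet-class] (only ortholog pairs are used).
#' @param genes gene models (species, chromosome per gene).
#' @param species_chain ordered species vector (species-tree order).
#' @param archset optional [ArchitectureSet-class] for member types.
#' @param blocks optional collinear pairs for the chromosome
#'   correspondence; without them each lineage's chromosome lineage is its
#'   anchor member's chromosome.
#' @return a [LineageSet-class].
#' @export
assembleLineages <- function(homologs, genes, species_chain,
                             archset = NULL, blocks = NULL) {
  p <- pairTable(homologs)
  p <- p[p$relation == "ortholog", , drop = FALSE]
  sp <- stats::setNames(genes$species, genes$gene_id)
  chrom <- stats::setNames(genes$chromosome, genes$gene_id)
  types <- if (is.null(archset)) character(0) else
    stats::setNames(archTable(archset)$type_name, archTable(archset)$gene_id)
  adj <- abs(match(p$species_a, species_chain) -
               match(p$species_b, species_chain)) == 1
  adj[is.na(adj)] <- FALSE
  p <- p[adj, , drop = FALSE]
  p <- p[order(p$gene_a, p$gene_b), , drop = FALSE]
  # union-find over genes
  parent <- new.env(parent = emptyenv())
  find <- function(x) {
    r <- x
    while (!is.null(px <- parent[[r]]) && px != r) r <- px
    if (is.null(parent[[r]])) parent[[r]] <- r
    r
  }
  for (i in seq_len(nrow(p))) {
    ra <- find(p$gene_a[i]); rb <- find(p$gene_b[i])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  members_of <- split(
    unique(c(p$gene_a, p$gene_b)),
    vapply(unique(c(p$gene_a, p$gene_b)), find, character(1)))
  # deterministic lineage order: by sorted first member id
  members_of <- members_of[order(vapply(members_of, function(g)
    min(g), character(1)))]
  cmaps <- if (!is.null(blocks))
    chromosomeCorrespondence(blocks, species_chain) else
      replicate(max(length(species_chain) - 1L, 0L), character(0),
                simplify = FALSE)
  mapToFirst <- function(chr, species) {
    i <- match(species, species_chain)
    while (!is.na(i) && i > 1) {
      m <- cmaps[[i - 1L]]
      chr <- if (chr %in% names(m)) unname(m[chr]) else NA_character_
      if (is.na(chr)) return(NA_character_)
      i <- i - 1L
    }
    chr
  }
  mrows <- list(); frows <- list()
  for (k in seq_along(members_of)) {
    g <- sort(members_of[[k]])
    gsp <- unname(sp[g])
    if (anyDuplicated(gsp))
      stop("conflicting lineage: genes ",
           paste(g[gsp %in% gsp[duplicated(gsp)]], collapse = ", "),
           " share species ", gsp[duplicated(gsp)][1])
    lid <- sprintf("lin_%03d", k)
    ord <- order(match(gsp, species_chain))
    g <- g[ord]; gsp <- gsp[ord]
    ty <- ifelse(g %in% names(types), unname(types[g]), NA_character_)
    mapped <- mapply(mapToFirst, unname(chrom[g]), gsp)
    anchor <- if (!all(is.na(mapped)))
      stats::na.omit(mapped)[1] else unname(chrom[g])[1]
    mrows[[k]] <- data.frame(lineage_id = lid, species = gsp, gene_id = g,
                             chromosome = unname(chrom[g]), type_name = ty,
                             stringsAsFactors = FALSE)
    frows[[k]] <- data.frame(
      lineage_id = lid,
      complete = all(species_chain %in% gsp),
      type_conserved = !anyNA(ty) && length(unique(ty)) == 1,
      chromosome_lineage = anchor, stringsAsFactors = FALSE)
  }
  members <- if (length(mrows)) do.call(rbind, mrows) else
    data.frame(lineage_id = character(), species = character(),
               gene_id = character(), chromosome = character(),
               type_name = character(), stringsAsFactors = FALSE)
  flags <- if (length(frows)) do.call(rbind, frows) else
    data.frame(lineage_id = character(), complete = logical(),
               type_conserved = logical(),
               chromosome_lineage = character(), stringsAsFactors = FALSE)
  rownames(members) <- rownames(flags) <- NULL
  new("LineageSet", members = members, flags = flags,
      species_chain = species_chain)
}

#' Summary statistics over a set of lineages
#'
#' @param lineages a [LineageSet-class].
#' @return named integer vector: \code{total}, \code{incomplete_count},
#'   \code{type_changed_count}, \code{chromosome_lineage_count}.
#' @export
lineageStats <- function(lineages) {
  f <- lineageFlags(lineages)
  c(total = nrow(f),
    incomplete_count = sum(!f$complete),
    type_changed_count = sum(!f$type_conserved),
    chromosome_lineage_count = length(unique(f$chromosome_lineage)))
}
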