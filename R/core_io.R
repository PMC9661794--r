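# Readers and writers for the external formats the pipeline consumes:
# tab-separated domain-hit tables, MCScanX-style collinearity text, GFF3
# gene models, 12-column BLAST tabular hits, per-residue coiled-coil score
# tracks, PlantCARE-style cis-element exports, count matrices and Newick
# species trees. Coordinates are 1-based inclusive throughout.

# Pfam accession -> domain class letter. NB-ARC is N, TIR is T, RPW8 is R,
# and the seven LRR repeat models all collapse to L.
PFAM_CLASS_MAP <- c(
  PF00931 = "N",
  PF01582 = "T",
  PF05659 = "R",
  PF00560 = "L", PF07723 = "L", PF07725 = "L", PF12799 = "L",
  PF13306 = "L", PF08191 = "L", PF13855 = "L"
)

#' Map a domain model accession (or bare class letter) to its class letter
#'
#' @param x character vector of Pfam-style accessions (version suffixes are
#'   tolerated, e.g. \code{PF00931.23}) or bare letters in {N,T,C,L,R}.
#' @return character vector of class letters; \code{NA} where unmapped.
#' @export
domainClassOf <- function(x) {
  bare <- sub("\\..*$", "", x)
  out <- ifelse(bare %in% DOMAIN_LETTERS, bare,
                unname(PFAM_CLASS_MAP[bare]))
  out
}

#' Read a domain-hit table
#'
#' Reads a tab-separated table of significant domain matches with columns
#' \code{protein_id}, \code{domain} (a class letter or a model accession),
#' \code{start}, \code{end}, \code{evalue}. Hits above the significance
#' threshold are dropped; accessions are mapped to class letters; rows with
#' unmappable accessions are skipped with a warning. Input order is kept.
#'
#' @param path file path.
#' @param evalue_max keep hits with evalue <= this (default 1e-10).
#' @return data.frame with columns \code{protein_id}, \code{domain_class},
#'   \code{start}, \code{end}, \code{evalue}, \code{source}.
#' @export
parseDomainHits <- function(path, evalue_max = 1e-10) {
  lines <- readLinesChecked(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(emptyDomainHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_ok <- lengths(fields) >= 5
  if (any(!n_ok))
    stop("malformed domain-hit row at line ", which(!n_ok)[1],
         ": expected 5 tab-separated columns")
  mat <- do.call(rbind, lapply(fields, `[`, 1:5))
  start <- suppressWarnings(as.integer(mat[, 3]))
  end <- suppressWarnings(as.integer(mat[, 4]))
  evalue <- suppressWarnings(as.numeric(mat[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(evalue) |
                 start < 1 | end < start)
  if (length(bad) > 0)
    stop("malformed domain-hit row at line ", bad[1],
         ": bad coordinates or evalue")
  cls <- domainClassOf(mat[, 2])
  if (anyNA(cls)) {
    unk <- unique(mat[is.na(cls), 2])
    warning("skipping hits with unmapped domain accession(s): ",
            paste(unk, collapse = ", "))
  }
  keep <- !is.na(cls) & evalue <= evalue_max
  data.frame(protein_id = mat[keep, 1], domain_class = cls[keep],
             start = start[keep], end = end[keep], evalue = evalue[keep],
             source = mat[keep, 2], stringsAsFactors = FALSE)
}

emptyDomainHits <- function() {
  data.frame(protein_id = character(), domain_class = character(),
             start = integer(), end = integer(), evalue = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

#' Write a domain-hit table in the dialect parseDomainHits reads
#' @param hits data.frame as returned by [parseDomainHits()].
#' @param path output file path.
#' @export
writeDomainHits <- function(hits, path) {
  df <- data.frame(hits$protein_id, hits$source, hits$start, hits$end,
                   format(hits$evalue, scientific = TRUE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read MCScanX-style collinearity text
#'
#' Blocks open with a \code{## Alignment} header line; each following line
#' is one gene pair. Blocks with zero pairs are dropped with a warning.
#'
#' @param path file path.
#' @return data.frame with columns \code{block_id}, \code{species_a},
#'   \code{species_b}, \code{chr_a}, \code{chr_b}, \code{gene_a},
#'   \code{gene_b} (one row per pair, block order preserved).
#' @export
parseCollinearity <- function(path) {
  lines <- readLinesChecked(path)
  lines <- lines[!grepl("^#[^#]", lines)]  # drop '# ...' comment lines
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^## Alignment", ln)) {
      cur <- parseAlignmentHeader(ln)
      out[[length(out) + 1L]] <- list(header = cur, pairs = list())
    } else {
      if (is.null(cur))
        stop("collinearity pair line before any '## Alignment' header")
      fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
      fields <- fields[nzchar(fields)]
      # dialect: '<block>- <idx>: geneA geneB score'; genes are the two
      # fields before the trailing score (or the last two fields)
      gidx <- grep("^[A-Za-z]", fields)
      if (length(gidx) < 2)
        stop("cannot find two gene ids in collinearity line: ", ln)
      pr <- fields[gidx[1:2]]
      blk <- out[[length(out)]]
      blk$pairs[[length(blk$pairs) + 1L]] <- pr
      out[[length(out)]] <- blk
    }
  }
  rows <- list()
  for (blk in out) {
    if (length(blk$pairs) == 0) {
      warning("dropping collinear block '", blk$header$block_id,
              "' with zero gene pairs")
      next
    }
    pm <- do.call(rbind, blk$pairs)
    rows[[length(rows) + 1L]] <- data.frame(
      block_id = blk$header$block_id,
      species_a = blk$header$species_a, species_b = blk$header$species_b,
      chr_a = blk$header$chr_a, chr_b = blk$header$chr_b,
      gene_a = pm[, 1], gene_b = pm[, 2], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(block_id = character(), species_a = character(),
                      species_b = character(), chr_a = character(),
                      chr_b = character(), gene_a = character(),
                      gene_b = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

parseAlignmentHeader <- function(ln) {
  # '## Alignment 3: score=... e_value=... N=... speA_chr2&speB_chr5 plus'
  num <- sub("^## Alignment ([^:]+):.*$", "\\1", ln)
  chrs <- regmatches(ln, regexpr("[^ ]+&[^ ]+", ln))
  chr_a <- chr_b <- NA_character_
  species_a <- species_b <- NA_character_
  if (length(chrs) == 1) {
    parts <- strsplit(chrs, "&", fixed = TRUE)[[1]]
    chr_a <- parts[1]; chr_b <- parts[2]
    species_a <- sub("_[^_]*$", "", chr_a)
    species_b <- sub("_[^_]*$", "", chr_b)
  }
  list(block_id = paste0("block_", num), species_a = species_a,
       species_b = species_b, chr_a = chr_a, chr_b = chr_b)
}

#' Write collinear blocks in the dialect parseCollinearity reads
#' @param blocks data.frame as returned by [parseCollinearity()].
#' @param path output file path.
#' @export
writeCollinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synthetic collinearity file", con)
  if (nrow(blocks) > 0) {
    for (bid in unique(blocks$block_id)) {
      b <- blocks[blocks$block_id == bid, , drop = FALSE]
      num <- sub("^block_", "", bid)
      writeLines(sprintf(
        "## Alignment %s: score=100.0 e_value=0 N=%d %s&%s plus",
        num, nrow(b), b$chr_a[1], b$chr_b[1]), con)
      writeLines(sprintf("%s-  %d:\t%s\t%s\t      0",
                         num, seq_len(nrow(b)) - 1L, b$gene_a, b$gene_b),
                 con)
    }
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses gene features for span and chromosome and counts exon features per
#' gene (linked by Parent/ID attributes, mRNA level tolerated). Genes with
#' no exon children are assigned \code{exon_count = 1} with a warning,
#' matching the prevalence of single-exon resistance genes.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns \code{gene_id}, \code{species},
#'   \code{chromosome}, \code{start}, \code{end}, \code{strand},
#'   \code{exon_count}, \code{gene_length}.
#' @export
parseGeneModels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0)
    return(data.frame(gene_id = character(), species = character(),
                      chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      exon_count = integer(), gene_length = integer(),
                      stringsAsFactors = FALSE))
  gid <- as.character(genes$ID)
  species <- if ("species" %in% names(genes))
    as.character(genes$species) else rep(NA_character_, nrow(genes))
  # map mRNA IDs up to their gene so exon Parents resolve either way
  parent_of <- character(0)
  mrna <- gff[gff$type == "mRNA", , drop = FALSE]
  if (nrow(mrna) > 0) {
    mp <- vapply(mrna$Parent, function(p) as.character(p)[1], character(1))
    parent_of[as.character(mrna$ID)] <- mp
  }
  exons <- gff[gff$type == "exon", , drop = FALSE]
  exon_parent <- character(0)
  if (nrow(exons) > 0) {
    ep <- vapply(exons$Parent, function(p)
      if (length(p) == 0) NA_character_ else as.character(p)[1], character(1))
    resolved <- ifelse(ep %in% gid, ep, unname(parent_of[ep]))
    if (anyNA(resolved))
      warning("skipping ", sum(is.na(resolved)),
              " exon(s) with unresolvable Parent")
    exon_parent <- resolved[!is.na(resolved)]
  }
  cnt <- table(exon_parent)
  exon_count <- as.integer(cnt[gid])
  if (anyNA(exon_count)) {
    warning(sum(is.na(exon_count)),
            " gene(s) without exon features: assuming exon_count = 1")
    exon_count[is.na(exon_count)] <- 1L
  }
  data.frame(gene_id = gid, species = species,
             chromosome = as.character(genes$seqid),
             start = as.integer(genes$start), end = as.integer(genes$end),
             strand = as.character(genes$strand),
             exon_count = exon_count,
             gene_length = as.integer(genes$end - genes$start + 1L),
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3 in the dialect parseGeneModels reads
#' @param genes data.frame as returned by [parseGeneModels()].
#' @param path output file path.
#' @export
writeGeneModels <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf(
      "%s\tnbslineage\tgene\t%d\t%d\t.\t%s\t.\tID=%s;species=%s",
      g$chromosome, g$start, g$end, g$strand, g$gene_id, g$species), con)
    # evenly spaced exons inside the gene span
    k <- g$exon_count
    bounds <- round(seq(g$start, g$end + 1L, length.out = 2L * k + 1L))
    for (j in seq_len(k)) {
      es <- bounds[2L * j - 1L]
      ee <- max(es, bounds[2L * j] - 1L)
      writeLines(sprintf(
        "%s\tnbslineage\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        g$chromosome, es, ee, g$strand, g$gene_id), con)
    }
  }
  invisible(path)
}

#' Read 12-column BLAST tabular similarity hits
#'
#' @param path file path (outfmt 6 / -m 8 style).
#' @param evalue_max keep hits with evalue <= this (default 1e-10, the
#'   all-vs-all search cutoff).
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{alignment_length}, \code{evalue},
#'   \code{bitscore}.
#' @export
parseSimilarityHits <- function(path, evalue_max = 1e-10) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE,
                      col.names = c("query_id", "subject_id",
                                    "percent_identity", "alignment_length",
                                    "mismatches", "gap_opens", "q_start",
                                    "q_end", "s_start", "s_end", "evalue",
                                    "bitscore")),
    error = function(e) NULL)
  if (is.null(raw))
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(),
                      alignment_length = integer(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  keep <- raw$evalue <= evalue_max
  data.frame(query_id = raw$query_id[keep],
             subject_id = raw$subject_id[keep],
             percent_identity = raw$percent_identity[keep],
             alignment_length = as.integer(raw$alignment_length[keep]),
             evalue = raw$evalue[keep], bitscore = raw$bitscore[keep],
             stringsAsFactors = FALSE)
}

#' Write similarity hits as 12-column BLAST tabular
#' @param hits data.frame as returned by [parseSimilarityHits()].
#' @param path output file path.
#' @export
writeSimilarityHits <- function(hits, path) {
  n <- nrow(hits)
  df <- data.frame(hits$query_id, hits$subject_id, hits$percent_identity,
                   hits$alignment_length, rep(0L, n), rep(0L, n),
                   rep(1L, n), hits$alignment_length, rep(1L, n),
                   hits$alignment_length,
                   format(hits$evalue, scientific = TRUE, trim = TRUE),
                   hits$bitscore)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-residue coiled-coil score tracks
#'
#' Long tab-separated format with columns \code{protein_id},
#' \code{position}, \code{score}; one row per residue, scores in [0, 1].
#'
#' @param path file path.
#' @return named list of numeric score vectors, one per protein.
#' @export
parseCoilTracks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) return(list())
  if (!all(c("protein_id", "position", "score") %in% names(raw)))
    stop("coil-track file must have columns protein_id, position, score")
  if (any(raw$score < 0 | raw$score > 1))
    stop("coiled-coil scores must lie in [0, 1]")
  out <- split(raw[, c("position", "score")], raw$protein_id)
  lapply(out, function(df) {
    df <- df[order(df$position), ]
    if (!identical(as.integer(df$position), seq_len(nrow(df))))
      stop("coil track positions must be 1..protein_length")
    df$score
  })
}

#' Write coiled-coil score tracks in the dialect parseCoilTracks reads
#' @param tracks named list of per-residue score vectors.
#' @param path output file path.
#' @export
writeCoilTracks <- function(tracks, path) {
  dfs <- lapply(names(tracks), function(p)
    data.frame(protein_id = p, position = seq_along(tracks[[p]]),
               score = tracks[[p]]))
  df <- if (length(dfs) == 0)
    data.frame(protein_id = character(), position = integer(),
               score = numeric()) else do.call(rbind, dfs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PlantCARE-style cis-element export
#'
#' Tab-separated with header; columns \code{gene_id}, \code{element_name},
#' \code{position} (bases upstream of the translational start, 1..2000),
#' \code{strand}, \code{function_label}.
#'
#' @param path file path.
#' @return data.frame of cis-element occurrences.
#' @export
parseCisElements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "element_name", "position")
  if (!all(need %in% names(raw)))
    stop("cis-element file must have columns: ",
         paste(need, collapse = ", "))
  if (any(raw$position < 1 | raw$position > 2000))
    stop("cis-element positions must lie in [1, 2000] bp upstream")
  if (!"function_label" %in% names(raw)) raw$function_label <- NA_character_
  if (!"strand" %in% names(raw)) raw$strand <- "+"
  raw[, c("gene_id", "element_name", "position", "strand",
          "function_label")]
}

#' Read a count matrix with gene lengths
#'
#' Tab-separated with header: first column gene ids, a \code{length} column
#' in bases, remaining columns per-sample integer counts.
#'
#' @param path file path.
#' @return list with \code{counts} (integer matrix, genes x samples) and
#'   \code{gene_lengths} (named numeric vector).
#' @export
parseCountMatrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"length" %in% names(raw))
    stop("count matrix must have a 'length' column")
  gene_ids <- raw[[1]]
  lens <- raw$length
  samp <- setdiff(names(raw), c(names(raw)[1], "length"))
  counts <- as.matrix(raw[, samp, drop = FALSE])
  rownames(counts) <- gene_ids
  storage.mode(counts) <- "integer"
  names(lens) <- gene_ids
  list(counts = counts, gene_lengths = lens)
}

#' Read a species tree and return the tip order as a species chain
#'
#' @param path Newick file path.
#' @return character vector of tip labels in tree (ladder) order.
#' @export
speciesChainFromTree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("cannot read Newick tree from ", path)
  tree$tip.label
}

readLinesChecked <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  readLines(path, warn = FALSE)
}
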