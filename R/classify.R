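# Architecture classification: coiled-coil segment calling from per-residue
# score tracks, same-class hit merging, domain-letter ordering, the NBS type
# and subclass labels, and the type-by-species summary table.

#' Call coiled-coil (C) segments from a per-residue score track
#'
#' Maximal runs of at least \code{min_len} consecutive residues scoring at
#' or above \code{threshold} become C-class domain hits spanning the run.
#'
#' @param scores numeric vector of per-residue scores in [0, 1].
#' @param protein_id identifier attached to the returned hits.
#' @param threshold score cutoff (default 0.5).
#' @param min_len minimal run length in residues (default 8).
#' @return data.frame of C-class domain hits (possibly zero rows).
#' @export
detectCC <- function(scores, protein_id = "protein", threshold = 0.5,
                     min_len = 8) {
  stopifnot(all(scores >= 0 & scores <= 1))
  if (length(scores) == 0) return(emptyDomainHits())
  r <- rle(scores >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(emptyDomainHits())
  data.frame(protein_id = protein_id, domain_class = "C",
             start = starts[keep], end = ends[keep],
             evalue = 0, source = "coil_track", stringsAsFactors = FALSE)
}

#' Merge same-class domain hits into ordered architecture letters
#'
#' Hits of the same class whose residue intervals overlap or are separated
#' by at most \code{gap_max} residues are merged into one domain unit;
#' different classes never merge. Units are then ordered along the protein
#' by interval midpoint (ties by start, then class letter), yielding the
#' architecture letter sequence. Repeated letters survive (NN, NLNL, ...):
#' only proximity collapses same-class hits, as when a run of LRR repeat
#' matches becomes a single L.
#'
#' @param hits data.frame of domain hits for ONE protein (columns
#'   \code{domain_class}, \code{start}, \code{end}).
#' @param gap_max maximal residue gap between merged same-class hits
#'   (default 150).
#' @return data.frame with columns \code{letter}, \code{start}, \code{end},
#'   one row per merged unit in protein order.
#' @export
mergeHits <- function(hits, gap_max = 150) {
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(letter = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  stopifnot(all(hits$end >= hits$start))
  units <- list()
  for (cls in unique(hits$domain_class)) {
    h <- hits[hits$domain_class == cls, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    cs <- h$start[1]; ce <- h$end[1]
    for (i in seq_len(nrow(h))[-1]) {
      gap <- h$start[i] - ce - 1L
      if (gap <= gap_max) {
        ce <- max(ce, h$end[i])
      } else {
        units[[length(units) + 1L]] <- c(cls, cs, ce)
        cs <- h$start[i]; ce <- h$end[i]
      }
    }
    units[[length(units) + 1L]] <- c(cls, cs, ce)
  }
  m <- do.call(rbind, units)
  out <- data.frame(letter = m[, 1], start = as.integer(m[, 2]),
                    end = as.integer(m[, 3]), stringsAsFactors = FALSE)
  mid <- (out$start + out$end) / 2
  out <- out[order(mid, out$start, out$letter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one gene's architecture letters into its NBS type
#'
#' The type name is the concatenated letter string (CNL, NL, CNLCN, ...).
#' The gene belongs to the NBS-LRR subclass when it retains both an NB-ARC
#' (N) and an LRR (L) domain; otherwise it is non-NBS-LRR. A gene with no
#' N at all is not an NBS gene.
#'
#' @param letters character vector of ordered architecture letters.
#' @return list with \code{type_name}, \code{subclass}, \code{is_nbs}.
#' @export
classifyArchitecture <- function(letters) {
  if (length(letters) == 0)
    stop("empty architecture: gene has no domain letters to classify")
  stopifnot(all(letters %in% DOMAIN_LETTERS))
  type_name <- paste(letters, collapse = "")
  has_n <- "N" %in% letters
  has_l <- "L" %in% letters
  list(type_name = type_name,
       subclass = if (has_n && has_l) "NBS-LRR" else "non-NBS-LRR",
       is_nbs = has_n)
}

#' Build an ArchitectureSet from domain hits and coiled-coil tracks
#'
#' Runs the full per-gene classification: coiled-coil segments are called
#' from the score tracks, pooled with the tabulated domain hits, merged
#' with [mergeHits()] and classified with [classifyArchitecture()]. Genes
#' whose merged letters are empty are dropped.
#'
#' @param hits data.frame of domain hits over all proteins (as from
#'   [parseDomainHits()]).
#' @param coil_tracks named list of per-residue score vectors (as from
#'   [parseCoilTracks()]); may be empty.
#' @param species named character vector mapping gene_id to species, or a
#'   single species label for all genes.
#' @param gap_max same-class merge gap (default 150 residues).
#' @param cc_threshold coiled-coil score cutoff (default 0.5).
#' @param cc_min_len minimal coiled-coil run (default 8 residues).
#' @return an [ArchitectureSet-class] covering every gene with at least one
#'   domain letter (NBS or not; filter with \code{is_nbs} downstream).
#' @export
buildArchitectures <- function(hits, coil_tracks = list(), species = NA,
                               gap_max = 150, cc_threshold = 0.5,
                               cc_min_len = 8) {
  cc <- lapply(names(coil_tracks), function(p)
    detectCC(coil_tracks[[p]], p, cc_threshold, cc_min_len))
  all_hits <- rbind(hits[, c("protein_id", "domain_class", "start", "end")],
                    do.call(rbind, c(list(emptyDomainHits()[, c(
                      "protein_id", "domain_class", "start", "end")]),
                      lapply(cc, `[`, , c("protein_id", "domain_class",
                                          "start", "end")))))
  ids <- sort(unique(all_hits$protein_id))
  rows <- lapply(ids, function(g) {
    merged <- mergeHits(all_hits[all_hits$protein_id == g, , drop = FALSE],
                        gap_max = gap_max)
    if (nrow(merged) == 0) return(NULL)
    cls <- classifyArchitecture(merged$letter)
    sp <- if (length(species) == 1 && is.null(names(species)))
      species else unname(species[g])
    data.frame(gene_id = g, species = as.character(sp),
               type_name = cls$type_name, subclass = cls$subclass,
               is_nbs = cls$is_nbs, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(gene_id = character(), species = character(),
                      type_name = character(), subclass = character(),
                      is_nbs = logical(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("ArchitectureSet", table = tab)
}

#' Type-by-species count table with subclass subtotals
#'
#' Summarizes an [ArchitectureSet-class] into the classic resistance-gene
#' survey table: one row per architecture type grouped by subclass, one
#' column per species, plus subclass subtotals, per-species totals and the
#' grand total. Only NBS genes (architectures containing an N) are counted;
#' non-NBS genes are returned separately.
#'
#' @param archset an [ArchitectureSet-class].
#' @return list with \code{counts} (type x species integer matrix, rows
#'   ordered NBS-LRR types first), \code{subclass_totals} (2 x species),
#'   \code{species_totals}, \code{grand_total} and \code{non_nbs}
#'   (data.frame of excluded genes without any N domain).
#' @export
typeCountTable <- function(archset) {
  tab <- archTable(archset)
  non_nbs <- tab[!tab$is_nbs, , drop = FALSE]
  tab <- tab[tab$is_nbs, , drop = FALSE]
  species <- sort(unique(archTable(archset)$species))
  if (nrow(tab) == 0) {
    counts <- matrix(0L, 0, length(species),
                     dimnames = list(NULL, species))
    sub_tot <- matrix(0L, 2, length(species),
                      dimnames = list(c("NBS-LRR", "non-NBS-LRR"), species))
    return(list(counts = counts, subclass_totals = sub_tot,
                species_totals = stats::setNames(integer(length(species)),
                                                 species),
                grand_total = 0L, non_nbs = non_nbs))
  }
  types <- unique(tab[, c("type_name", "subclass")])
  types <- types[order(types$subclass != "NBS-LRR", types$type_name), ]
  counts <- matrix(0L, nrow(types), length(species),
                   dimnames = list(types$type_name, species))
  xt <- table(tab$type_name, tab$species)
  counts[rownames(xt), colnames(xt)] <- as.integer(xt)
  sub_tot <- rbind(
    "NBS-LRR" = colSums(counts[types$subclass == "NBS-LRR", , drop = FALSE]),
    "non-NBS-LRR" = colSums(counts[types$subclass == "non-NBS-LRR", ,
                                   drop = FALSE]))
  storage.mode(sub_tot) <- "integer"
  species_totals <- colSums(sub_tot)
  list(counts = counts, subclass_totals = sub_tot,
       species_totals = species_totals,
       grand_total = sum(species_totals), non_nbs = non_nbs)
}

#' Pearson correlation with exact two-sided p-value
#'
#' Thin, validating front end to the exact t-transform test on n - 2
#' degrees of freedom, used for the exon-count versus gene-length structure
#' statistic and for module-trait correlation.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with \code{r} and \code{p}.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Exon-count versus gene-length correlation
#'
#' The structure statistic for a gene set: Pearson correlation between the
#' number of exons and the genomic gene length.
#'
#' @param gene_models data.frame as from [parseGeneModels()].
#' @return list with \code{r} and \code{p}.
#' @export
structureCorrelation <- function(gene_models) {
  pearsonR(gene_models$exon_count, gene_models$gene_length)
}

#' Is a gene's motif order consistent with the canonical order?
#'
#' Motifs absent from the canonical order are ignored; the remaining motif
#' ids must form a subsequence of the canonical permutation (missing motifs
#' are allowed, reordering is not).
#'
#' @param motif_ids integer vector of motif indices in positional order.
#' @param canonical integer vector, a permutation of distinct motif ids
#'   (default the conserved NL/CNL order 6,5,3,1,7,2,8,4).
#' @return logical scalar.
#' @export
motifOrderConserved <- function(motif_ids,
                                canonical = c(6, 5, 3, 1, 7, 2, 8, 4)) {
  if (anyDuplicated(canonical)) stop("canonical order must be distinct")
  obs <- motif_ids[motif_ids %in% canonical]
  if (length(obs) == 0) return(TRUE)
  pos <- 1L
  for (m in obs) {
    if (pos > length(canonical)) return(FALSE)
    hit <- match(m, canonical[pos:length(canonical)])
    if (is.na(hit)) return(FALSE)
    pos <- pos + hit
  }
  TRUE
}

#' Load a published-style type-by-species count table
#'
#' Reads a wide tab-separated table (one row per architecture type, one
#' column per species) such as the packaged six-orchid NBS survey counts,
#' and returns it in long form.
#'
#' @param path file path; default the packaged orchid survey table.
#' @return data.frame with columns \code{type_name}, \code{species},
#'   \code{count}.
#' @export
loadTypeCounts <- function(path = system.file(
  "extdata", "orchid_nbs_type_counts.tsv", package = "nbslineage")) {
  wide <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  species <- setdiff(names(wide), "type")
  long <- do.call(rbind, lapply(species, function(s)
    data.frame(type_name = wide$type, species = s, count = wide[[s]],
               stringsAsFactors = FALSE)))
  long[long$count > 0, , drop = FALSE]
}

#' Expand type counts into a per-gene ArchitectureSet
#'
#' Turns a long count table (as from [loadTypeCounts()]) into one
#' architecture record per gene, so summary operations can be exercised on
#' published count tables as inputs.
#'
#' @param counts data.frame with \code{type_name}, \code{species},
#'   \code{count}.
#' @return an [ArchitectureSet-class].
#' @export
expandTypeCounts <- function(counts) {
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    ty <- counts$type_name[i]
    data.frame(
      gene_id = sprintf("%s_%s_%03d", counts$species[i], ty,
                        seq_len(counts$count[i])),
      species = counts$species[i], type_name = ty,
      subclass = if (grepl("N", ty) && grepl("L", ty)) "NBS-LRR" else
        "non-NBS-LRR",
      is_nbs = grepl("N", ty), stringsAsFactors = FALSE)
  }))
  new("ArchitectureSet", table = rows)
}
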