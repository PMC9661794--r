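#' @import methods
NULL

DOMAIN_LETTERS <- c("N", "T", "C", "L", "R")

#' ArchitectureSet: per-gene domain architectures
#'
#' Container for the classified domain architectures of a set of genes.
#' Each row records a gene's ordered domain-letter string over the alphabet
#' {C, N, T, L, R} (coiled-coil, NB-ARC, TIR, LRR, RPW8), its type name
#' (the letter string itself, e.g. \code{CNL}), its subclass
#' (\code{NBS-LRR} when both an N and an L are present, otherwise
#' \code{non-NBS-LRR}) and whether the gene is an NBS gene at all
#' (contains at least one N).
#'
#' @slot table data.frame with columns \code{gene_id}, \code{species},
#'   \code{type_name}, \code{subclass}, \code{is_nbs}.
#' @export
setClass("ArchitectureSet", representation(table = "data.frame"))

setValidity("ArchitectureSet", function(object) {
  tab <- object@table
  need <- c("gene_id", "species", "type_name", "subclass", "is_nbs")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tab) == 0) return(TRUE)
  letters_ok <- vapply(strsplit(tab$type_name, ""), function(l)
    all(l %in% DOMAIN_LETTERS), logical(1))
  if (!all(letters_ok))
    return("type_name must use only the letters C, N, T, L, R")
  has_n <- grepl("N", tab$type_name, fixed = TRUE)
  has_l <- grepl("L", tab$type_name, fixed = TRUE)
  if (!all(tab$is_nbs == has_n))
    return("is_nbs must equal presence of an N letter")
  expect_sub <- ifelse(has_n & has_l, "NBS-LRR", "non-NBS-LRR")
  if (!all(tab$subclass == expect_sub))
    return("subclass must be NBS-LRR iff the architecture has both N and L")
  if (anyDuplicated(tab$gene_id))
    return("gene_id values must be unique")
  TRUE
})

#' HomologySet: typed homolog pairs
#'
#' Homolog pairs classified into the three relation types used for
#' resistance-gene family evolution: \code{ortholog} (different species,
#' supported by a collinear block), \code{homochromosomal_duplication}
#' (same species, same chromosome) and \code{heterochromosomal_duplication}
#' (same species, different chromosomes).
#'
#' @slot pairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{species_a}, \code{species_b}, \code{relation}, \code{evidence},
#'   \code{same_type}.
#' @export
setClass("HomologySet", representation(pairs = "data.frame"))

RELATION_LEVELS <- c("ortholog", "homochromosomal_duplication",
                     "heterochromosomal_duplication")

setValidity("HomologySet", function(object) {
  p <- object@pairs
  need <- c("gene_a", "gene_b", "species_a", "species_b", "relation",
            "evidence", "same_type")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) == 0) return(TRUE)
  if (!all(p$relation %in% RELATION_LEVELS))
    return("unknown relation type")
  orth <- p$relation == "ortholog"
  if (any(p$species_a[orth] == p$species_b[orth]))
    return("ortholog pairs must join different species")
  if (any(p$species_a[!orth] != p$species_b[!orth]))
    return("duplication pairs must be within one species")
  if (any(p$gene_a == p$gene_b))
    return("self pairs are not allowed")
  TRUE
})

#' LineageSet: cross-species orthologous lineages
#'
#' An orthologous lineage is a chain of NBS genes connected by ortholog
#' pairs across an ordered set of species. A lineage is \emph{complete}
#' when every species of the chain contributes a member; missing members
#' indicate gene degeneration. It is \emph{type conserved} when all
#' members share one architecture type.
#'
#' @slot members data.frame with columns \code{lineage_id}, \code{species},
#'   \code{gene_id}, \code{chromosome}, \code{type_name}.
#' @slot flags data.frame with one row per lineage: \code{lineage_id},
#'   \code{complete}, \code{type_conserved}, \code{chromosome_lineage}.
#' @slot species_chain character vector, the species order used.
#' @export
setClass("LineageSet", representation(members = "data.frame",
                                      flags = "data.frame",
                                      species_chain = "character"))

setValidity("LineageSet", function(object) {
  m <- object@members; f <- object@flags
  if (!all(c("lineage_id", "species", "gene_id", "chromosome",
             "type_name") %in% names(m)))
    return("members is missing required columns")
  if (!all(c("lineage_id", "complete", "type_conserved",
             "chromosome_lineage") %in% names(f)))
    return("flags is missing required columns")
  if (nrow(f) > 0 && anyDuplicated(f$lineage_id))
    return("duplicate lineage_id in flags")
  if (!setequal(unique(m$lineage_id), f$lineage_id))
    return("members and flags disagree on lineage ids")
  if (nrow(m) > 0 && anyDuplicated(m$gene_id))
    return(paste("gene(s) assigned to more than one lineage:",
                 paste(unique(m$gene_id[duplicated(m$gene_id)]),
                       collapse = ", ")))
  TRUE
})

#' @describeIn ArchitectureSet number of classified genes
#' @param x an ArchitectureSet
#' @export
setMethod("length", "ArchitectureSet", function(x) nrow(x@table))

setMethod("show", "ArchitectureSet", function(object) {
  tab <- object@table
  cat("ArchitectureSet with", nrow(tab), "gene(s) in",
      length(unique(tab$species)), "species\n")
  if (nrow(tab) > 0) {
    cat("  NBS-LRR:", sum(tab$subclass == "NBS-LRR"),
        " non-NBS-LRR:", sum(tab$subclass == "non-NBS-LRR"),
        " non-NBS:", sum(!tab$is_nbs), "\n")
    tt <- sort(table(tab$type_name), decreasing = TRUE)
    cat("  top types:", paste(names(tt)[seq_len(min(5, length(tt)))],
                              collapse = ", "), "\n")
  }
})

setMethod("show", "HomologySet", function(object) {
  p <- object@pairs
  cat("HomologySet with", nrow(p), "pair(s)\n")
  if (nrow(p) > 0)
    for (r in RELATION_LEVELS)
      cat(sprintf("  %s: %d\n", r, sum(p$relation == r)))
})

setMethod("show", "LineageSet", function(object) {
  f <- object@flags
  cat("LineageSet with", nrow(f), "lineage(s) over species chain",
      paste(object@species_chain, collapse = " -> "), "\n")
  if (nrow(f) > 0)
    cat("  complete:", sum(f$complete),
        " type-conserved:", sum(f$type_conserved),
        " chromosome lineages:", length(unique(f$chromosome_lineage)), "\n")
})

#' Accessor for the architecture table
#' @param x an ArchitectureSet
#' @return data.frame of per-gene architectures
#' @export
archTable <- function(x) {
  stopifnot(is(x, "ArchitectureSet"))
  x@table
}

#' Accessor for the homolog-pair table
#' @param x a HomologySet
#' @return data.frame of typed pairs
#' @export
pairTable <- function(x) {
  stopifnot(is(x, "HomologySet"))
  x@pairs
}

#' Accessors for lineage membership and flags
#' @param x a LineageSet
#' @return data.frame of lineage members (or per-lineage flags)
#' @export
lineageMembers <- function(x) {
  stopifnot(is(x, "LineageSet"))
  x@members
}

#' @rdname lineageMembers
#' @export
lineageFlags <- function(x) {
  stopifnot(is(x, "LineageSet"))
  x@flags
}
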