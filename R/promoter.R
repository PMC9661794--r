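# Promoter cis-element categorization: a closed element-name -> category
# mapping (shipped as an editable table under inst/extdata), category
# percentages of all element occurrences, and per-function breakdowns.

CIS_CATEGORIES <- c("hormone-related", "stress-responsive", "plant growth")

#' Load a cis-element category map
#'
#' The map is a two-plus-column tab-separated table: \code{element_name},
#' \code{category} (one of hormone-related, stress-responsive, plant
#' growth) and optionally \code{function_label}. The packaged default
#' covers the common PlantCARE vocabulary (TCA-element, ABRE, LTR, ...).
#'
#' @param path path to a map file; default the packaged map.
#' @return data.frame with columns \code{element_name}, \code{category},
#'   \code{function_label}.
#' @export
loadCisCategoryMap <- function(path = system.file("extdata",
                                                  "cis_category_map.tsv",
                                                  package = "nbslineage")) {
  map <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("element_name", "category") %in% names(map)))
    stop("category map needs columns element_name, category")
  bad <- setdiff(unique(map$category), CIS_CATEGORIES)
  if (length(bad) > 0)
    stop("unknown categories in map: ", paste(bad, collapse = ", "))
  if (!"function_label" %in% names(map)) map$function_label <- NA_character_
  map
}

# round half away from zero to `digits` decimals (printed-percentage style;
# base round() is banker's rounding)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total, rounded half-up to one decimal
#'
#' @param count numerator count(s).
#' @param total denominator.
#' @return numeric percentage(s) on the 0-100 scale, one decimal.
#' @export
percentOf <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  roundHalfUp(100 * count / total, 1)
}

#' Categorize promoter cis-elements into the three functional categories
#'
#' Each element occurrence is assigned its category from the closed map;
#' unmapped element names are an error (listed). Percentages are of the
#' total number of occurrences, rounded half-up to one decimal.
#'
#' @param elements data.frame of occurrences (as from
#'   [parseCisElements()]).
#' @param map category map (as from [loadCisCategoryMap()]).
#' @return data.frame with one row per category: \code{category},
#'   \code{count}, \code{percent}; attribute \code{total} carries the
#'   denominator.
#' @export
categorizeElements <- function(elements, map = loadCisCategoryMap()) {
  if (nrow(elements) == 0)
    stop("no cis-element occurrences to categorize (total = 0)")
  cat_of <- stats::setNames(map$category, map$element_name)
  cats <- unname(cat_of[elements$element_name])
  if (anyNA(cats))
    stop("unmapped cis-element name(s): ",
         paste(sort(unique(elements$element_name[is.na(cats)])),
               collapse = ", "))
  total <- length(cats)
  counts <- vapply(CIS_CATEGORIES, function(k) sum(cats == k), integer(1))
  out <- data.frame(category = CIS_CATEGORIES, count = unname(counts),
                    percent = percentOf(unname(counts), total),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Genes carrying at least one element of a given name
#'
#' @param elements data.frame of occurrences.
#' @param element_name element name to look up (e.g. "TCA-element").
#' @return sorted unique character vector of gene ids.
#' @export
genesWithElement <- function(elements, element_name) {
  sort(unique(elements$gene_id[elements$element_name == element_name]))
}

#' Per-function breakdown of one category's elements
#'
#' Counts occurrences by function label within a category; percentages are
#' of the grand total of all occurrences (all categories), matching how
#' stress-responsive sub-shares are usually reported.
#'
#' @param elements data.frame of occurrences.
#' @param map category map.
#' @param category category to break down (default stress-responsive).
#' @return data.frame with \code{function_label}, \code{count},
#'   \code{percent} (of grand total).
#' @export
subcategoryBreakdown <- function(elements, map = loadCisCategoryMap(),
                                 category = "stress-responsive") {
  if (!category %in% CIS_CATEGORIES) stop("unknown category: ", category)
  cat_of <- stats::setNames(map$category, map$element_name)
  fun_of <- stats::setNames(map$function_label, map$element_name)
  cats <- unname(cat_of[elements$element_name])
  if (anyNA(cats))
    stop("unmapped cis-element name(s): ",
         paste(sort(unique(elements$element_name[is.na(cats)])),
               collapse = ", "))
  grand <- length(cats)
  sel <- cats == category
  fl <- elements$function_label[sel]
  miss <- is.na(fl) | !nzchar(fl)
  fl[miss] <- unname(fun_of[elements$element_name[sel]])[miss]
  cnt <- table(fl)
  data.frame(function_label = names(cnt), count = as.integer(cnt),
             percent = percentOf(as.integer(cnt), grand),
             stringsAsFactors = FALSE, row.names = NULL)
}
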