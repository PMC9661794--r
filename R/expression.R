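# Desk-scale expression workflow: FPKM from a count matrix, two-condition
# differential-expression calls (Welch test on log2(FPKM+1), BH adjustment,
# fold change > 1.5 and adjusted p < 0.05), and unsigned co-expression
# modules via topological overlap with a module-trait correlation.

#' Bundle counts, gene lengths and a design into a SummarizedExperiment
#'
#' @param counts integer matrix, genes x samples.
#' @param gene_lengths numeric vector of transcript lengths in bases,
#'   aligned with (or named by) the rows of \code{counts}.
#' @param condition character/factor of per-sample condition labels,
#'   typically \code{treated}/\code{control}.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assays
#'   \code{counts} and \code{fpkm}, rowData \code{gene_length} and colData
#'   \code{condition}.
#' @export
makeExpressionSet <- function(counts, gene_lengths, condition) {
  if (!is.null(names(gene_lengths)))
    gene_lengths <- gene_lengths[rownames(counts)]
  stopifnot(length(gene_lengths) == nrow(counts),
            length(condition) == ncol(counts))
  fpkm <- computeFpkm(counts, gene_lengths)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, fpkm = fpkm),
    rowData = S4Vectors::DataFrame(gene_length = unname(gene_lengths)),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   row.names = colnames(counts)))
}

#' FPKM from raw counts
#'
#' \code{fpkm = counts * 1e9 / (gene_length * library_size)} with the
#' library size defaulting to the column sum of counts.
#'
#' @param counts integer matrix, genes x samples.
#' @param gene_lengths numeric vector of lengths in bases (> 0).
#' @param library_sizes per-sample totals; defaults to \code{colSums}.
#' @return numeric matrix of FPKM values.
#' @export
computeFpkm <- function(counts, gene_lengths,
                        library_sizes = colSums(counts)) {
  stopifnot(all(gene_lengths > 0))
  if (any(library_sizes <= 0)) stop("zero library size")
  t(t(counts / (gene_lengths / 1e3)) / (library_sizes / 1e6))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating front end to the step-up false-discovery-rate procedure.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values (same order as input, capped at 1).
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between two conditions
#'
#' Per gene: Welch's unequal-variance t-test on log2(FPKM + 1), BH
#' adjustment across genes, and a fold change of mean treated FPKM over
#' mean control FPKM (each with a 0.01 pseudo-count). A gene is \code{up}
#' when fold change exceeds 1.5 strictly and adjusted p < 0.05; \code{down}
#' when fold change is below 1/1.5 with adjusted p < 0.05; otherwise
#' \code{ns}.
#'
#' @param se SummarizedExperiment from [makeExpressionSet()], or an FPKM
#'   matrix.
#' @param condition per-sample labels (required when \code{se} is a bare
#'   matrix); exactly two levels, each with >= 2 replicates.
#' @param treated,control the two condition labels.
#' @param fc_min fold-change threshold (default 1.5, strict).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame with \code{gene_id}, \code{fold_change},
#'   \code{log2_fc}, \code{p_raw}, \code{p_adj}, \code{status}.
#' @export
callDegs <- function(se, condition = NULL, treated = "treated",
                     control = "control", fc_min = 1.5, alpha = 0.05) {
  if (methods::is(se, "SummarizedExperiment")) {
    fpkm <- SummarizedExperiment::assay(se, "fpkm")
    condition <- SummarizedExperiment::colData(se)$condition
  } else fpkm <- as.matrix(se)
  ti <- which(condition == treated); ci <- which(condition == control)
  if (length(ti) < 2 || length(ci) < 2)
    stop("each condition needs at least 2 replicates")
  lx <- log2(fpkm + 1)
  p_raw <- vapply(seq_len(nrow(lx)), function(i) {
    a <- lx[i, ti]; b <- lx[i, ci]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }, numeric(1))
  p_adj <- bhAdjust(p_raw)
  fc <- (rowMeans(fpkm[, ti, drop = FALSE]) + 0.01) /
    (rowMeans(fpkm[, ci, drop = FALSE]) + 0.01)
  status <- rep("ns", nrow(fpkm))
  status[fc > fc_min & p_adj < alpha] <- "up"
  status[fc < 1 / fc_min & p_adj < alpha] <- "down"
  data.frame(gene_id = rownames(fpkm), fold_change = unname(fc),
             log2_fc = unname(log2(fc)), p_raw = p_raw, p_adj = p_adj,
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Unsigned soft-threshold adjacency
#'
#' \code{a_ij = |cor(x_i, x_j)|^beta} with a zero diagonal; genes are rows.
#'
#' @param fpkm expression matrix, genes x samples (>= 3 samples).
#' @param beta soft-thresholding power (default 6).
#' @return symmetric adjacency matrix with zero diagonal.
#' @export
softAdjacency <- function(fpkm, beta = 6) {
  stopifnot(beta >= 1, ncol(fpkm) >= 3)
  sds <- apply(fpkm, 1, stats::sd)
  if (any(sds == 0))
    stop("constant expression rows: ",
         paste(rownames(fpkm)[sds == 0], collapse = ", "))
  a <- abs(stats::cor(t(fpkm)))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' with unit diagonal, where \code{k_i} is node connectivity. Measures how
#' much two genes share network neighbours beyond their direct link.
#'
#' @param adjacency symmetric matrix, zero diagonal, entries in [0, 1].
#' @return symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1)) stop("entries must lie in [0,1]")
  if (any(diag(adjacency) != 0)) stop("diagonal must be zero")
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  den <- outer(k, k, pmin) + 1 - adjacency
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2  # symmetrize away float noise
  tom
}

# classic module colour palette, by descending module size
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan")

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM
#' with a static cut at \code{cut_height}; clusters of at least
#' \code{min_module_size} genes become modules named by colour in
#' decreasing size order, everything else is \code{grey}.
#'
#' @param tom TOM matrix (as from [tomSimilarity()]).
#' @param min_module_size smallest non-grey module (default 30).
#' @param cut_height static tree-cut height on 1 - TOM (default 0.8).
#' @return character vector of module labels, one per gene (named by
#'   rownames of \code{tom} when present).
#' @export
detectModules <- function(tom, min_module_size = 30, cut_height = 0.8) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- sort(table(cl), decreasing = TRUE)
  labels <- rep("grey", length(cl))
  col_i <- 1L
  for (cid in names(sizes)) {
    if (sizes[[cid]] < min_module_size) next
    lab <- if (col_i <= length(MODULE_COLORS)) MODULE_COLORS[col_i] else
      paste0("module", col_i)
    labels[cl == as.integer(cid)] <- lab
    col_i <- col_i + 1L
  }
  names(labels) <- rownames(tom)
  labels
}

#' Module eigengene
#'
#' First principal component of the row-standardized member expression
#' matrix, returned unit-norm and sign-oriented so that its correlation
#' with the members' mean standardized profile is positive.
#'
#' @param fpkm expression matrix, genes x samples.
#' @param members gene ids (or row indices) of one module.
#' @return numeric per-sample vector of unit norm.
#' @export
moduleEigengene <- function(fpkm, members) {
  x <- fpkm[members, , drop = FALSE]
  if (nrow(x) == 0) stop("empty module")
  xs <- t(scale(t(x)))
  xs[is.nan(xs)] <- 0
  sv <- svd(xs, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  ref <- colMeans(xs)
  if (sum(eg * ref) < 0) eg <- -eg
  eg / sqrt(sum(eg^2))
}

#' Module-trait correlation
#'
#' Pearson correlation (with exact two-sided p) between a module eigengene
#' and a per-sample numeric trait coding, e.g. treated = 1, control = 0.
#'
#' @param eigengene per-sample vector from [moduleEigengene()].
#' @param trait_indicator numeric per-sample trait coding.
#' @return list with \code{r} and \code{p}.
#' @export
moduleTraitCorrelation <- function(eigengene, trait_indicator) {
  pearsonR(eigengene, trait_indicator)
}

#' Full module workflow: adjacency, TOM, modules, eigengenes, trait table
#'
#' @param fpkm expression matrix, genes x samples.
#' @param trait_indicator numeric per-sample trait coding.
#' @param beta soft power (default 6).
#' @param min_module_size smallest module (default 30).
#' @param cut_height static cut height (default 0.8).
#' @return list with \code{labels}, \code{eigengenes} (sample x module),
#'   \code{trait} (data.frame module, r, p sorted by decreasing r).
#' @export
coexpressionModules <- function(fpkm, trait_indicator, beta = 6,
                                min_module_size = 30, cut_height = 0.8) {
  a <- softAdjacency(fpkm, beta)
  tom <- tomSimilarity(a)
  labels <- detectModules(tom, min_module_size, cut_height)
  mods <- setdiff(unique(labels), "grey")
  egs <- vapply(mods, function(m)
    moduleEigengene(fpkm, which(labels == m)), numeric(ncol(fpkm)))
  trait <- do.call(rbind, lapply(mods, function(m) {
    ct <- moduleTraitCorrelation(egs[, m], trait_indicator)
    data.frame(module = m, r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  }))
  if (is.null(trait))
    trait <- data.frame(module = character(), r = numeric(), p = numeric())
  trait <- trait[order(-trait$r), , drop = FALSE]
  rownames(trait) <- NULL
  list(labels = labels, eigengenes = egs, trait = trait)
}
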