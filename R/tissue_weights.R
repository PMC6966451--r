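#' Variance-stabilizing transform for expression counts
#'
#' Applies `log2(count / size_factor + 1)` per tissue, with median-of-ratios
#' size factors: the reference profile is the per-gene geometric mean across
#' tissues (over genes expressed everywhere), and each tissue's size factor
#' is the median ratio of its counts to the reference. This flattens the
#' mean-variance relationship of counts while staying monotone, so
#' downstream correlations compare profile shapes rather than sequencing
#' depth.
#'
#' @param expr genes x tissues matrix of non-negative counts with rownames
#'   (gene ids) and colnames (tissue ids).
#' @return Transformed matrix of the same shape, with the size factors in
#'   attribute `size_factors`.
#' @export
transform_counts <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 tissues")
  if (any(expr < 0)) stop("negative counts")
  zero <- colSums(expr) == 0
  if (any(zero)) {
    stop("all-zero count column(s): ", paste(colnames(expr)[zero], collapse = ", "))
  }
  everywhere <- rowSums(expr > 0) == ncol(expr)
  if (!any(everywhere)) {
    sf <- rep(1, ncol(expr))
  } else {
    loggeo <- rowMeans(log(expr[everywhere, , drop = FALSE]))
    sf <- apply(expr[everywhere, , drop = FALSE], 2, function(cnt) {
      exp(stats::median(log(cnt) - loggeo))
    })
  }
  out <- log2(sweep(expr, 2, sf, "/") + 1)
  attr(out, "size_factors") <- stats::setNames(sf, colnames(expr))
  out
}

#' Select the most variable genes
#'
#' Ranks genes by the maximum absolute deviation from their median value
#' across tissues and keeps the top `n`. Ties are broken deterministically
#' by gene id.
#'
#' @param expr transformed genes x tissues matrix with rownames.
#' @param n number of genes to keep (default 2000).
#' @return Matrix restricted to the selected genes, ordered by decreasing
#'   deviation.
#' @export
select_variable_genes <- function(expr, n = 2000) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("g%d", seq_len(nrow(expr)))
  if (n > nrow(expr)) {
    warning(sprintf("requested %d genes but only %d available; using all", n, nrow(expr)))
    n <- nrow(expr)
  }
  med <- apply(expr, 1, stats::median)
  dev <- apply(abs(expr - med), 1, max)
  ord <- order(-dev, rownames(expr))
  expr[ord[seq_len(n)], , drop = FALSE]
}

#' Cluster tissues by expression correlation
#'
#' Hierarchical clustering (average linkage) of tissues with distance
#' 1 - Pearson correlation between expression profiles. Columns are sorted
#' by tissue id before clustering so that ties in merge height resolve
#' lexicographically by the smallest member label. Anti-correlated tissues
#' give distances in (1, 2], which are kept as-is.
#'
#' @param expr transformed (and typically variable-gene-restricted)
#'   genes x tissues matrix.
#' @return An `hclust` tree with tissue labels.
#' @export
build_dendrogram <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 tissues")
  if (is.null(colnames(expr))) stop("tissue ids (colnames) required")
  expr <- expr[, order(colnames(expr)), drop = FALSE]
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression profile (correlation undefined) for tissue(s): ",
         paste(colnames(expr)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(expr, method = "pearson"))
  stats::hclust(d, method = "average")
}

#' Export a tissue dendrogram in Newick format
#'
#' @param tree an `hclust` or `ape::phylo` tree.
#' @param path output file.
#' @export
write_dendrogram <- function(tree, path) {
  phy <- if (inherits(tree, "phylo")) tree else ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

# Root-to-tip edge attribution shared by all leaves below an edge.
.equal_splits_raw <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- max(phy$edge)
  # number of leaves below each node
  below <- integer(nn)
  below[seq_len(ntip)] <- 1L
  o <- rev(ape::postorder(phy))          # edges, root first
  for (i in rev(o)) {                    # child-first accumulation
    e <- phy$edge[i, ]
    below[e[1]] <- below[e[1]] + below[e[2]]
  }
  raw <- numeric(nn)
  for (i in o) {                         # root-first propagation
    e <- phy$edge[i, ]
    len <- if (is.null(phy$edge.length)) 1 else phy$edge.length[i]
    raw[e[2]] <- raw[e[1]] + len / below[e[2]]
  }
  stats::setNames(raw[seq_len(ntip)], phy$tip.label)
}

#' Per-tissue weights from a dendrogram (equal-splits attribution)
#'
#' Summarizes each tissue's contribution to the total expression divergence
#' represented by the tree. Each edge's length is divided equally among the
#' leaves below it; a leaf's raw score is the sum of its shares along the
#' root-to-leaf path, and weights are the raw scores normalized to sum to 1.
#' Redundant (closely related) tissues therefore share, rather than double,
#' the weight of their common history. The rule is isolated here so an
#' alternative attribution (e.g. a Brownian-motion-based one) can be swapped
#' in without touching consensus construction.
#'
#' @param tree an `hclust` tree (converted internally) or an `ape::phylo`.
#' @return Named numeric vector of weights summing to 1.
#' @export
leaf_weights <- function(tree) {
  phy <- if (inherits(tree, "phylo")) tree else ape::as.phylo(tree)
  if (length(phy$tip.label) == 1) {
    return(stats::setNames(1, phy$tip.label))
  }
  raw <- .equal_splits_raw(phy)
  if (sum(raw) == 0) {
    # degenerate star with zero branch lengths: uniform
    return(stats::setNames(rep(1 / length(raw), length(raw)), names(raw)))
  }
  raw / sum(raw)
}

#' Distribute tissue weights over TAD maps
#'
#' When several TAD maps come from the same tissue/cell line, each map
#' receives an equal share of that tissue's weight; the per-map weights are
#' then renormalized to sum to 1.
#'
#' @param weights named vector of tissue weights (from [leaf_weights()]).
#' @param maps list of `tad_map` objects whose `sample_id`s must all appear
#'   in `weights`.
#' @return Numeric vector of per-map weights (one per element of `maps`,
#'   named by sample_id), summing to 1.
#' @export
assign_map_weights <- function(weights, maps) {
  ids <- vapply(maps, attr, "", "sample_id")
  miss <- setdiff(unique(ids), names(weights))
  if (length(miss)) {
    stop("no tissue weight for TAD map(s): ", paste(miss, collapse = ", "))
  }
  share <- unname(weights[ids]) / as.vector(table(ids)[ids])
  w <- share / sum(share)
  stats::setNames(w, ids)
}

#' Write tissue or map weights as a two-column TSV
#'
#' @param weights named numeric vector.
#' @param path output file.
#' @export
write_weights <- function(weights, path) {
  utils::write.table(data.frame(id = names(weights), weight = unname(weights)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
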