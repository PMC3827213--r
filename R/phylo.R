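#' Poisson-corrected distance matrix from an alignment
#'
#' For each pair of rows, `p` is the fraction of mismatches over columns
#' where both rows have a residue; the corrected distance is
#' `d = -ln(1 - p)`. Saturated pairs (`p >= p_cap`) are assigned `d_max`.
#'
#' @param alignment An `shsp_alignment` (>= 2 rows).
#' @param p_cap Saturation threshold (default 0.95).
#' @param d_max Distance assigned to saturated pairs (default 10).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
poisson_distance <- function(alignment, p_cap = 0.95, d_max = 10) {
  stopifnot(inherits(alignment, "shsp_alignment"))
  rows <- alignment$rows
  n <- length(rows)
  if (n < 2L) stop("need at least 2 rows")
  charmat <- do.call(rbind, strsplit(rows, ""))
  resid <- !(charmat == "-" | charmat == ".")
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- resid[i, ] & resid[j, ]
      ns <- sum(shared)
      if (ns == 0L) {
        stop("rows ", names(rows)[i], " and ", names(rows)[j],
             " share no ungapped columns")
      }
      p <- sum(charmat[i, shared] != charmat[j, shared]) / ns
      d[i, j] <- d[j, i] <- if (p >= p_cap) d_max else -log(1 - p)
    }
  }
  d
}

#' Build a BioNJ tree from a distance matrix
#'
#' Variance-weighted neighbor joining (BioNJ, via ape). Negative branch
#' lengths arising from the NJ update are clamped to zero.
#'
#' @param dm Symmetric distance matrix with >= 3 taxa (dimnames = taxa) or a
#'   `dist` object.
#' @return An unrooted `phylo` tree (ape).
#' @export
bionj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm))
  if (nrow(dm) < 3L) stop("BioNJ needs at least 3 taxa")
  if (is.null(rownames(dm))) stop("distance matrix needs taxon names")
  if (any(!is.finite(dm))) stop("non-finite distances")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix not symmetric")
  if (any(diag(dm) != 0)) stop("nonzero diagonal")
  tr <- ape::bionj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Tip-index set below each node (keyed by node number), via postorder sweep.
tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    parent <- po[k, 1]
    child <- po[k, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  lapply(sets, function(s) sort(unique(s)))
}

#' Test whether a taxon set is monophyletic (unrooted convention)
#'
#' TRUE iff some edge bipartition of the tree separates exactly `taxa_set`
#' from all other leaves; by this convention the result is identical for a
#' set and its complement, and any single leaf is monophyletic.
#'
#' @param tree A `phylo` tree.
#' @param taxa_set Character vector of tip labels; must be a non-empty
#'   proper subset of the tree's tips.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa_set) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  unknown <- setdiff(taxa_set, tips)
  if (length(unknown) > 0L) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  if (length(taxa_set) == 0L) stop("empty taxon set")
  if (length(unique(taxa_set)) == length(tips)) {
    stop("taxon set must be a proper subset of the tips")
  }
  target <- sort(match(unique(taxa_set), tips))
  if (length(target) == 1L) return(TRUE)
  comp <- setdiff(seq_along(tips), target)
  below <- tips_below(tree)
  for (k in seq_len(nrow(tree$edge))) {
    s <- below[[tree$edge[k, 2]]]
    if (identical(s, target) || identical(s, comp)) return(TRUE)
  }
  FALSE
}

#' Read a newick tree file
#' @param path Path to a newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}

#' Write a tree as newick
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a PHYLIP-style square distance matrix
#' @param dm Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @export
write_phylip_dm <- function(dm, path) {
  stopifnot(is.matrix(dm), !is.null(rownames(dm)))
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i) {
               paste0(formatC(rownames(dm)[i], width = -10),
                      paste(sprintf("%.6f", dm[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
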