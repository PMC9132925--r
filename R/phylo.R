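#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the properties the
#' downstream correlation matrix needs: a single rooted tree, unique tip
#' labels and branch lengths on every edge. Ultrametricity is not required
#' but is checked and reported (mega-tree extracts are typically near- but
#' not exactly ultrametric).
#'
#' @param path path to a Newick file.
#' @param species optional character vector of modeled species; any species
#'   absent from the tree triggers a warning listing them (they can then be
#'   grafted with [graft_at_genus()]).
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path, species = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("read_newick: empty file: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("read_newick: cannot parse ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("read_newick: no tree parsed from ", path, call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  check_phylogeny(tree)
  if (!is.null(species)) {
    absent <- setdiff(species, tree$tip.label)
    if (length(absent))
      warning("species absent from tree: ", paste(absent, collapse = ", "),
              call. = FALSE)
  }
  if (!ape::is.ultrametric(tree, option = 2))
    message("read_newick: tree is not ultrametric; correlations use ",
            "geometric-mean depth normalization")
  tree
}

check_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths", call. = FALSE)
  invisible(tree)
}

genus_of <- function(species_id) sub("[_ ].*$", "", species_id)

#' Graft a species onto its genus in a phylogeny
#'
#' Attaches a tip for a species missing from the tree to its congeners,
#' emulating genus-level placement against a mega-tree. With two or more
#' congeners the new tip is bound at their most recent common ancestor; with
#' a single congener the congener's subtending branch is split at its
#' midpoint and the tip bound there. In both cases the pendant branch length
#' is chosen so that the new tip's root-to-tip depth equals the mean depth
#' of its congeners (for an ultrametric tree this keeps the tree
#' ultrametric).
#'
#' @param tree an [ape::phylo] object.
#' @param species_id label of the new tip (binomial, genus as the token
#'   before the first underscore or space).
#' @param genus_name genus to graft into; default is parsed from
#'   `species_id`.
#' @return the augmented tree (one more tip).
#' @export
graft_at_genus <- function(tree, species_id, genus_name = genus_of(species_id)) {
  check_phylogeny(tree)
  if (species_id %in% tree$tip.label)
    stop("graft_at_genus: ", species_id, " already in tree", call. = FALSE)
  cong <- which(genus_of(tree$tip.label) == genus_name)
  if (length(cong) == 0L)
    stop("graft_at_genus: no congener of genus '", genus_name,
         "' in tree; place ", species_id, " manually", call. = FALSE)
  depth <- ape::node.depth.edgelength(tree)
  if (length(cong) == 1L) {
    # split the single congener's subtending branch at its midpoint
    edge_i <- which(tree$edge[, 2] == cong)
    L <- tree$edge.length[edge_i]
    pendant <- L / 2
    where <- cong
    position <- L / 2
  } else {
    mrca <- ape::getMRCA(tree, cong)
    pendant <- mean(depth[cong]) - depth[mrca]
    if (pendant < 0) {
      warning("graft_at_genus: mean congener depth above MRCA; pendant ",
              "clamped to 0", call. = FALSE)
      pendant <- 0
    }
    where <- mrca
    position <- 0
  }
  tip <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                        tip.label = species_id,
                        edge.length = pendant,
                        Nnode = 1L),
                   class = "phylo")
  out <- ape::bind.tree(tree, tip, where = where, position = position)
  check_phylogeny(out)
  out
}

#' Phylogenetic correlation matrix from a tree
#'
#' Builds the unit-diagonal species correlation matrix implied by Brownian
#' trait evolution on the tree: entry (i, j) is the root-to-MRCA shared path
#' length of tips i and j divided by the geometric mean of their root-to-tip
#' depths. For an ultrametric tree this equals the Brownian
#' variance-covariance matrix divided by tree depth; non-ultrametric input
#' is normalized per pair rather than rejected.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return symmetric matrix with unit diagonal, dimnames = tip labels;
#'   positive semi-definite up to numerical jitter.
#' @export
phylo_correlation <- function(tree) {
  check_phylogeny(tree)
  V <- ape::vcv(tree)
  d <- diag(V)
  if (any(d <= 0))
    stop("phylo_correlation: tip(s) at zero depth: ",
         paste(rownames(V)[d <= 0], collapse = ", "), call. = FALSE)
  C <- V / sqrt(outer(d, d))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("phylo_correlation: matrix not PSD (min eigenvalue ", ev, ")",
         call. = FALSE)
  C
}

#' Write a correlation matrix as delimited text
#'
#' @param C square matrix with dimnames.
#' @param path output path.
#' @export
write_correlation <- function(C, path) {
  df <- data.frame(species_id = rownames(C), as.data.frame(C),
                   check.names = FALSE)
  write_tsv(df, path)
}
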