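## Tree I/O, validation, pruning and posterior subsampling.
## Trees are ape "phylo" objects; posterior samples are "multiPhylo".

#' Read a tree file as a posterior sample
#'
#' Reads one or more dated phylogenies from a Newick or NEXUS file
#' (NEXUS `translate` tables are honoured) and returns them as a
#' `multiPhylo` posterior sample in file order.  A file holding a
#' single tree yields a sample of size one.
#'
#' @param path Path to the tree file.
#' @param format `"auto"` (default, guessed from the file's first
#'   non-blank characters), `"newick"` or `"nexus"`.
#' @return A `multiPhylo` object with attribute `source_label` set to
#'   the file name.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("(A:1.0,B:1.0):0.0;", tf)
#' trees <- read_trees(tf)
#' length(trees)
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && grepl("^#NEXUS", trimws(first[1]),
                                         ignore.case = TRUE))
      "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop("could not parse '", path, "' as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  if (is.null(trees)) stop("could not parse '", path, "' as ", format)
  trees <- as_posterior(trees)
  if (length(trees) == 0L) stop("no trees found in '", path, "'")
  attr(trees, "source_label") <- basename(path)
  trees
}

#' Write trees with full branch-length precision
#'
#' @param trees A `phylo` or `multiPhylo` object.
#' @param path Output file path (Newick, one tree per line).
#' @param digits Significant digits for branch lengths (default 10).
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path, digits = 10) {
  trees <- as_posterior(trees)
  ape::write.tree(trees, file = path, digits = digits)
  invisible(path)
}

## coerce phylo / list / multiPhylo to multiPhylo
as_posterior <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)  # multiPhylo of 1
  if (is.list(trees) && !inherits(trees, "multiPhylo")) {
    stopifnot(all(vapply(trees, inherits, TRUE, "phylo")))
    class(trees) <- "multiPhylo"
  }
  trees
}

#' Prune a tree to one tip per species
#'
#' Phylogenies often carry multiple subspecies or varieties per species;
#' diversification analyses at the species level require one tip each.
#' For every species represented by several tips, one tip is chosen
#' uniformly at random and the rest dropped; degree-2 nodes created by
#' pruning are collapsed with branch lengths summed, so root-to-tip
#' depths of retained tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param species_map Named character vector (or two-column data frame
#'   `tip_label,species`) mapping every tip label to its species.
#' @param seed Integer seed making the random choice reproducible.
#' @param rename If `TRUE` (default), retained tips are relabelled with
#'   their species names.
#' @return The pruned `phylo` object.
#' @examples
#' tr <- ape::read.tree(text = "((X_a:1,X_b:1):2,Y:3);")
#' map <- c(X_a = "X", X_b = "X", Y = "Y")
#' prune_to_species(tr, map, seed = 1)$tip.label
#' @export
prune_to_species <- function(tree, species_map, seed = NULL, rename = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(species_map)) {
    species_map <- setNames(as.character(species_map[[2]]),
                            as.character(species_map[[1]]))
  }
  orphans <- setdiff(tree$tip.label, names(species_map))
  if (length(orphans))
    stop("tips missing from species map: ", paste(orphans, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  sp <- species_map[tree$tip.label]
  keep <- vapply(split(tree$tip.label, sp), function(tips) {
    if (length(tips) == 1L) tips else tips[sample.int(length(tips), 1L)]
  }, character(1))
  drop <- setdiff(tree$tip.label, keep)
  out <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  if (rename) out$tip.label <- unname(sp[out$tip.label])
  out
}

#' Check a tree for ultrametricity and return its root age
#'
#' A dated tree is ultrametric: all root-to-tip path lengths are equal.
#' Output rounding makes exact equality unrealistic, so equality is
#' judged relative to tree depth.
#'
#' @param tree A `phylo` object with at least 2 tips.
#' @param rel_tol Relative tolerance: the tree passes iff
#'   `max(depth) - min(depth) <= rel_tol * max(depth)`.
#' @return A list with `ultrametric` (logical) and `root_age` (the
#'   maximum root-to-tip depth, in Myr).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) found")
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  list(ultrametric = (max(d) - min(d)) <= rel_tol * max(d),
       root_age = max(d))
}

## root-to-node path lengths for all nodes (preorder accumulation)
node_depths <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_all)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(ord$edge)))) {  # preorder: parents first
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + ord$edge.length[e]
  }
  depth
}

#' Subsample a posterior tree set evenly
#'
#' Returns `n` trees at evenly spaced indices spanning the sample (the
#' first tree is always included); deterministic, so repeated
#' application with the same `n` is the identity.
#'
#' @param trees A `multiPhylo` posterior sample.
#' @param n Number of trees to keep (`0 < n <= length(trees)`).
#' @return A `multiPhylo` of `n` trees.
#' @examples
#' # 10 trees, n = 5 -> trees 1, 3, 5, 7, 9
#' @export
subsample_evenly <- function(trees, n) {
  trees <- as_posterior(trees)
  N <- length(trees)
  if (n <= 0) stop("n must be positive")
  if (n > N) stop("n (", n, ") exceeds sample size (", N, ")")
  idx <- floor((seq_len(n) - 1) * N / n) + 1L
  out <- trees[idx]
  attr(out, "source_label") <- attr(trees, "source_label")
  out
}
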