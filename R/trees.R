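#' Read a phylogeny from Newick or NEXUS
#'
#' Thin validated wrapper around [ape::read.tree()] / [ape::read.nexus()].
#' Branch lengths are taken as durations in million years (My) and are never
#' rescaled by this package; calibration is upstream. Trees without branch
#' lengths are rejected because every downstream rate computation needs
#' durations.
#'
#' @param path Path to a tree file.
#' @param format Either `"newick"` or `"nexus"`. Defaults to guessing from
#'   the file extension (`.nex`/`.nexus` or a `#NEXUS` header -> NEXUS).
#' @return An object of class `phylo` with branch lengths, validated by
#'   [validate_tree()].
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (ext %in% c("nex", "nexus", "trees") ||
                  startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  tree <- if (format == "nexus") {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L)
      stop("file contains ", length(tree), " trees; expected exactly one")
    tree <- tree[[1L]]
  }
  if (is.null(tree)) stop("failed to parse tree file: ", path)
  validate_tree(tree)
  tree
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a phylogeny
#'
#' Checks the invariants all analyses rely on: a single root, unique tip
#' labels, non-negative branch durations, and full connectivity.
#'
#' @param tree A `phylo` object.
#' @param require_binary Require a strictly bifurcating tree.
#' @return `tree`, invisibly. Errors describe the violated invariant.
#' @export
validate_tree <- function(tree, require_binary = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 1L) stop("tree has no tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; durations in My are required")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  # exactly one root: every node except one appears as a child exactly once
  child <- tree$edge[, 2L]
  if (anyDuplicated(child)) stop("a node has more than one parent")
  all_nodes <- seq_len(n + tree$Nnode)
  roots <- setdiff(all_nodes, child)
  if (length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots))
  if (require_binary &&
      !(ape::is.rooted(tree) && ape::is.binary(tree)))
    stop("tree contains polytomies; call resolve_polytomies() first")
  invisible(tree)
}

#' Randomly resolve polytomies
#'
#' Multifurcations (common in composite trees where uncertain species are
#' attached as polytomies) are resolved into random bifurcations with
#' zero-length inserted branches, so patristic distances and root-to-tip
#' depths are unchanged. The resolution is reproducible under `seed`.
#'
#' @param tree A `phylo` object.
#' @param seed Integer seed fixing the random resolution.
#' @return A strictly binary `phylo` with identical tip set and tip depths.
#' @export
resolve_polytomies <- function(tree, seed) {
  validate_tree(tree)
  if (ape::is.binary(tree)) return(tree)
  out <- with_seed(seed, ape::multi2di(tree, random = TRUE))
  # multi2di assigns NA or 0 length to inserted edges depending on version
  out$edge.length[is.na(out$edge.length)] <- 0
  out
}

#' Enumerate ancestor-descendant branches
#'
#' Returns every parent -> child edge of the tree exactly once, terminal
#' branches included: the unit of ancestor-descendant comparison used by
#' [branch_changes()].
#'
#' @param tree A `phylo` object.
#' @return A data frame with columns `parent`, `child` (ape node ids, tips
#'   `1..n`), `child_label` (species name for terminal branches, `NA`
#'   otherwise), `duration` (My), and `is_terminal`.
#' @export
branches <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  child <- tree$edge[, 2L]
  data.frame(
    parent = tree$edge[, 1L],
    child = child,
    child_label = ifelse(child <= n, tree$tip.label[pmin(child, n)],
                         NA_character_),
    duration = tree$edge.length,
    is_terminal = child <= n,
    stringsAsFactors = FALSE
  )
}

#' Node depths from the root
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of root-to-node path lengths (My), indexed by ape
#'   node id.
#' @keywords internal
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  depth <- numeric(n + tree$Nnode)
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "postorder")
  e <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  len <- rev(ord$edge.length)
  for (i in seq_len(nrow(e))) depth[e[i, 2L]] <- depth[e[i, 1L]] + len[i]
  depth
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so simulation helpers never
#' perturb the global random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Match a named vector of tip values against a tree's tips; errors name the
# missing species. Returns values ordered 1..n by tip id.
match_tip_values <- function(tree, tip_values, what = "tip value") {
  if (is.null(names(tip_values)))
    stop("tip values must be a named vector (names = species)")
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss))
    stop("missing ", what, " for: ", paste(miss, collapse = ", "))
  x <- as.numeric(tip_values[tree$tip.label])
  if (anyNA(x))
    stop("non-numeric or NA ", what, " for: ",
         paste(tree$tip.label[is.na(x)], collapse = ", "))
  names(x) <- tree$tip.label
  x
}
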