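#' Patient sample tree
#'
#' A rooted binary phylogeny of tumour samples from one patient. The object
#' stores the sample subtree (rooted at the MRCA of the samples, branch
#' lengths in years) together with the branch from the last unaltered common
#' ancestor (LUCA) to the MRCA. The LUCA carries the normal diploid state
#' and is connected by a zero-length branch to a normal tip; that tip is
#' implicit here and materialized only on export.
#'
#' @param tree An \code{ape::phylo} object: rooted, binary, branch lengths
#'   in years, tips labelled by sample id.
#' @param luca_len Length in years of the LUCA-to-MRCA branch (>= 0).
#' @param tip_times Named numeric vector of sampling-time offsets in years
#'   from the first sample (minimum 0). \code{NULL} means all samples taken
#'   at the same time.
#' @param A0 Patient age in years at the first sampling time (\code{NA} when
#'   unknown; required for node ages).
#' @return An object of class \code{cnp_tree}.
#' @export
cnp_tree <- function(tree, luca_len, tip_times = NULL, A0 = NA_real_) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("`tree` must have branch lengths (in years)", call. = FALSE)
  }
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    stop("`tree` must be a rooted binary tree", call. = FALSE)
  }
  if (!is.finite(luca_len) || luca_len < 0) {
    stop("`luca_len` must be non-negative", call. = FALSE)
  }
  if (!is.null(tip_times)) {
    missing <- setdiff(tree$tip.label, names(tip_times))
    if (length(missing) > 0) {
      stop("tip_times missing for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tip_times <- tip_times[tree$tip.label]
    if (any(tip_times < 0) || min(tip_times) > 1e-9) {
      stop("tip_times must be >= 0 with at least one sample at 0",
           call. = FALSE)
    }
  }
  structure(list(tree = tree, luca_len = luca_len, tip_times = tip_times,
                 A0 = A0),
            class = "cnp_tree")
}

#' @export
print.cnp_tree <- function(x, ...) {
  n <- length(x$tree$tip.label)
  cat("Patient sample tree with", n, "samples\n")
  cat("  LUCA -> MRCA branch:", format(x$luca_len, digits = 4), "years\n")
  if (!is.null(x$tip_times)) {
    cat("  sampling offsets (years):",
        paste(format(x$tip_times, digits = 3), collapse = ", "), "\n")
  }
  if (!is.na(x$A0)) cat("  patient age at first sample:", x$A0, "years\n")
  invisible(x)
}

# depth (years) of every node from the MRCA root of the sample subtree
.node_depths <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  depth <- numeric(n_node)
  root <- n_tip + 1L
  # edges in preorder: reorder guarantees parents before children
  eo <- ape::reorder.phylo(phy, "postorder")
  edges <- eo$edge[rev(seq_len(nrow(eo$edge))), , drop = FALSE]
  lens <- eo$edge.length[rev(seq_len(nrow(eo$edge)))]
  for (k in seq_len(nrow(edges))) {
    depth[edges[k, 2L]] <- depth[edges[k, 1L]] + lens[k]
  }
  depth
}

#' Node ages in years since patient birth
#'
#' Ages increase from 0 at birth. Requires \code{A0} (patient age at the
#' first sample). Tip ages equal \code{A0} plus the sampling offsets; ages of
#' internal nodes follow from the branch lengths.
#'
#' @param x A \code{cnp_tree} with non-missing \code{A0}.
#' @return Numeric vector of ages indexed as in the underlying \code{phylo}
#'   (tips first, then internal nodes), with the LUCA age as attribute
#'   \code{"luca_age"}.
#' @export
node_ages <- function(x) {
  stopifnot(inherits(x, "cnp_tree"))
  if (is.na(x$A0)) stop("patient age `A0` is required for node ages",
                        call. = FALSE)
  phy <- x$tree
  n_tip <- length(phy$tip.label)
  depth <- .node_depths(phy)
  offs <- if (is.null(x$tip_times)) rep(0, n_tip) else x$tip_times
  # MRCA age implied by each tip; they must agree
  mrca_age <- x$A0 + offs - depth[seq_len(n_tip)]
  if (diff(range(mrca_age)) > 1e-6) {
    stop("branch lengths inconsistent with sampling times", call. = FALSE)
  }
  ages <- mean(mrca_age) + depth
  attr(ages, "luca_age") <- mean(mrca_age) - x$luca_len
  ages
}

#' Export the full tree including the normal tip
#'
#' @param x A \code{cnp_tree}.
#' @param normal_label Label for the normal tip.
#' @return An \code{ape::phylo} rooted at the LUCA, with the normal tip
#'   attached by a zero-length branch.
#' @export
full_phylo <- function(x, normal_label = "normal") {
  stopifnot(inherits(x, "cnp_tree"))
  sub <- ape::write.tree(x$tree)
  sub <- sub(";$", "", sub)
  txt <- sprintf("(%s:%.10g,%s:0);", sub, x$luca_len, normal_label)
  ape::read.tree(text = txt)
}

#' Write a sample tree as Newick
#'
#' The tree is written in its full form: LUCA root, normal tip on a
#' zero-length branch, branch lengths in years. When the patient age is
#' known, internal node labels carry the node ages in years since birth.
#'
#' @param x A \code{cnp_tree}.
#' @param file Optional path; when \code{NULL} the Newick string is returned.
#' @param normal_label Label for the normal tip.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(x, file = NULL, normal_label = "normal") {
  if (!is.na(x$A0)) {
    ages <- node_ages(x)
    n_tip <- length(x$tree$tip.label)
    sub <- x$tree
    sub$node.label <- sprintf("%.4f", ages[(n_tip + 1L):length(ages)])
    subtxt <- sub(";$", "", ape::write.tree(sub))
    txt <- sprintf("(%s:%.10g,%s:0)%.4f;", subtxt, x$luca_len,
                   normal_label, attr(ages, "luca_age"))
  } else {
    txt <- ape::write.tree(full_phylo(x, normal_label))
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a sample tree from Newick
#'
#' Expects the full form produced by \code{\link{write_newick}}: a rooted
#' binary tree whose root has a normal tip child on a (near) zero-length
#' branch and the sample subtree on the other side.
#'
#' @param text Newick string, or \code{NULL} when \code{file} is given.
#' @param file Optional path to a Newick file.
#' @param tip_times,A0 Optional timing metadata attached to the result.
#' @param normal_label Label of the normal tip.
#' @return A \code{cnp_tree}.
#' @export
read_newick <- function(text = NULL, file = NULL, tip_times = NULL,
                        A0 = NA_real_, normal_label = "normal") {
  phy <- if (is.null(text)) ape::read.tree(file)
         else ape::read.tree(text = text)
  if (!(normal_label %in% phy$tip.label)) {
    stop("no tip labelled '", normal_label, "' in the Newick tree",
         call. = FALSE)
  }
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  normal_tip <- match(normal_label, phy$tip.label)
  root_children <- phy$edge[phy$edge[, 1L] == root, 2L]
  if (!(normal_tip %in% root_children)) {
    stop("normal tip must attach directly to the root (LUCA)", call. = FALSE)
  }
  mrca_node <- setdiff(root_children, normal_tip)
  luca_len <- phy$edge.length[phy$edge[, 1L] == root &
                                phy$edge[, 2L] == mrca_node]
  if (mrca_node <= n_tip) {
    stop("sample side of the tree must contain at least 2 samples",
         call. = FALSE)
  }
  sub <- ape::extract.clade(phy, mrca_node)
  cnp_tree(sub, luca_len = luca_len, tip_times = tip_times, A0 = A0)
}

## ---- lightweight rooted-topology representation -------------------------
## A topology is a tip label (character) or a list of two subtopologies.
## Used for exhaustive enumeration and NNI; converted to phylo on demand.

.topo_newick <- function(tp) {
  if (is.character(tp)) return(tp)
  paste0("(", .topo_newick(tp[[1]]), ",", .topo_newick(tp[[2]]), ")")
}

.topo_phylo <- function(tp) {
  ape::read.tree(text = paste0(.topo_newick(tp), ";"))
}

.topo_from_phylo <- function(phy) {
  n_tip <- length(phy$tip.label)
  rec <- function(node) {
    if (node <= n_tip) return(phy$tip.label[node])
    ch <- phy$edge[phy$edge[, 1L] == node, 2L]
    list(rec(ch[1L]), rec(ch[2L]))
  }
  rec(n_tip + 1L)
}

# canonical key invariant to child order; equal keys <=> same rooted topology
.topo_key <- function(tp) {
  if (is.character(tp)) return(tp)
  keys <- sort(c(.topo_key(tp[[1]]), .topo_key(tp[[2]])))
  paste0("(", keys[1L], ",", keys[2L], ")")
}

#' Enumerate all rooted binary topologies on a set of samples
#'
#' There are \eqn{(2n-3)!!} labelled rooted binary topologies on \eqn{n}
#' tips; enumeration is practical for up to about seven samples.
#'
#' @param labels Character vector of sample labels (or a single integer n,
#'   expanded to \code{S1..Sn}).
#' @param cap Refuse enumeration beyond this many samples unless
#'   \code{override = TRUE}.
#' @param override Allow enumeration past the cap.
#' @return List of \code{ape::phylo} topologies (no branch lengths).
#' @export
enumerate_topologies <- function(labels, cap = 7L, override = FALSE) {
  if (is.numeric(labels) && length(labels) == 1L) {
    labels <- paste0("S", seq_len(labels))
  }
  n <- length(labels)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (n > cap && !override) {
    stop("enumeration over ", n, " samples exceeds the cap (", cap,
         "); use the heuristic search or override", call. = FALSE)
  }
  topos <- list(list(labels[1L], labels[2L]))
  if (n >= 3L) {
    for (k in 3:n) {
      tip <- labels[k]
      out <- vector("list", length(topos) * (2L * k - 3L))
      pos <- 0L
      for (tp in topos) {
        for (variant in .attach_tip_everywhere(tp, tip)) {
          pos <- pos + 1L
          out[[pos]] <- variant
        }
      }
      topos <- out
    }
  }
  lapply(topos, .topo_phylo)
}

# all ways to attach `tip` on an edge of tp, or above its root
.attach_tip_everywhere <- function(tp, tip) {
  res <- list(list(tp, tip))  # above the root
  if (is.character(tp)) return(res)
  for (side in 1:2) {
    other <- tp[[3L - side]]
    for (sub in .attach_tip_everywhere(tp[[side]], tip)) {
      grown <- if (side == 1L) list(sub, other) else list(other, sub)
      res <- c(res, list(grown))
    }
  }
  res
}

#' Nearest-neighbour-interchange rearrangements of a rooted topology
#'
#' Every internal edge of the sample subtree (an edge whose child is an
#' internal node) yields two rearrangements that swap the sibling subtree
#' with one child of that node. The LUCA root and the normal tip do not take
#' part in rearrangement.
#'
#' @param phy An \code{ape::phylo} rooted binary sample topology.
#' @return List of \code{phylo} neighbours (branch lengths dropped).
#' @export
nni_neighbors <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  tp <- .topo_from_phylo(phy)
  out <- list()
  rec <- function(node, rebuild) {
    if (is.character(node)) return()
    a <- node[[1]]; b <- node[[2]]
    for (side in 1:2) {
      child <- node[[3L - side]]
      sib <- node[[side]]
      if (!is.character(child)) {
        # swap sib with each grandchild inside `child`
        out[[length(out) + 1L]] <<-
          rebuild(.swap_build(side, child, sib, 1L))
        out[[length(out) + 1L]] <<-
          rebuild(.swap_build(side, child, sib, 2L))
      }
    }
    rec(a, function(x) rebuild(list(x, b)))
    rec(b, function(x) rebuild(list(a, x)))
  }
  rec(tp, identity)
  lapply(out, .topo_phylo)
}

.swap_build <- function(side, child, sib, which_gc) {
  gc_keep <- child[[3L - which_gc]]
  gc_move <- child[[which_gc]]
  new_child <- list(sib, gc_keep)
  if (side == 1L) list(gc_move, new_child) else list(new_child, gc_move)
}

# sorted-label clade strings for internal edges (root clade excluded)
.clade_keys <- function(phy) {
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  internal <- sort(setdiff(unique(phy$edge[, 1L]), root))
  if (length(internal) == 0L) return(character(0))
  vapply(internal, function(node) {
    tips <- ape::extract.clade(phy, node)$tip.label
    paste(sort(tips), collapse = "|")
  }, character(1))
}

#' Test whether two rooted topologies are identical
#'
#' @param t1,t2 \code{phylo} or \code{cnp_tree} objects over the same tips.
#' @return Logical.
#' @export
same_topology <- function(t1, t2) {
  p1 <- if (inherits(t1, "cnp_tree")) t1$tree else t1
  p2 <- if (inherits(t2, "cnp_tree")) t2$tree else t2
  identical(.topo_key(.topo_from_phylo(p1)), .topo_key(.topo_from_phylo(p2)))
}
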