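# Stable networks: identifiable pairs, irreducibility, and the stability
# decision via three independent routes (direct fold-of-unfold, the
# compressed+irreducible characterisation, and the guide-tree criterion).

#' Identifiable pairs of tree vertices
#'
#' Two distinct (non-root) tree vertices `v`, `w` of a network are
#' identifiable when some root path ending at `v` and some root path ending
#' at `w` carry isomorphic subtrees of the unfolding. Computed by unfolding
#' and comparing canonical forms of the suppressed subtrees below each path
#' vertex.
#'
#' @param n A `phydag` phylogenetic network.
#' @param cap Passed to [unfold_star()].
#' @return A two-column character matrix, one identifiable pair per row
#'   (lexicographically ordered and deduplicated; zero rows when none).
#' @export
identifiable_pairs <- function(n, cap = 1e5) {
  ures <- unfold_star(n, cap)
  identifiable_pairs_from(n, ures)
}

identifiable_pairs_from <- function(n, ures) {
  adj <- graph_adj(n)
  tree_v <- setdiff(
    n$vertices[!(adj$indeg >= 2L & adj$outdeg == 1L)], n$root)
  codes <- canonical_codes(ures$u)
  endv <- ures$fstar$vmap[ures$u$vertices]          # path vertex -> end vertex
  sel <- names(endv)[endv %in% tree_v]
  out <- matrix(character(0), ncol = 2L)
  if (length(sel)) {
    by_code <- split(unname(endv[sel]), codes[sel])
    for (vs in by_code) {
      vs <- sort(unique(vs), method = "radix")
      if (length(vs) >= 2L) {
        idx <- utils::combn(vs, 2L)
        out <- rbind(out, t(idx))
      }
    }
    out <- unique(out)
  }
  colnames(out) <- c("v", "w")
  out
}

#' Is a network irreducible?
#'
#' A network is irreducible when it contains no identifiable pair of tree
#' vertices.
#'
#' @inheritParams identifiable_pairs
#' @return `TRUE` or `FALSE`.
#' @export
is_irreducible <- function(n, cap = 1e5) nrow(identifiable_pairs(n, cap)) == 0L

#' Decide whether a network is stable
#'
#' A phylogenetic network is stable when folding its unfolding returns a
#' network isomorphic to it. The report computes the answer three ways:
#' `stable_direct` (fold the unfolding, compare), `stable_by_thm1`
#' (compressed and no two distinct tree vertices with identical child sets;
#' only meaningful for semi-resolved networks, otherwise `NA`), and
#' `stable_by_cor3` (the tree of root paths is isomorphic, as a pseudo
#' MUL-tree, to the guide tree of the unfolding).
#'
#' @inheritParams identifiable_pairs
#' @return A list of class `stability_report` with fields `stable_direct`,
#'   `compressed`, `semi_resolved`, `irreducible`, `identifiable` (matrix),
#'   `duplicate_child_sets` (matrix of offending tree-vertex pairs),
#'   `stable_by_thm1` (logical or `NA`), `stable_by_cor3`.
#' @export
is_stable <- function(n, cap = 1e5) {
  chk <- validate_graph(n, "phylo_network")
  if (!chk$ok) stop("not a valid phylogenetic network: ",
                    paste(chk$violations, collapse = "; "))
  props <- net_properties(n)
  ures <- unfold_star(n, cap)
  u <- ures$u

  ft <- fold(u)
  stable_direct <- isTRUE(network_isomorphic(ft$result, n))

  idf <- identifiable_pairs_from(n, ures)
  irreducible <- nrow(idf) == 0L

  adj <- graph_adj(n)
  tree_internal <- setdiff(
    n$vertices[adj$indeg == 1L & adj$outdeg >= 2L], n$root)
  dup <- matrix(character(0), ncol = 2L)
  if (length(tree_internal) >= 2L) {
    chsig <- vapply(tree_internal, function(v)
      paste(sort(unique(adj$children[[v]]), method = "radix"), collapse = ","),
      character(1))
    for (vs in split(tree_internal, chsig)) {
      if (length(vs) >= 2L)
        dup <- rbind(dup, t(utils::combn(sort(vs, method = "radix"), 2L)))
    }
  }
  colnames(dup) <- c("v", "w")

  thm1 <- if (props$semi_resolved) props$compressed && nrow(dup) == 0L else NA
  cor3 <- multree_isomorphic(ures$ustar, ft$guide)

  structure(list(stable_direct = stable_direct,
                 compressed = props$compressed,
                 semi_resolved = props$semi_resolved,
                 irreducible = irreducible,
                 identifiable = idf,
                 duplicate_child_sets = dup,
                 stable_by_thm1 = thm1,
                 stable_by_cor3 = cor3),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  cat(sprintf("  stable (direct)        %s\n", x$stable_direct))
  cat(sprintf("  compressed             %s\n", x$compressed))
  cat(sprintf("  semi-resolved          %s\n", x$semi_resolved))
  cat(sprintf("  irreducible            %s\n", x$irreducible))
  cat(sprintf("  stable (child sets)    %s\n", x$stable_by_thm1))
  cat(sprintf("  stable (guide tree)    %s\n", x$stable_by_cor3))
  if (nrow(x$identifiable))
    cat("  identifiable pairs:   ",
        paste(apply(x$identifiable, 1L, paste, collapse = "~"),
              collapse = " "), "\n")
  invisible(x)
}
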