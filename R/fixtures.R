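# Named example objects used throughout the documentation and tests.

#' Example networks and MUL-trees
#'
#' Small named objects used across the package's examples and tests:
#' * `fixture_n1()` — binary, compressed, tree-child network on `{a, b, c}`
#'   with one reticulation `r`: arcs `(rho,u)`, `(rho,v)`, `(u,a)`, `(u,r)`,
#'   `(v,b)`, `(v,r)`, `(r,c)`.
#' * `fixture_n2()` — binary, compressed network on `{a, b}` whose two
#'   internal tree vertices share both reticulation children (not
#'   tree-sibling, not stable).
#' * `fixture_m1()` — the MUL-tree `((a,c),(b,c))`.
#' * `fixture_m2()` — the MUL-tree `((a,b),(a,b))`.
#' * `fixture_m3()` — the cherry `(a,a)` with both leaves labelled `a`.
#'
#' @return A `phydag`.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_n1 <- function() {
  phydag(c("rho", "u", "v", "r", "a", "b", "c"),
         data.frame(tail = c("rho", "rho", "u", "u", "v", "v", "r"),
                    head = c("u", "v", "a", "r", "b", "r", "c")),
         root = "rho", labels = c(a = "a", b = "b", c = "c"))
}

#' @rdname fixtures
#' @export
fixture_n2 <- function() {
  phydag(c("rho", "v", "w", "r1", "r2", "a", "b"),
         data.frame(tail = c("rho", "rho", "v", "v", "w", "w", "r1", "r2"),
                    head = c("v", "w", "r1", "r2", "r1", "r2", "a", "b")),
         root = "rho", labels = c(a = "a", b = "b"))
}

#' @rdname fixtures
#' @export
fixture_m1 <- function() read_mul_newick("((a,c),(b,c));")

#' @rdname fixtures
#' @export
fixture_m2 <- function() read_mul_newick("((a,b),(a,b));")

#' @rdname fixtures
#' @export
fixture_m3 <- function() read_mul_newick("(a,a);")
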