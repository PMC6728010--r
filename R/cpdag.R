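# Markov-equivalence machinery: CPDAG of a DAG, Meek orientation rules, and
# the structural Hamming distance between equivalence classes.
#
# Partially directed graphs are integer-free logical matrices P where
# P[i,j] & !P[j,i] means a directed edge i -> j and P[i,j] & P[j,i] an
# undirected edge.

#' Completed partially directed acyclic graph of a DAG
#'
#' Keeps the skeleton, orients the v-structures (colliders x -> z <- y with x
#' and y non-adjacent), and closes under the Meek orientation rules R1-R3
#' (R4 only arises with background knowledge, which is never supplied here),
#' yielding the canonical representative of the DAG's Markov equivalence
#' class.
#'
#' @param g a `guardnet_dag`.
#' @return logical matrix of class `"guardnet_pdag"`.
#' @examples
#' cpdag(dag(c("a", "b", "c"), rbind(c("a", "c"), c("b", "c"))))
#' @export
cpdag <- function(g) {
  a <- g$amat
  P <- a | t(a)  # skeleton, all undirected
  n <- nrow(a)
  for (z in seq_len(n)) {
    pa <- which(a[, z])
    if (length(pa) < 2) next
    for (x in pa) for (y in pa) {
      if (x >= y) next
      if (!a[x, y] && !a[y, x]) {  # non-adjacent parents: collider at z
        P[z, x] <- FALSE
        P[z, y] <- FALSE
      }
    }
  }
  P <- meek_closure(P)
  structure(P, class = "guardnet_pdag")
}

#' @export
print.guardnet_pdag <- function(x, ...) {
  nodes <- rownames(x)
  lines <- character(0)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j && x[i, j] && x[j, i])
      lines <- c(lines, paste(nodes[i], "--", nodes[j]))
    if (x[i, j] && !x[j, i])
      lines <- c(lines, paste(nodes[i], "->", nodes[j]))
  }
  cat("CPDAG:\n", paste0("  ", lines, collapse = "\n"), "\n")
  invisible(x)
}

meek_closure <- function(P) {
  n <- nrow(P)
  adj <- function(i, j) P[i, j] || P[j, i]
  dir_ <- function(i, j) P[i, j] && !P[j, i]
  und <- function(i, j) P[i, j] && P[j, i]
  repeat {
    changed <- FALSE
    for (b in seq_len(n)) for (c_ in seq_len(n)) {
      if (b == c_ || !und(b, c_)) next
      orient <- FALSE
      for (a in seq_len(n)) {
        if (a == b || a == c_) next
        # R1: a -> b, b -- c, a and c non-adjacent  =>  b -> c
        if (dir_(a, b) && !adj(a, c_)) { orient <- TRUE; break }
      }
      if (!orient) {
        # R2: b -> a -> c with b -- c  =>  b -> c
        for (a in seq_len(n)) {
          if (a == b || a == c_) next
          if (dir_(b, a) && dir_(a, c_)) { orient <- TRUE; break }
        }
      }
      if (!orient) {
        # R3: b -- a, b -- d, a -> c, d -> c, a and d non-adjacent => b -> c
        cand <- which(vapply(seq_len(n), function(a)
          a != b && a != c_ && und(b, a) && dir_(a, c_), TRUE))
        if (length(cand) >= 2) {
          for (a in cand) for (d in cand) {
            if (a < d && !adj(a, d)) { orient <- TRUE }
          }
        }
      }
      if (orient) { P[c_, b] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  P
}

pdag_of <- function(g) {
  if (inherits(g, "guardnet_pdag")) return(g)
  if (inherits(g, "guardnet_dag")) return(cpdag(g))
  stop("expected a guardnet_dag or guardnet_pdag")
}

#' Structural Hamming distance between equivalence classes
#'
#' Converts DAG inputs to their CPDAGs and counts node pairs whose edge type
#' (absent, directed either way, or undirected) differs — so two
#' Markov-equivalent DAGs are at distance 0.
#'
#' @param g1,g2 `guardnet_dag` or `guardnet_pdag` objects on the same nodes.
#' @return non-negative integer.
#' @export
shd <- function(g1, g2) {
  P1 <- pdag_of(g1); P2 <- pdag_of(g2)
  n1 <- rownames(P1); n2 <- rownames(P2)
  if (!setequal(n1, n2)) stop("graphs are defined on different node sets")
  P2 <- P2[n1, n1]
  d <- 0L
  for (i in seq_along(n1)) for (j in seq_along(n1)) {
    if (i >= j) next
    t1 <- edge_type(P1, i, j); t2 <- edge_type(P2, i, j)
    if (t1 != t2) d <- d + 1L
  }
  d
}

edge_type <- function(P, i, j) {
  if (P[i, j] && P[j, i]) return("undirected")
  if (P[i, j]) return("forward")
  if (P[j, i]) return("backward")
  "none"
}
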