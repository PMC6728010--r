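# Constraint-based structure learning: Grow-Shrink and IAMB Markov-blanket
# discovery over the Fisher-z conditional-independence test, followed by a
# shared skeleton/orientation phase that always returns a DAG.

dep <- function(data, x, y, Z, alpha) {
  !fisher_z_ci_test(data, x, y, Z, alpha)$independent
}

# Grow-Shrink blanket of `x`: grow by scanning candidates in column order,
# adding any variable dependent on x given the current blanket, until a full
# pass adds nothing; then shrink by removing any member independent of x
# given the rest of the blanket.
gs_blanket <- function(data, x, alpha) {
  others <- setdiff(colnames(data), x)
  B <- character(0)
  repeat {
    added <- FALSE
    for (y in setdiff(others, B)) {
      if (dep(data, x, y, B, alpha)) { B <- c(B, y); added <- TRUE }
    }
    if (!added) break
  }
  repeat {
    removed <- FALSE
    for (y in B) {
      if (!dep(data, x, y, setdiff(B, y), alpha)) {
        B <- setdiff(B, y); removed <- TRUE; break
      }
    }
    if (!removed) break
  }
  sort(B)
}

# IAMB blanket: forward phase admits, at each step, the candidate with the
# largest |partial correlation| given the current blanket (if dependent),
# interleaved with backward removal of members that have become independent.
iamb_blanket <- function(data, x, alpha) {
  others <- setdiff(colnames(data), x)
  B <- character(0)
  repeat {
    cand <- setdiff(others, B)
    if (length(cand) == 0) break
    assoc <- vapply(cand, function(y)
      abs(partial_correlation(data, x, y, B)), 0)
    best <- cand[which.max(assoc)]
    if (!dep(data, x, best, B, alpha)) break
    B <- c(B, best)
    repeat {
      removed <- FALSE
      for (y in B) {
        if (y == best) next
        if (!dep(data, x, y, setdiff(B, y), alpha)) {
          B <- setdiff(B, y); removed <- TRUE; break
        }
      }
      if (!removed) break
    }
  }
  sort(B)
}

#' Markov blankets of every variable
#'
#' @param data complete numeric matrix/data.frame.
#' @param alpha significance level of the Fisher-z tests.
#' @param method `"gs"` (Grow-Shrink) or `"iamb"`.
#' @param symmetrize if TRUE (default) blankets are symmetrized by
#'   intersection: y stays in blanket(x) only if x is in blanket(y).
#' @return named list of character vectors.
#' @export
markov_blankets <- function(data, alpha = 0.05, method = c("gs", "iamb"),
                            symmetrize = TRUE) {
  method <- match.arg(method)
  data <- as.matrix(data)
  fn <- if (method == "gs") gs_blanket else iamb_blanket
  B <- lapply(stats::setNames(colnames(data), colnames(data)),
              function(x) fn(data, x, alpha))
  if (symmetrize)
    for (x in names(B))
      B[[x]] <- sort(Filter(function(y) x %in% B[[y]], B[[x]]))
  B
}

# Skeleton from symmetrized blankets: x and y are adjacent iff y is in
# blanket(x) and no subset S of the smaller of B(x)\{y}, B(y)\{x} separates
# them. Separating sets are recorded for v-structure orientation.
blanket_skeleton <- function(data, B, alpha) {
  nodes <- names(B)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  sepset <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- nodes[i]; y <- nodes[j]
    if (!(y %in% B[[x]])) {
      # a node is d-separated from everything outside its blanket by the
      # blanket itself — record it so v-structure detection can consult it
      sepset[[paste(x, y, sep = "|")]] <- setdiff(B[[x]], y)
      next
    }
    bx <- setdiff(B[[x]], y); by <- setdiff(B[[y]], x)
    base <- if (length(bx) <= length(by)) bx else by
    separated <- FALSE
    for (S in all_subsets(base)) {
      if (!dep(data, x, y, S, alpha)) {
        separated <- TRUE
        sepset[[paste(x, y, sep = "|")]] <- S
        break
      }
    }
    if (!separated) adj[x, y] <- adj[y, x] <- TRUE
  }
  list(adj = adj, sepset = sepset)
}

all_subsets <- function(s) {
  out <- list(character(0))
  for (k in seq_along(s))
    out <- c(out, utils::combn(s, k, simplify = FALSE))
  out
}

# Orient v-structures from sepsets, close under Meek rules, then extend to a
# full DAG: remaining undirected edges are oriented lexicographically
# (tail < head in node order) unless that closes a directed cycle, in which
# case the reverse is used; an edge whose both orientations close cycles
# (possible only after conflicting v-structures) is dropped.
skeleton_to_dag <- function(data, sk) {
  P <- sk$adj
  nodes <- rownames(P)
  n <- length(nodes)
  for (z in seq_len(n)) {
    nb <- which(sk$adj[z, ])
    for (x in nb) for (y in nb) {
      if (x >= y) next
      if (sk$adj[x, y]) next
      key <- paste(nodes[min(x, y)], nodes[max(x, y)], sep = "|")
      S <- sk$sepset[[key]]
      if (is.null(S)) S <- character(0)
      if (!(nodes[z] %in% S)) {
        # collider x -> z <- y, unless an arm is already oriented away
        if (P[x, z] && P[z, x]) P[z, x] <- FALSE
        if (P[y, z] && P[z, y]) P[z, y] <- FALSE
      }
    }
  }
  P <- meek_closure(P)
  # directed part may contain conflict-induced cycles: drop weakest edges
  amat <- P & !t(P)
  while (!is_acyclic(amat)) {
    e <- which(amat, arr.ind = TRUE)
    on_cycle <- vapply(seq_len(nrow(e)), function(k) {
      a2 <- amat; a2[e[k, 1], e[k, 2]] <- FALSE
      has_directed_path(a2, e[k, 2], e[k, 1])
    }, TRUE)
    cand <- e[on_cycle, , drop = FALSE]
    w <- vapply(seq_len(nrow(cand)), function(k)
      abs(partial_correlation(data, nodes[cand[k, 1]], nodes[cand[k, 2]])), 0)
    drop_ <- cand[which.min(w), ]
    amat[drop_[1], drop_[2]] <- FALSE
    P[drop_[1], drop_[2]] <- FALSE
  }
  # lexicographic extension of the undirected remainder
  und <- which(P & t(P), arr.ind = TRUE)
  und <- und[und[, 1] < und[, 2], , drop = FALSE]
  if (nrow(und) > 0) {
    ord <- order(nodes[und[, 1]], nodes[und[, 2]])
    for (k in ord) {
      i <- und[k, 1]; j <- und[k, 2]
      if (!has_directed_path(amat, j, i)) {
        amat[i, j] <- TRUE
      } else if (!has_directed_path(amat, i, j)) {
        amat[j, i] <- TRUE
      }  # else: both orientations close a cycle; drop the edge
    }
  }
  amat_to_dag(amat, nodes)
}

#' Grow-Shrink structure learning
#'
#' Learns each variable's Markov blanket with the Grow-Shrink algorithm
#' (grow phase admits variables dependent given the current blanket, shrink
#' phase removes those independent given the rest), symmetrizes blankets by
#' intersection, resolves neighbours by subset search within blankets,
#' orients v-structures and Meek-propagates, and returns a DAG (remaining
#' undirected edges oriented by the deterministic lexicographic rule;
#' acyclicity is enforced).
#'
#' @param data complete numeric matrix/data.frame.
#' @param alpha significance level for the Fisher-z tests.
#' @return a `guardnet_dag`.
#' @export
grow_shrink <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  B <- markov_blankets(data, alpha, method = "gs")
  skeleton_to_dag(data, blanket_skeleton(data, B, alpha))
}

#' IAMB structure learning
#'
#' As [grow_shrink()], but blankets are discovered with the Incremental
#' Association Markov Blanket algorithm: the grow phase adds, at each step,
#' the variable with maximal |partial correlation| given the current blanket,
#' interleaved with backward removal.
#'
#' @inheritParams grow_shrink
#' @return a `guardnet_dag`.
#' @export
iamb <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  B <- markov_blankets(data, alpha, method = "iamb")
  skeleton_to_dag(data, blanket_skeleton(data, B, alpha))
}
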