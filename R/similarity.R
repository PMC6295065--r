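# Disease semantic similarity over ontology DAGs, and association-profile
# (MISIM-style) miRNA functional similarity.

#' Construct a disease DAG
#'
#' A disease's DAG is the disease itself plus all of its ontology ancestors,
#' together with the parent-to-child edges among them. This is the standard
#' MeSH-derived structure used for disease semantic similarity: each node
#' contributes to the disease's semantics with a weight that decays with
#' distance from the disease.
#'
#' @param disease_id Character scalar; must be one of `nodes`.
#' @param nodes Character vector of node ids (the disease and its ancestors).
#' @param edges Two-column character matrix or data frame of directed
#'   parent-to-child edges among `nodes`.
#' @return An object of class `disease_dag` with elements `disease_id`,
#'   `nodes` and `edges` (a two-column character matrix).
#' @examples
#' disease_dag("d", c("root", "a", "d"),
#'             rbind(c("root", "a"), c("a", "d")))
#' @export
disease_dag <- function(disease_id, nodes, edges) {
  stopifnot(is.character(disease_id), length(disease_id) == 1L, nzchar(disease_id))
  nodes <- unique(as.character(nodes))
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- matrix(as.character(edges), ncol = 2L)
  }
  colnames(edges) <- c("parent", "child")
  dag <- structure(list(disease_id = disease_id, nodes = nodes, edges = edges),
                   class = "disease_dag")
  validate_disease_dag(dag)
  dag
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> %s: %d nodes, %d edges\n",
              x$disease_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# topological order of `nodes` under parent->child `edges`; NULL on cycle
topo_order <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  kids <- split(edges[, "child"], factor(edges[, "parent"], levels = nodes))
  tab <- table(factor(edges[, "child"], levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

validate_disease_dag <- function(dag) {
  if (!dag$disease_id %in% dag$nodes)
    stop("disease id '", dag$disease_id, "' is not among the DAG nodes", call. = FALSE)
  bad <- setdiff(c(dag$edges), dag$nodes)
  if (length(bad))
    stop("edge endpoints not in node set: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(topo_order(dag$nodes, dag$edges)))
    stop("cycle detected in DAG of '", dag$disease_id, "'", call. = FALSE)
  invisible(dag)
}

#' Semantic contribution profile of a disease DAG
#'
#' Each node `t` of the DAG contributes to the disease `d` with weight
#' `D_d(d) = 1` and, for any ancestor `t`,
#' `D_d(t) = max { decay * D_d(t') : t' a child of t in the DAG }`,
#' so a node's contribution decays geometrically with its distance from the
#' disease along the steepest descending path. The semantic value `DV(d)` is
#' the sum of all contributions.
#'
#' @param dag A [disease_dag()].
#' @param decay Multiplicative decay per hierarchy level, in (0, 1).
#'   Defaults to 0.5, the conventional value for MeSH-based similarity.
#' @return Object of class `semantic_profile`: list with `disease_id`,
#'   `contribution` (named numeric, all values in (0, 1]) and
#'   `semantic_value` (their sum).
#' @examples
#' dag <- disease_dag("d", c("root", "a", "d"),
#'                    rbind(c("root", "a"), c("a", "d")))
#' semantic_profile(dag)  # contributions 1, 0.5, 0.25; DV = 1.75
#' @export
semantic_profile <- function(dag, decay = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), is.numeric(decay), length(decay) == 1L,
            decay > 0, decay < 1)
  validate_disease_dag(dag)
  ord <- topo_order(dag$nodes, dag$edges)
  # process nodes children-first (reverse topological order from d upward)
  contrib <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  contrib[dag$disease_id] <- 1
  kids <- split(dag$edges[, "child"], factor(dag$edges[, "parent"], levels = dag$nodes))
  for (t in rev(ord)) {
    if (t == dag$disease_id) next
    ck <- contrib[kids[[t]]]
    ck <- ck[!is.na(ck)]
    if (length(ck)) contrib[t] <- decay * max(ck)
  }
  if (anyNA(contrib)) {
    orphans <- names(contrib)[is.na(contrib)]
    stop("node(s) with no path down to '", dag$disease_id, "': ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  structure(list(disease_id = dag$disease_id,
                 contribution = contrib,
                 semantic_value = sum(contrib)),
            class = "semantic_profile")
}

#' @export
print.semantic_profile <- function(x, ...) {
  cat(sprintf("<semantic_profile> %s: %d nodes, DV = %.4f\n",
              x$disease_id, length(x$contribution), x$semantic_value))
  invisible(x)
}

#' Semantic similarity between two diseases
#'
#' The similarity is the summed contribution of the shared DAG nodes to both
#' diseases, normalised by the two semantic values:
#' `S(i, j) = sum_{t in T(i) ^ T(j)} (D_i(t) + D_j(t)) / (DV(i) + DV(j))`.
#' Diseases sharing more (and deeper) ancestors score higher; the result lies
#' in [0, 1] with `S(i, i) = 1`.
#'
#' @param p_i,p_j [semantic_profile()] objects.
#' @return Numeric scalar in [0, 1].
#' @export
disease_similarity <- function(p_i, p_j) {
  stopifnot(inherits(p_i, "semantic_profile"), inherits(p_j, "semantic_profile"))
  shared <- intersect(names(p_i$contribution), names(p_j$contribution))
  if (!length(shared)) return(0)
  sum(p_i$contribution[shared] + p_j$contribution[shared]) /
    (p_i$semantic_value + p_j$semantic_value)
}

#' Similarity between a disease and a disease set
#'
#' Best-match similarity: the maximum pairwise similarity between `d` and any
#' member of `group`, read off a precomputed disease similarity matrix.
#'
#' @param d Disease id.
#' @param group Nonempty character vector of disease ids.
#' @param W_d Labelled square disease similarity matrix.
#' @return Numeric scalar.
#' @export
disease_group_similarity <- function(d, group, W_d) {
  if (length(group) == 0L) stop("empty disease group", call. = FALSE)
  labs <- rownames(W_d)
  missing <- setdiff(c(d, group), labs)
  if (length(missing))
    stop("disease id(s) not in similarity matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  max(W_d[d, group])
}

#' Pairwise disease semantic similarity matrix
#'
#' Computes [semantic_profile()] for every DAG and fills the symmetric matrix
#' of pairwise [disease_similarity()] values. The upper triangle is computed
#' and mirrored, and the diagonal is set to exactly 1.
#'
#' @param dags List of [disease_dag()] objects with unique disease ids.
#' @param decay Passed to [semantic_profile()].
#' @return Labelled symmetric numeric matrix with unit diagonal.
#' @export
build_disease_similarity <- function(dags, decay = 0.5) {
  stopifnot(length(dags) >= 1L)
  ids <- vapply(dags, function(d) d$disease_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate disease ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  profiles <- lapply(dags, semantic_profile, decay = decay)
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        s <- disease_similarity(profiles[[i]], profiles[[j]])
        W[i, j] <- s
        W[j, i] <- s
      }
    }
  }
  diag(W) <- 1
  W
}

#' miRNA functional similarity from association profiles
#'
#' MISIM-style similarity: two miRNAs are functionally similar to the extent
#' that the diseases they are associated with are semantically similar. With
#' `DT1`, `DT2` the associated-disease sets of the two miRNAs,
#' `MISIM = (sum_i S(dt_1i, DT2) + sum_j S(dt_2j, DT1)) / (|DT1| + |DT2|)`,
#' where `S(d, DT)` is the best-match [disease_group_similarity()]. A miRNA
#' with no associated diseases has similarity 0 to every other miRNA (no
#' functional evidence) and 1 to itself; the diagonal is always exactly 1.
#'
#' @param A Binary association matrix, miRNAs in rows, diseases in columns
#'   (see [read_association()]).
#' @param W_d Disease similarity matrix covering every disease column of `A`.
#' @return Labelled symmetric miRNA similarity matrix with unit diagonal.
#' @export
mirna_functional_similarity <- function(A, W_d) {
  check_association_matrix(A)
  missing <- setdiff(colnames(A), rownames(W_d))
  if (length(missing))
    stop("disease(s) absent from similarity matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mirnas <- rownames(A)
  n <- length(mirnas)
  dts <- lapply(seq_len(n), function(i) colnames(A)[A[i, ] == 1])
  W <- matrix(0, n, n, dimnames = list(mirnas, mirnas))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      dt1 <- dts[[i]]
      for (j in seq.int(i + 1L, n)) {
        dt2 <- dts[[j]]
        if (length(dt1) == 0L || length(dt2) == 0L) next  # no evidence -> 0
        sub <- W_d[dt1, dt2, drop = FALSE]
        s <- (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
          (length(dt1) + length(dt2))
        W[i, j] <- s
        W[j, i] <- s
      }
    }
  }
  diag(W) <- 1
  W
}

#' Validate a similarity matrix
#'
#' Checks that a matrix is square, labelled, symmetric (within tolerance),
#' has a unit diagonal and entries in [0, 1].
#'
#' @param W Matrix to check.
#' @param tol Symmetry/diagonal tolerance.
#' @return Invisibly, `W`; errors otherwise.
#' @export
check_similarity_matrix <- function(W, tol = 1e-8) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("similarity matrix must be square", call. = FALSE)
  if (is.null(rownames(W)) || is.null(colnames(W)) ||
      !identical(rownames(W), colnames(W)))
    stop("similarity matrix must carry identical row and column labels", call. = FALSE)
  if (max(abs(W - t(W))) > tol)
    stop("similarity matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(W) - 1) > tol))
    stop("similarity matrix diagonal must be 1", call. = FALSE)
  if (min(W) < -tol || max(W) > 1 + tol)
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  invisible(W)
}

# binary labelled association matrix, miRNAs x diseases
check_association_matrix <- function(A) {
  if (!is.matrix(A)) stop("association matrix must be a matrix", call. = FALSE)
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("association matrix must have miRNA row names and disease column names",
         call. = FALSE)
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A)))
    stop("association matrix labels must be unique", call. = FALSE)
  if (!all(A %in% c(0, 1))) {
    bad <- which(!(A %in% c(0, 1)))[1L]
    rc <- arrayInd(bad, dim(A))
    stop(sprintf("non-binary association value at row %d ('%s'), column %d ('%s')",
                 rc[1], rownames(A)[rc[1]], rc[2], colnames(A)[rc[2]]), call. = FALSE)
  }
  invisible(A)
}
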