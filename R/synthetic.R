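# Seeded synthetic fixtures: ontology-like DAG forests and block-structured
# association matrices, so the whole pipeline is testable without downloads.

#' Specification for a synthetic fixture
#'
#' The generator emulates the shape of the real inputs: a disease ontology
#' organised as balanced trees (one per community, so diseases in the same
#' community share deep ancestors and hence high semantic similarity) and a
#' binary association matrix with planted miRNA/disease communities plus
#' Bernoulli noise. The defaults (20 miRNAs x 12 diseases, 3 blocks,
#' within-block association probability 0.8 against a 0.05 background,
#' depth-3 binary trees) give a small, clearly separable instance.
#'
#' @param n_mirnas,n_diseases Entity counts (>= 1).
#' @param n_blocks Number of planted communities.
#' @param p_within,p_between Association probabilities for block-matched and
#'   mismatched (miRNA, disease) pairs; `p_between <= p_within`.
#' @param dag_depth,dag_branching Shape of each community's ontology tree;
#'   the tree must have at least as many leaves as the community has
#'   diseases.
#' @param seed Integer seed; the same spec always yields bit-identical
#'   fixtures.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_mirnas = 20L, n_diseases = 12L, n_blocks = 3L,
                         p_within = 0.8, p_between = 0.05,
                         dag_depth = 3L, dag_branching = 2L, seed = 1L) {
  stopifnot(n_mirnas >= 1, n_diseases >= 1, n_blocks >= 1,
            p_between >= 0, p_within <= 1, p_between <= p_within,
            dag_depth >= 1, dag_branching >= 1)
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_diseases = as.integer(n_diseases),
                 n_blocks = as.integer(n_blocks),
                 p_within = p_within, p_between = p_between,
                 dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# run code under a temporary RNG state; offset splits the stream per component
with_fixture_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed %% 1000000L) * 1000L + offset)
  force(code)
}

# even partition of n items into k consecutive groups
block_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate an ontology-like DAG forest
#'
#' Builds one balanced tree per block (root `B<b>`, internal node ids as
#' dot-delimited paths mirroring tree numbers) and places the block's
#' diseases on consecutive leaves, so that diseases within a block share
#' deep ancestors while diseases in different blocks share none. The
#' structure is fully deterministic given the spec.
#'
#' @param spec A [fixture_spec()].
#' @return List with `dags` (one [disease_dag()] per disease), `edges`
#'   (data frame of all parent-child edges) and `disease_blocks` (named
#'   integer vector of block memberships).
#' @export
make_dag_forest <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  sizes <- block_sizes(spec$n_diseases, spec$n_blocks)
  leaves_per_tree <- spec$dag_branching^spec$dag_depth
  if (leaves_per_tree < max(sizes))
    stop(sprintf("tree with depth %d and branching %d has %d leaves; block needs %d diseases",
                 spec$dag_depth, spec$dag_branching, leaves_per_tree, max(sizes)),
         call. = FALSE)
  fmt <- paste0("D%0", max(2L, nchar(spec$n_diseases)), "d")
  disease_ids <- sprintf(fmt, seq_len(spec$n_diseases))
  dags <- vector("list", spec$n_diseases)
  all_edges <- list()
  blocks <- integer(0)
  idx <- 0L
  for (b in seq_len(spec$n_blocks)) {
    root <- sprintf("B%d", b)
    # full balanced tree below the root; leaf node ids carry the full path
    level_nodes <- list(root)
    edges <- list()
    for (depth in seq_len(spec$dag_depth)) {
      parents <- level_nodes[[depth]]
      children <- unlist(lapply(parents, function(p)
        paste0(p, ".", seq_len(spec$dag_branching))))
      edges[[depth]] <- cbind(parent = rep(parents, each = spec$dag_branching),
                              child = children)
      level_nodes[[depth + 1L]] <- children
    }
    edges <- do.call(rbind, edges)
    leaves <- level_nodes[[spec$dag_depth + 1L]]
    for (s in seq_len(sizes[b])) {
      idx <- idx + 1L
      did <- disease_ids[idx]
      leaf <- leaves[s]
      # rename this leaf to the disease id and keep its ancestor chain
      chain <- character(0)
      node <- leaf
      repeat {
        chain <- c(node, chain)
        parent <- edges[edges[, "child"] == node, "parent"]
        if (length(parent) == 0L) break
        node <- parent
      }
      nodes <- c(setdiff(chain, leaf), did)
      anc <- setdiff(chain, leaf)
      dag_edges <- cbind(parent = anc,
                         child = c(anc[-1L], did))
      dags[[idx]] <- disease_dag(did, nodes, dag_edges)
      blocks[did] <- b
      all_edges[[length(all_edges) + 1L]] <- dag_edges
    }
  }
  edges <- unique(as.data.frame(do.call(rbind, all_edges),
                                stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  list(dags = dags, edges = edges, disease_blocks = blocks)
}

#' Generate a planted-block association matrix
#'
#' miRNAs and diseases are partitioned into `n_blocks` consecutive groups;
#' each cell is Bernoulli(`p_within`) when the groups match and
#' Bernoulli(`p_between`) otherwise. The matched cells are the planted
#' ground truth used by recovery tests.
#'
#' @param spec A [fixture_spec()].
#' @return List with `A` (binary labelled matrix), `planted_pairs` (data
#'   frame of block-matched mirna/disease pairs), `mirna_blocks` and
#'   `disease_blocks` (named membership vectors).
#' @export
make_associations <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  fmt_m <- paste0("M%0", max(2L, nchar(spec$n_mirnas)), "d")
  fmt_d <- paste0("D%0", max(2L, nchar(spec$n_diseases)), "d")
  mirnas <- sprintf(fmt_m, seq_len(spec$n_mirnas))
  diseases <- sprintf(fmt_d, seq_len(spec$n_diseases))
  mb <- rep(seq_len(spec$n_blocks), block_sizes(spec$n_mirnas, spec$n_blocks))
  db <- rep(seq_len(spec$n_blocks), block_sizes(spec$n_diseases, spec$n_blocks))
  names(mb) <- mirnas; names(db) <- diseases
  match_mat <- outer(mb, db, `==`)
  p <- ifelse(match_mat, spec$p_within, spec$p_between)
  A <- with_fixture_seed(spec$seed, 1L, {
    matrix(as.numeric(stats::rbinom(length(p), 1L, as.vector(p))),
           nrow = spec$n_mirnas, dimnames = list(mirnas, diseases))
  })
  planted <- which(match_mat, arr.ind = TRUE)
  planted_pairs <- data.frame(mirna = mirnas[planted[, 1L]],
                              disease = diseases[planted[, 2L]],
                              stringsAsFactors = FALSE)
  list(A = A, planted_pairs = planted_pairs,
       mirna_blocks = mb, disease_blocks = db)
}

#' Generate a complete synthetic fixture
#'
#' Composes the generators in the same order as the real data flow:
#' ontology forest, disease semantic similarity, planted association matrix,
#' and association-derived miRNA functional similarity
#' ([mirna_functional_similarity()], mirroring how MISIM is built from the
#' association data rather than sampled independently).
#'
#' @param spec A [fixture_spec()].
#' @return Object of class `l1mda_fixture`: `dags`, `edges`, `A`, `W_m`,
#'   `W_d`, `planted_pairs`, `mirna_blocks`, `disease_blocks`, `spec`.
#' @examples
#' fx <- make_fixture(fixture_spec(seed = 42))
#' dim(fx$A)
#' @export
make_fixture <- function(spec = fixture_spec()) {
  forest <- make_dag_forest(spec)
  W_d <- build_disease_similarity(forest$dags)
  assoc <- make_associations(spec)
  stopifnot(identical(colnames(assoc$A), rownames(W_d)))
  W_m <- mirna_functional_similarity(assoc$A, W_d)
  structure(list(dags = forest$dags, edges = forest$edges,
                 A = assoc$A, W_m = W_m, W_d = W_d,
                 planted_pairs = assoc$planted_pairs,
                 mirna_blocks = assoc$mirna_blocks,
                 disease_blocks = assoc$disease_blocks,
                 spec = spec),
            class = "l1mda_fixture")
}

#' @export
print.l1mda_fixture <- function(x, ...) {
  cat(sprintf("<l1mda_fixture> %d miRNAs x %d diseases, %d blocks, %d known associations (seed %d)\n",
              nrow(x$A), ncol(x$A), x$spec$n_blocks, sum(x$A), x$spec$seed))
  invisible(x)
}

#' Write a fixture bundle to a directory
#'
#' Writes the DAG edge list, the association pair list, both similarity
#' matrices and the ground-truth block memberships as TSV files.
#'
#' @param fixture An `l1mda_fixture`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "l1mda_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dag = file.path(dir, "dag_edges.tsv"),
             associations = file.path(dir, "associations.tsv"),
             mirna_sim = file.path(dir, "mirna_similarity.tsv"),
             disease_sim = file.path(dir, "disease_similarity.tsv"),
             blocks = file.path(dir, "blocks.tsv"))
  utils::write.table(fixture$edges, paths["dag"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_association(fixture$A, paths["associations"], format = "pairs")
  write_similarity(fixture$W_m, paths["mirna_sim"])
  write_similarity(fixture$W_d, paths["disease_sim"])
  blocks <- rbind(data.frame(id = names(fixture$mirna_blocks), kind = "mirna",
                             block = unname(fixture$mirna_blocks)),
                  data.frame(id = names(fixture$disease_blocks), kind = "disease",
                             block = unname(fixture$disease_blocks)))
  utils::write.table(blocks, paths["blocks"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
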