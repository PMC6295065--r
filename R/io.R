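# Readers and writers for the tabular interchange formats. TSV is the
# canonical dialect; a comma-delimited fallback is auto-detected from the
# header line. Readers validate and reject rather than silently coerce.

detect_sep <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_table_strict <- function(path, sep, header = TRUE, row_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- tryCatch(
    utils::read.table(path, sep = sep, header = header, row.names = row_names,
                      check.names = FALSE, colClasses = NA, fill = FALSE,
                      blank.lines.skip = FALSE, quote = "",
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop("malformed table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  out
}

#' Read a labelled similarity matrix
#'
#' Expects a square numeric table with a header row and first-column labels
#' (tab- or comma-delimited, auto-detected). On read, symmetry is checked to
#' a tolerance of 1e-6 and then enforced exactly by averaging with the
#' transpose; off-unit diagonal entries within the tolerance are snapped to
#' 1 with a warning. Values outside [-1e-6, 1 + 1e-6], missing labels or a
#' non-square layout are rejected.
#'
#' @param path File path.
#' @return Labelled symmetric numeric matrix.
#' @seealso [write_similarity()]
#' @export
read_similarity <- function(path) {
  sep <- detect_sep(path)
  df <- read_table_strict(path, sep, header = TRUE, row_names = 1L)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("similarity matrix has non-numeric entries: ", path,
                           call. = FALSE)
  if (nrow(M) != ncol(M))
    stop(sprintf("similarity matrix must be square, got %d x %d: %s",
                 nrow(M), ncol(M), path), call. = FALSE)
  if (is.null(rownames(M)) || is.null(colnames(M)) ||
      any(!nzchar(rownames(M))) || any(!nzchar(colnames(M))))
    stop("similarity matrix must have row and column labels: ", path, call. = FALSE)
  if (!identical(rownames(M), colnames(M)))
    stop("row and column labels disagree: ", path, call. = FALSE)
  if (min(M) < -1e-6 || max(M) > 1 + 1e-6)
    stop("similarity values outside [0, 1]: ", path, call. = FALSE)
  if (max(abs(M - t(M))) > 1e-6)
    stop("similarity matrix asymmetric beyond tolerance 1e-6: ", path, call. = FALSE)
  M <- (M + t(M)) / 2
  if (any(diag(M) != 1)) {
    if (max(abs(diag(M) - 1)) > 1e-6)
      stop("similarity diagonal differs from 1 beyond tolerance: ", path, call. = FALSE)
    warning("similarity diagonal off by <= 1e-6; snapped to 1", call. = FALSE)
    diag(M) <- 1
  }
  M[M < 0] <- 0
  M[M > 1] <- 1
  M
}

#' Write a labelled similarity matrix
#'
#' Tab-separated, header row plus first-column labels, full `%.17g`
#' precision so that a write/read cycle reproduces values exactly (well
#' beyond 15 significant digits).
#'
#' @param W Labelled square matrix.
#' @param path Output path.
#' @export
write_similarity <- function(W, path) {
  check_similarity_matrix(W)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(W)), collapse = "\t"), con)
  for (i in seq_len(nrow(W)))
    writeLines(paste(c(rownames(W)[i], sprintf("%.17g", W[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a miRNA-disease association table
#'
#' Two layouts are supported. `"matrix"`: a labelled 0/1 matrix with a
#' header row and first-column miRNA labels; any non-binary value is
#' rejected with its coordinates. `"pairs"`: a two-column
#' (miRNA, disease) list with a header line; extra columns (provenance) are
#' ignored, duplicate pairs collapse to a single 1 with a warning, and the
#' matrix is laid out over the sorted union of observed ids. `"auto"` picks
#' `"pairs"` for tables of 2-3 character columns, `"matrix"` otherwise.
#'
#' @param path File path (tab- or comma-delimited, auto-detected).
#' @param format `"auto"`, `"matrix"` or `"pairs"`.
#' @return Binary labelled matrix, miRNAs in rows, diseases in columns.
#' @export
read_association <- function(path, format = c("auto", "matrix", "pairs")) {
  format <- match.arg(format)
  sep <- detect_sep(path)
  if (format == "auto") {
    probe <- read_table_strict(path, sep, header = TRUE)
    format <- if (ncol(probe) %in% 2:3 &&
                  all(vapply(probe[1:2], is.character, logical(1))))
      "pairs" else "matrix"
  }
  if (format == "pairs") {
    df <- read_table_strict(path, sep, header = TRUE)
    if (ncol(df) < 2L) stop("pair list needs at least 2 columns: ", path, call. = FALSE)
    m <- as.character(df[[1L]]); d <- as.character(df[[2L]])
    if (any(!nzchar(m)) || any(!nzchar(d)))
      stop("empty entity id in pair list: ", path, call. = FALSE)
    key <- paste(m, d, sep = "\r")
    if (anyDuplicated(key)) {
      warning(sum(duplicated(key)), " duplicate pair(s) collapsed", call. = FALSE)
      keep <- !duplicated(key)
      m <- m[keep]; d <- d[keep]
    }
    mirnas <- sort(unique(m)); diseases <- sort(unique(d))
    A <- matrix(0, length(mirnas), length(diseases),
                dimnames = list(mirnas, diseases))
    A[cbind(match(m, mirnas), match(d, diseases))] <- 1
  } else {
    df <- read_table_strict(path, sep, header = TRUE, row_names = 1L)
    A <- as.matrix(df)
    if (!is.numeric(A))
      stop("association matrix has non-numeric entries: ", path, call. = FALSE)
    bad <- which(!(A %in% c(0, 1)))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(A))
      stop(sprintf("non-binary association value %g at row %d ('%s'), column %d ('%s'): %s",
                   A[bad[1L]], rc[1], rownames(A)[rc[1]], rc[2], colnames(A)[rc[2]],
                   path), call. = FALSE)
    }
  }
  storage.mode(A) <- "double"
  check_association_matrix(A)
  A
}

#' Write an association table
#'
#' @param A Binary labelled association matrix.
#' @param path Output path.
#' @param format `"matrix"` (labelled 0/1 TSV) or `"pairs"` (two-column
#'   miRNA/disease list of the 1 cells).
#' @export
write_association <- function(A, path, format = c("matrix", "pairs")) {
  format <- match.arg(format)
  check_association_matrix(A)
  if (format == "pairs") {
    idx <- which(A == 1, arr.ind = TRUE)
    df <- data.frame(mirna = rownames(A)[idx[, 1L]],
                     disease = colnames(A)[idx[, 2L]],
                     stringsAsFactors = FALSE)
    df <- df[order(df$mirna, df$disease), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(A, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}

#' Read a DAG edge list
#'
#' Two-column `parent`/`child` table with one header line; node ids are
#' opaque case-sensitive strings.
#'
#' @param path File path.
#' @return Data frame with character columns `parent` and `child`.
#' @export
read_dag_edges <- function(path) {
  sep <- detect_sep(path)
  df <- read_table_strict(path, sep, header = TRUE)
  if (ncol(df) < 2L) stop("edge list needs 2 columns: ", path, call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("parent", "child")
  df$parent <- as.character(df$parent); df$child <- as.character(df$child)
  if (any(!nzchar(df$parent)) || any(!nzchar(df$child)))
    stop("empty node id in edge list: ", path, call. = FALSE)
  df
}

#' Build per-disease DAGs from an ontology edge list
#'
#' Each disease's DAG is its ancestor closure: the disease itself, every
#' node from which it is reachable, and the edges among them.
#'
#' @param edges Data frame from [read_dag_edges()] (or equivalent).
#' @param diseases Character vector of disease ids; defaults to the leaf
#'   nodes (nodes that are never a parent).
#' @return List of [disease_dag()] objects.
#' @export
dags_from_edges <- function(edges, diseases = NULL) {
  parents_of <- split(edges$parent, edges$child)
  all_nodes <- unique(c(edges$parent, edges$child))
  if (is.null(diseases))
    diseases <- sort(setdiff(all_nodes, unique(edges$parent)))
  missing <- setdiff(diseases, all_nodes)
  if (length(missing))
    stop("disease id(s) not in ontology: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(diseases, function(d) {
    nodes <- d
    frontier <- d
    while (length(frontier)) {
      up <- unique(unlist(parents_of[frontier], use.names = FALSE))
      frontier <- setdiff(up, nodes)
      nodes <- c(nodes, frontier)
    }
    sub <- edges[edges$parent %in% nodes & edges$child %in% nodes, , drop = FALSE]
    disease_dag(d, nodes, as.matrix(sub))
  })
}

#' Read MeSH-style descriptor records
#'
#' Expects a two-column table (disease name, dot-delimited tree number; one
#' row per tree number, so a disease appearing at several ontology positions
#' has several rows). Only records whose tree number starts with `C`
#' (the disease category) are kept. Ancestry is prefix truncation at each
#' dot; a disease with multiple tree numbers gets ONE DAG over the union of
#' its ancestors. Ancestor tree numbers without a record of their own are
#' bridged: each ancestor chain is restricted to named entries and
#' consecutive survivors are linked, so every node keeps a path to the
#' disease.
#'
#' @param path File path.
#' @return List of [disease_dag()] objects, one per disease name.
#' @export
read_mesh_records <- function(path) {
  sep <- detect_sep(path)
  df <- read_table_strict(path, sep, header = TRUE)
  if (ncol(df) < 2L) stop("MeSH record table needs 2 columns: ", path, call. = FALSE)
  name <- as.character(df[[1L]]); treenum <- as.character(df[[2L]])
  keep <- grepl("^C", treenum)
  name <- name[keep]; treenum <- treenum[keep]
  if (!length(name)) stop("no Category C records in ", path, call. = FALSE)
  num2name <- stats::setNames(name, treenum)
  prefix_chain <- function(tn) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1L]]
    vapply(seq_along(parts), function(i) paste(parts[1:i], collapse = "."),
           character(1))
  }
  diseases <- unique(name)
  lapply(diseases, function(d) {
    nodes <- d
    edge_list <- list()
    for (tn in treenum[name == d]) {
      chain <- prefix_chain(tn)
      present <- chain[chain %in% names(num2name)]
      ids <- unname(num2name[present])
      ids[present == tn] <- d          # the disease itself
      ids <- ids[!duplicated(ids)]
      if (!identical(ids[length(ids)], d)) ids <- c(ids, d)
      nodes <- union(nodes, ids)
      if (length(ids) > 1L)
        edge_list[[length(edge_list) + 1L]] <-
          cbind(parent = ids[-length(ids)], child = ids[-1L])
    }
    edges <- unique(do.call(rbind, c(edge_list, list(matrix(character(0), ncol = 2)))))
    disease_dag(d, nodes, edges)
  })
}

#' Write long-format predictions
#'
#' One row per (miRNA, disease) pair with the fused score and the
#' known-association flag, sorted by score descending (ties by miRNA then
#' disease id for determinism).
#'
#' @param scores Fused score matrix (or an `l1graph` fit).
#' @param A Association matrix supplying the known flags.
#' @param path Output path.
#' @export
write_predictions <- function(scores, A, path) {
  if (inherits(scores, "l1graph")) scores <- scores$scores
  stopifnot(all(dim(scores) == dim(A)))
  df <- data.frame(mirna = rep(rownames(scores), times = ncol(scores)),
                   disease = rep(colnames(scores), each = nrow(scores)),
                   score = as.vector(scores),
                   known = as.integer(as.vector(A) == 1),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$mirna, df$disease), , drop = FALSE]
  df$score <- sprintf("%.17g", df$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
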