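# L1-norm graph semi-supervised solver: iteratively re-weighted Laplacian
# label propagation in miRNA space and disease space, plus fusion.

#' Solver configuration
#'
#' @param anchor_weight Positive scalar; uniform diagonal of the anchor
#'   matrix U that ties the solution to the observed associations. Larger
#'   values keep the scores closer to the 0/1 input.
#' @param epsilon Positive floor for the score-profile distance in the
#'   re-weighting step, guarding against division by zero when two rows of
#'   the score matrix coincide.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum number of re-weighting iterations.
#' @param seed Integer kept for bookkeeping of fixture generation; the solver
#'   itself is fully deterministic.
#' @return List of class `solver_config`.
#' @export
solver_config <- function(anchor_weight = 1, epsilon = 1e-8, tol = 1e-6,
                          max_iter = 100L, seed = 1L) {
  stopifnot(anchor_weight > 0, epsilon > 0, tol > 0, max_iter >= 1)
  structure(list(anchor_weight = as.numeric(anchor_weight),
                 epsilon = as.numeric(epsilon),
                 tol = as.numeric(tol),
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "solver_config")
}

# Euclidean distances between rows of Q
row_distances <- function(Q) {
  as.matrix(stats::dist(Q, method = "euclidean"))
}

#' Re-weighted similarity graph
#'
#' One half-quadratic step of the iteratively re-weighted scheme: the graph
#' weight between entities i and j becomes
#' `W_ij / (2 * max(||q_i - q_j||_2, epsilon))`, where `q_i` is row i of the
#' current score matrix. Entities whose current scores agree get their edges
#' boosted (down to the `epsilon` floor), which is what turns the unsquared
#' L1-type smoothness penalty into a sequence of ordinary Laplacian solves.
#' The diagonal is set to zero (self-edges cancel in the Laplacian; zeroing
#' them keeps the floor from inflating node degrees).
#'
#' @param W Square nonnegative similarity matrix.
#' @param Q Score matrix with one row per entity of `W`.
#' @param epsilon Distance floor (> 0).
#' @return Re-weighted matrix of the same shape as `W`.
#' @export
reweight <- function(W, Q, epsilon = 1e-8) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be square", call. = FALSE)
  Q <- as.matrix(Q)
  if (nrow(Q) != nrow(W))
    stop(sprintf("Q has %d rows but W is %d x %d", nrow(Q), nrow(W), ncol(W)),
         call. = FALSE)
  stopifnot(epsilon > 0)
  Wt <- W / (2 * pmax(row_distances(Q), epsilon))
  diag(Wt) <- 0
  dimnames(Wt) <- dimnames(W)
  Wt
}

#' L1-norm graph objective
#'
#' The value being minimised:
#' `sum_{i,j} W_ij ||q_i - q_j||_2 + sum_i U_ii ||q_i - a_i||_2^2`,
#' an unsquared (hence outlier-robust, sparsity-inducing) graph smoothness
#' penalty over all ordered entity pairs plus a quadratic fidelity term
#' anchoring each row of the score matrix to the observed associations.
#'
#' @param W Square similarity matrix.
#' @param Q Score matrix (rows = entities of `W`).
#' @param A_space Observed 0/1 matrix of the same shape as `Q`.
#' @param U Anchor weights: scalar or per-row vector (diagonal of U).
#' @return Numeric scalar.
#' @export
graph_objective <- function(W, Q, A_space, U = 1) {
  Q <- as.matrix(Q); A_space <- as.matrix(A_space)
  stopifnot(is.matrix(W), nrow(W) == ncol(W), nrow(Q) == nrow(W),
            all(dim(Q) == dim(A_space)))
  u <- rep_len(U, nrow(Q))
  sum(W * row_distances(Q)) + sum(u * rowSums((Q - A_space)^2))
}

#' Solve one propagation space
#'
#' Minimises [graph_objective()] over the score matrix Q for a single space
#' (miRNA or disease) by majorise-minimise iterations: starting from
#' `Q = A_space`, repeatedly form the re-weighted graph W-tilde
#' ([reweight()]), its Laplacian `L = D - W~`, and solve the symmetric
#' positive-definite system `(2L + U) Q = U A_space`. Each step minimises a
#' quadratic majoriser of the objective, so the objective trace is
#' non-increasing and the iteration converges to the global optimum of the
#' convex objective. (The factor 2 on the Laplacian reflects the smoothness
#' sum running over ordered pairs.)
#'
#' @param W Square similarity matrix for the space (k x k).
#' @param A_space k x c matrix of 0/1 anchors (the association matrix or its
#'   transpose).
#' @param config A [solver_config()].
#' @param verbose If `TRUE`, print one log line per iteration (iteration
#'   index, objective, relative change).
#' @return List of class `space_solution`: `Q` (final scores, labelled like
#'   `A_space`), `states` (per-iteration list with `iteration`, `objective`,
#'   `objective_vector_norm` — the L1 norm of the smoothness-term vector —,
#'   `fidelity` and `rel_change`), `W_tilde`, `D_tilde`, `L_tilde`, `U`
#'   (final re-weighted graph, degree vector, Laplacian, anchor diagonal),
#'   `converged`, `iterations`.
#' @export
solve_space <- function(W, A_space, config = solver_config(), verbose = FALSE) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be square", call. = FALSE)
  A_space <- as.matrix(A_space)
  if (nrow(A_space) != nrow(W))
    stop(sprintf("A has %d rows but W is %d x %d", nrow(A_space), nrow(W), ncol(W)),
         call. = FALSE)
  if (!all(A_space %in% c(0, 1)))
    stop("anchor matrix entries must be 0 or 1", call. = FALSE)
  k <- nrow(W)
  u <- rep(config$anchor_weight, k)
  Q <- A_space
  obj <- graph_objective(W, Q, A_space, u)
  states <- list()
  converged <- FALSE
  Wt <- matrix(0, k, k); ddeg <- numeric(k); L <- matrix(0, k, k)
  for (it in seq_len(config$max_iter)) {
    Wt <- reweight(W, Q, config$epsilon)
    ddeg <- rowSums(Wt)
    L <- diag(ddeg, k) - Wt
    M <- 2 * L + diag(u, k)
    Q <- tryCatch(solve(M, u * A_space),
                  error = function(e) stop("solver failed: linear system (2L + U) is ",
                                           "numerically singular: ", conditionMessage(e),
                                           call. = FALSE))
    dimnames(Q) <- dimnames(A_space)
    smooth <- sum(W * row_distances(Q))
    fidel <- sum(u * rowSums((Q - A_space)^2))
    obj_new <- smooth + fidel
    rel <- abs(obj - obj_new) / max(abs(obj), .Machine$double.eps)
    if (verbose)
      message(sprintf("iter %3d  objective %.8g  rel_change %.3g", it, obj_new, rel))
    states[[it]] <- list(iteration = it, objective = obj_new,
                         objective_vector_norm = smooth, fidelity = fidel,
                         rel_change = rel)
    obj <- obj_new
    if (rel < config$tol) { converged <- TRUE; break }
  }
  structure(list(Q = Q, states = states, W_tilde = Wt, D_tilde = ddeg,
                 L_tilde = L, U = u, converged = converged,
                 iterations = length(states)),
            class = "space_solution")
}

check_fit_labels <- function(A, W_m, W_d) {
  check_association_matrix(A)
  check_similarity_matrix(W_m)
  check_similarity_matrix(W_d)
  miss_m <- setdiff(rownames(A), rownames(W_m))
  miss_d <- setdiff(colnames(A), rownames(W_d))
  if (length(miss_m) || length(miss_d))
    stop("entities missing from similarity matrices: ",
         paste(c(miss_m, miss_d), collapse = ", "), call. = FALSE)
  invisible(NULL)
}

#' Fit the L1-norm graph association model
#'
#' The main fitting function. Given a binary miRNA-disease association
#' matrix `A` (n miRNAs x m diseases), a miRNA functional similarity matrix
#' `W_m` (n x n) and a disease semantic similarity matrix `W_d` (m x m), the
#' model propagates the observed labels over both similarity graphs under an
#' L1-norm smoothness penalty ([graph_objective()]), solved by iterative
#' re-weighting ([solve_space()]) separately in the miRNA space
#' (`Q_m`, anchored to `A`) and the disease space (`Q_d`, anchored to `A`
#' transposed). The fused prediction is `Q_final = (Q_m + t(Q_d)) / 2`; large
#' entries of `Q_final` at zero cells of `A` flag candidate associations.
#'
#' @param A Binary association matrix with miRNA row names and disease
#'   column names (see [read_association()]).
#' @param W_m,W_d miRNA and disease similarity matrices whose labels cover
#'   the rows resp. columns of `A` (see [mirna_functional_similarity()] and
#'   [build_disease_similarity()]).
#' @param anchor_weight,epsilon,tol,max_iter See [solver_config()].
#' @param config Alternatively, a ready-made [solver_config()]; overrides
#'   the individual arguments.
#' @param verbose Print per-iteration log lines.
#' @return Object of class `l1graph`: list with `scores` (Q_final, labelled
#'   like `A`), `Q_m`, `Q_d`, `space_m`, `space_d` (the two
#'   [solve_space()] solutions), `A`, `config`, `call`. Methods:
#'   [print.l1graph()], [summary.l1graph()], [coef.l1graph()],
#'   [fitted.l1graph()], [residuals.l1graph()], [predict.l1graph()],
#'   [plot.l1graph()].
#' @examples
#' fx <- make_fixture(fixture_spec(seed = 7))
#' fit <- l1graph(fx$A, fx$W_m, fx$W_d)
#' fit
#' head(predict(fit, disease = colnames(fx$A)[1], k = 5))
#' @export
l1graph <- function(A, W_m, W_d, anchor_weight = 1, epsilon = 1e-8,
                    tol = 1e-6, max_iter = 100L, config = NULL,
                    verbose = FALSE) {
  if (is.null(config))
    config <- solver_config(anchor_weight = anchor_weight, epsilon = epsilon,
                            tol = tol, max_iter = max_iter)
  # align similarity matrices to the association matrix's label order
  check_fit_labels(A, W_m, W_d)
  W_m <- W_m[rownames(A), rownames(A), drop = FALSE]
  W_d <- W_d[colnames(A), colnames(A), drop = FALSE]
  sm <- solve_space(W_m, A, config, verbose = verbose)
  sd_ <- solve_space(W_d, t(A), config, verbose = verbose)
  scores <- (sm$Q + t(sd_$Q)) / 2
  dimnames(scores) <- dimnames(A)
  structure(list(scores = scores, Q_m = sm$Q, Q_d = sd_$Q,
                 space_m = sm, space_d = sd_, A = A, config = config,
                 call = match.call()),
            class = "l1graph")
}

#' @export
print.l1graph <- function(x, ...) {
  cat("L1-norm graph miRNA-disease association model\n")
  cat(sprintf("  %d miRNAs x %d diseases, %d known associations\n",
              nrow(x$A), ncol(x$A), sum(x$A)))
  cat(sprintf("  anchor_weight = %g, converged: miRNA space %s (%d it), disease space %s (%d it)\n",
              x$config$anchor_weight,
              x$space_m$converged, x$space_m$iterations,
              x$space_d$converged, x$space_d$iterations))
  invisible(x)
}

#' @rdname l1graph
#' @param object,x An `l1graph` fit.
#' @param ... Unused.
#' @export
summary.l1graph <- function(object, ...) {
  s <- object$scores
  known <- object$A == 1
  out <- list(
    n_mirnas = nrow(object$A), n_diseases = ncol(object$A),
    n_known = sum(object$A),
    config = object$config,
    iterations = c(mirna = object$space_m$iterations,
                   disease = object$space_d$iterations),
    objective = c(mirna = utils::tail(object$space_m$states, 1)[[1]]$objective,
                  disease = utils::tail(object$space_d$states, 1)[[1]]$objective),
    score_known = summary(s[known]),
    score_unknown = summary(s[!known]))
  class(out) <- "summary.l1graph"
  out
}

#' @export
print.summary.l1graph <- function(x, ...) {
  cat("L1-norm graph association model\n")
  cat(sprintf("  %d miRNAs x %d diseases, %d known associations\n",
              x$n_mirnas, x$n_diseases, x$n_known))
  cat(sprintf("  iterations: %d (miRNA space), %d (disease space)\n",
              x$iterations["mirna"], x$iterations["disease"]))
  cat(sprintf("  final objectives: %.6g (miRNA), %.6g (disease)\n",
              x$objective["mirna"], x$objective["disease"]))
  cat("  scores at known associations:\n"); print(x$score_known)
  cat("  scores at unconfirmed pairs:\n"); print(x$score_unknown)
  invisible(x)
}

#' @rdname l1graph
#' @export
coef.l1graph <- function(object, ...) object$scores

#' @rdname l1graph
#' @export
fitted.l1graph <- function(object, ...) object$scores

#' @rdname l1graph
#' @export
residuals.l1graph <- function(object, ...) object$scores - object$A

#' Predict ranked candidates from an l1graph fit
#'
#' With `disease` given, returns that disease's candidate miRNAs ranked by
#' fused score (see [rank_candidates()]); otherwise returns the full fused
#' score matrix.
#'
#' @param object An `l1graph` fit.
#' @param disease Optional disease id.
#' @param k Number of top candidates to keep.
#' @param exclude_known Drop miRNAs already associated with `disease`.
#' @param ... Unused.
#' @export
predict.l1graph <- function(object, disease = NULL, k = 50L,
                            exclude_known = FALSE, ...) {
  if (is.null(disease)) return(object$scores)
  rank_candidates(object$scores, object$A, disease, k = k,
                  exclude_known = exclude_known)
}

#' Plot the objective traces of an l1graph fit
#'
#' One line per propagation space; the trace is non-increasing by
#' construction.
#'
#' @param x An `l1graph` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.l1graph <- function(x, ...) {
  om <- vapply(x$space_m$states, `[[`, numeric(1), "objective")
  od <- vapply(x$space_d$states, `[[`, numeric(1), "objective")
  n <- max(length(om), length(od))
  traces <- cbind(mirna = c(om, rep(NA, n - length(om))),
                  disease = c(od, rep(NA, n - length(od))))
  graphics::matplot(seq_len(n), traces, type = "b", pch = c(1, 2),
                    xlab = "iteration", ylab = "objective",
                    main = "L1-graph objective trace", ...)
  graphics::legend("topright", legend = c("miRNA space", "disease space"),
                   pch = c(1, 2), col = 1:2, lty = 1:2, bty = "n")
  invisible(x)
}
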