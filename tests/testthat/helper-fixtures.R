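# Shared builders and independent oracles used across the test files.

# simple labelled DAGs -------------------------------------------------------

chain_dag <- function(ids) {
  # ids from root to disease; disease is the last id
  n <- length(ids)
  edges <- if (n > 1) cbind(ids[-n], ids[-1]) else matrix(character(0), ncol = 2)
  disease_dag(ids[n], ids, edges)
}

# two children A, B under shared root R
sibling_dags <- function() {
  list(A = disease_dag("A", c("R", "A"), rbind(c("R", "A"))),
       B = disease_dag("B", c("R", "B"), rbind(c("R", "B"))))
}

# small labelled matrices ----------------------------------------------------

toy_similarity <- function(n, labels = sprintf("e%d", seq_len(n)), fill = 0) {
  W <- matrix(fill, n, n, dimnames = list(labels, labels))
  diag(W) <- 1
  W
}

# the spec's 4 miRNAs x 2 diseases toy instance
toy_instance <- function() {
  W <- matrix(0.1, 4, 4)
  W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 0.9
  diag(W) <- 0
  A <- rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 0))
  list(W = W, A = A)
}

# random labelled binary association matrix + similarity matrices
random_problem <- function(n, m, seed, p = 0.3) {
  set.seed(seed)
  A <- matrix(rbinom(n * m, 1, p), n,
              dimnames = list(sprintf("M%02d", 1:n), sprintf("D%02d", 1:m)))
  rand_sim <- function(k, labels) {
    S <- matrix(runif(k * k), k, k)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(labels, labels)
    S
  }
  list(A = A, W_m = rand_sim(n, rownames(A)), W_d = rand_sim(m, colnames(A)))
}

# independent oracles --------------------------------------------------------

# AUC by exhaustive positive x negative pair counting, ties half a win
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# derivative-free minimization of the graph objective over Q (small
# instances). The objective is convex but non-smooth where score rows
# coincide, so single-start simplex search can stall; use several generic
# starts and alternate simplex and quasi-Newton polishing, keeping the best.
brute_min_objective <- function(W, A, anchor_weight = 1) {
  fn <- function(q) graph_objective(W, matrix(q, nrow(A), ncol(A)), A, anchor_weight)
  starts <- list(as.vector(A),
                 rep(0, length(A)),
                 rep(0.5, length(A)),
                 as.vector(matrix(colMeans(A), nrow(A), ncol(A), byrow = TRUE)))
  set.seed(1)
  starts <- c(starts, list(stats::runif(length(A))))
  best <- Inf
  for (par in starts) {
    for (i in 1:4) {
      o1 <- stats::optim(par, fn, method = "Nelder-Mead",
                         control = list(maxit = 50000, reltol = 1e-15))
      o2 <- stats::optim(o1$par, fn, method = "BFGS",
                         control = list(maxit = 5000, reltol = 1e-15))
      par <- o2$par
      best <- min(best, o1$value, o2$value)
    }
  }
  best
}

objective_trace <- function(space_solution) {
  vapply(space_solution$states, `[[`, numeric(1), "objective")
}
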