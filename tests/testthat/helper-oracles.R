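# Shared fixtures and independent oracles used across test files.

# random symmetric weighted graph on S nodes with edge probability prob
random_graph <- function(S, prob = 0.3) {
  a <- matrix(0, S, S)
  m <- S * (S - 1) / 2
  a[upper.tri(a)] <- stats::rbinom(m, 1, prob) * stats::runif(m, 0.2, 1)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("R%02d", seq_len(S)),
                      sprintf("R%02d", seq_len(S)))
  a
}

# binary rook-adjacency grid graph (m x m), for Moran's I checks
grid_adjacency <- function(m) {
  S <- m * m
  idx <- function(i, j) (i - 1) * m + j
  a <- matrix(0, S, S)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < m) a[idx(i, j), idx(i + 1, j)] <- a[idx(i + 1, j), idx(i, j)] <- 1
    if (j < m) a[idx(i, j), idx(i, j + 1)] <- a[idx(i, j + 1), idx(i, j)] <- 1
  }
  dimnames(a) <- list(sprintf("G%03d", seq_len(S)),
                      sprintf("G%03d", seq_len(S)))
  a
}

# a random penalized-regression instance with every region observed
random_instance <- function(S = NULL, n = NULL, p = NULL) {
  if (is.null(S)) S <- sample(5:25, 1)
  if (is.null(n)) n <- sample((2 * S):300, 1)
  if (is.null(p)) p <- sample(0:4, 1)
  a <- random_graph(S)
  graph <- build_laplacian(a)
  region <- c(seq_len(S), sample(S, n - S, replace = TRUE))
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, if (p > 0) paste0("v", seq_len(p))))
  z <- matrix(0, n, S, dimnames = list(NULL, graph$regions))
  z[cbind(seq_len(n), region)] <- 1
  y <- stats::rnorm(n, 50, 10)
  design <- structure(list(X = x, Z = z, y = y, regions = graph$regions,
                           spec = NULL, n_s = colSums(z)),
                      class = "areal_design")
  list(design = design, graph = graph)
}

# objective function of the penalized problem (independent of the solver)
penalized_objective <- function(theta, design, graph, lambda, gamma) {
  p <- ncol(design$X); s <- ncol(design$Z)
  xt <- cbind(design$X, design$Z)
  pen <- lambda * (graph$L + gamma * diag(s))
  alpha <- theta[p + seq_len(s)]
  sum((design$y - xt %*% theta)^2) + drop(t(alpha) %*% pen %*% alpha)
}

# generic numerical minimizer of the objective (quasi-Newton with analytic
# gradient), independent of the closed-form solve path
oracle_minimize <- function(design, graph, lambda, gamma) {
  p <- ncol(design$X); s <- ncol(design$Z)
  xt <- cbind(design$X, design$Z)
  pen <- matrix(0, p + s, p + s)
  pen[p + seq_len(s), p + seq_len(s)] <- lambda * (graph$L + gamma * diag(s))
  fn <- function(th) sum((design$y - xt %*% th)^2) +
    drop(t(th) %*% pen %*% th)
  gr <- function(th) -2 * drop(crossprod(xt, design$y - xt %*% th)) +
    2 * drop(pen %*% th)
  stats::optim(rep(0, p + s), fn, gr, method = "BFGS",
               control = list(maxit = 20000, reltol = 1e-16))$par
}

# breadth-first-search connected components (oracle for graph component
# logic; independent of igraph)
bfs_components <- function(a) {
  S <- nrow(a)
  comp <- rep(NA_integer_, S)
  cur <- 0L
  for (start in seq_len(S)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(a[v, ] > 0 & is.na(comp)))
    }
  }
  comp
}

# records table for a hand-built two-variable design
toy_records <- function() {
  data.frame(
    record_id = paste0("I", 1:6),
    region_id = c("A", "A", "B", "B", "C", "C"),
    outcome = c(50, 60, 55, 45, 70, 30),
    gender = c("Male", "Female", "Female", "Male", "Female", "Female"),
    urban = c("Urban", "Urban", "Rural", "Urban", "Rural", "Urban"),
    stringsAsFactors = FALSE)
}

toy_spec <- function() {
  design_spec(list(gender = c("Male", "Female"),
                   urban = c("Rural", "Urban")),
              c(gender = "Male", urban = "Rural"))
}

# binary-edge graph on given region ids from an edge list
graph_from_edges <- function(ids, edges) {
  a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in edges) a[e[1], e[2]] <- a[e[2], e[1]] <- 1
  build_laplacian(a)
}
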