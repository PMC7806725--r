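#' Locally supervised metric learning (LSML)
#'
#' Learns a disease-specific similarity measure generalizing the
#' Mahalanobis distance,
#' \deqn{D(x_i, x_j) = \sqrt{(x_i - x_j)^T W W^T (x_i - x_j)},}
#' by average neighborhood margin maximization: for each training point the
#' spread over its nearest *different*-outcome neighbors (scatterness `S`)
#' should exceed the spread over its nearest *same*-outcome neighbors
#' (compactness `C`), so `W` is taken as the leading eigenvectors of
#' `S - C`.  Per-variable similarity weights are the column sums
#' `1^T W W^T`.
#'
#' @param X Numeric DP-by-variable matrix (or data.table with `dp_id`),
#'   *not* yet standardized; standardization parameters are estimated and
#'   stored in the model.
#' @param y Binary outcome labels (both classes present; each class must
#'   have more than `k_hom` members).
#' @param k_hom,k_het Number of nearest same- and different-label
#'   neighbors (Euclidean in standardized space; distance ties broken by
#'   row index).
#' @param d Target dimension, or `"auto"` to keep the eigenvalues of
#'   `S - C` exceeding the mean of its positive eigenvalues (Kaiser-style;
#'   at least 1).  Keeping *every* positive eigenvalue degenerates to the
#'   identity transform because sampling noise makes almost all
#'   eigenvalues positive.
#' @return Object of class `pcto_lsml`: variable names, standardization
#'   parameters, orthonormal `W` (p x d, eigenvector signs fixed so each
#'   column's largest-magnitude entry is positive), hyperparameters and
#'   eigenvalues.
#' @seealso [lsml_distance()], [variable_weights()],
#'   [write_similarity_model()]
#' @export
train_lsml <- function(X, y, k_hom = 10, k_het = 10, d = "auto") {
  X <- as_variable_matrix(X)
  y <- as.integer(as.factor(y))
  if (length(unique(y)) != 2) stop("need exactly two outcome classes")
  tab <- table(y)
  if (any(tab < k_hom + 1))
    stop("a class has fewer than k_hom + 1 = ", k_hom + 1,
         " members; reduce k_hom/k_het")
  n <- nrow(X); p <- ncol(X)
  if (n <= max(k_hom, k_het) + 1) stop("need n > max(k_hom, k_het) + 1")
  center <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Z <- scale(X, center = center, scale = scl)

  D2 <- euclidean_sq(Z)
  C <- matrix(0, p, p); S <- matrix(0, p, p)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff <- which(y != y[i])
    hom <- same[order(D2[i, same], same)][seq_len(k_hom)]
    het <- diff[order(D2[i, diff], diff)][seq_len(min(k_het, length(diff)))]
    Dh <- Z[hom, , drop = FALSE] -
      matrix(Z[i, ], length(hom), p, byrow = TRUE)
    De <- Z[het, , drop = FALSE] -
      matrix(Z[i, ], length(het), p, byrow = TRUE)
    C <- C + crossprod(Dh) / k_hom
    S <- S + crossprod(De) / k_het
  }
  M <- (S - C); M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  if (identical(d, "auto")) {
    # Kaiser-style cut: sampling noise makes nearly all eigenvalues of
    # S - C strictly positive (a flat bulk), so keeping every positive one
    # returns W W' = I (plain Euclidean, uninformative weights).  Keep the
    # eigenvalues above the mean of the positive ones instead; at least 1.
    pos <- eig$values[eig$values > 0]
    cut <- if (length(pos)) mean(pos) else -Inf
    d_use <- max(1L, sum(eig$values > cut))
  } else {
    stopifnot(d >= 1, d <= p)
    d_use <- as.integer(d)
  }
  W <- eig$vectors[, seq_len(d_use), drop = FALSE]
  W <- fix_signs(W)
  lsml_model(W, center = center, scale = scl, variables = colnames(X),
             k_hom = k_hom, k_het = k_het,
             eigenvalues = eig$values[seq_len(d_use)])
}

euclidean_sq <- function(Z) {
  g <- tcrossprod(Z)
  n2 <- diag(g)
  d2 <- outer(n2, n2, "+") - 2 * g
  d2[d2 < 0] <- 0
  d2
}

fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  W
}

#' Construct a similarity model directly from its components
#'
#' Mostly used by the loader and in tests (e.g. to pin `W` to the identity
#' and recover plain Euclidean distance).
#'
#' @param W p-by-d matrix with orthonormal columns.
#' @param center,scale Standardization vectors (length p).
#' @param variables Variable names (length p).
#' @param k_hom,k_het,eigenvalues Optional training metadata.
#' @return Object of class `pcto_lsml`.
#' @export
lsml_model <- function(W, center = rep(0, nrow(W)),
                       scale = rep(1, nrow(W)),
                       variables = paste0("V", seq_len(nrow(W))),
                       k_hom = NA_integer_, k_het = NA_integer_,
                       eigenvalues = NULL) {
  W <- as.matrix(W)
  stopifnot(nrow(W) >= 1, ncol(W) >= 1, ncol(W) <= nrow(W),
            length(center) == nrow(W), length(scale) == nrow(W),
            length(variables) == nrow(W), all(is.finite(W)))
  ortho <- crossprod(W) - diag(ncol(W))
  if (max(abs(ortho)) > 1e-8)
    stop("columns of W are not orthonormal (max deviation ",
         signif(max(abs(ortho)), 3), ")")
  structure(list(variables = variables, center = setNames(center, variables),
                 scale = setNames(scale, variables), W = W,
                 k_hom = k_hom, k_het = k_het, d = ncol(W),
                 eigenvalues = eigenvalues),
            class = "pcto_lsml")
}

#' @export
print.pcto_lsml <- function(x, ...) {
  cat("<pcto_lsml> ", length(x$variables), " variables -> ", x$d,
      " dimension(s); k_hom=", x$k_hom, ", k_het=", x$k_het, "\n", sep = "")
  invisible(x)
}

# standardize a raw vector/matrix against the model, checking coverage
standardize_to_model <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x))) {
    miss <- setdiff(model$variables, colnames(x))
    if (length(miss)) stop("missing variable(s): ",
                           paste(miss, collapse = ", "))
    x <- x[, model$variables, drop = FALSE]
  } else if (ncol(x) != length(model$variables)) {
    stop("vector length ", ncol(x), " does not match model (",
         length(model$variables), " variables)")
  }
  sweep(sweep(x, 2, model$center), 2, model$scale, "/")
}

#' Learned distance between two patient-state vectors
#'
#' Standardizes both vectors with the model's stored parameters and returns
#' `sqrt((a-b)' W W' (a-b))`.  A pseudo-metric: symmetric, non-negative,
#' zero iff the standardized difference lies in the null space of `W'`.
#'
#' @param model A `pcto_lsml`.
#' @param a,b Named numeric vectors covering the model's variables.
#' @return Non-negative scalar.
#' @export
lsml_distance <- function(model, a, b) {
  za <- standardize_to_model(model, a)
  zb <- standardize_to_model(model, b)
  proj <- (za - zb) %*% model$W
  sqrt(sum(proj^2))
}

#' Distances from one index vector to the rows of a matrix
#'
#' Vectorized form of [lsml_distance()] for cohort scoring.
#'
#' @param model A `pcto_lsml`.
#' @param index Named numeric vector (the index patient state).
#' @param X Matrix/data.table of candidate rows.
#' @return Numeric vector of distances, one per row of `X`.
#' @export
lsml_distances <- function(model, index, X) {
  X <- as_variable_matrix(X)
  zi <- standardize_to_model(model, index)
  Z <- standardize_to_model(model, X)
  proj <- sweep(Z, 2, zi) %*% model$W
  sqrt(rowSums(proj^2))
}

#' Per-variable similarity weights
#'
#' The primary weights are the column sums `1^T W W^T` (the published
#' formula; off-diagonal terms can make them negative), with
#' `diag(W W^T)` emitted as a secondary always-non-negative diagnostic.
#'
#' @param model A `pcto_lsml`.
#' @return `data.table` with `variable`, `weight` (`1^T W W^T`) and
#'   `weight_diag` (`diag(W W^T)`).
#' @export
variable_weights <- function(model) {
  M <- tcrossprod(model$W)
  data.table::data.table(variable = model$variables,
                         weight = colSums(M), weight_diag = diag(M))
}

#' Serialize / load a similarity model
#'
#' JSON with full-precision doubles, so a save/load round-trip is
#' bit-exact.  The loader re-verifies column orthonormality to 1e-8.
#'
#' @param model A `pcto_lsml`.
#' @param path File path.
#' @export
write_similarity_model <- function(model, path) {
  out <- list(variables = model$variables,
              center = hexfloat(model$center),
              scale = hexfloat(model$scale),
              k_hom = model$k_hom, k_het = model$k_het, d = model$d,
              eigenvalues = model$eigenvalues,
              W = hexfloat(as.numeric(model$W)))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# C99 hex-float encoding: lossless text representation of doubles (decimal
# JSON numbers can drop the last ulp)
hexfloat <- function(x) sprintf("%a", as.numeric(x))

#' @rdname write_similarity_model
#' @export
read_similarity_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lsml_model(W = matrix(as.numeric(x$W), nrow = length(x$variables)),
             center = as.numeric(x$center), scale = as.numeric(x$scale),
             variables = x$variables,
             k_hom = x$k_hom, k_het = x$k_het,
             eigenvalues = x$eigenvalues)
}
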