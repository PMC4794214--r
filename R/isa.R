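#' Options for the ISA optimizer
#'
#' @param epsilon Smoothing constant in the subspace log-density
#'   `G(u) = -sqrt(u + epsilon)`; keeps the gradient finite at zero energy.
#' @param step0 Initial gradient-ascent step size.
#' @param step_grow,step_shrink Multipliers applied to the step after an
#'   accepted / rejected (backtracked) iteration.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the objective change.
#' @param tol_consec Number of consecutive sub-tolerance changes required.
#' @param init `"ica"` initializes from symmetric fixed-point ICA with the
#'   components grouped into subspaces by the correlation of their
#'   energies; `"random"` uses a random orthonormalized Gaussian matrix.
#'   The smoothed subspace objective has local maxima in which a learned
#'   subspace straddles two sources of structure; the ICA start avoids
#'   them.
#' @param ica_max_iter,ica_tol Fixed-point iteration cap and convergence
#'   tolerance for the `"ica"` initialization.
#' @param seed Seed for the initialization.
#' @return A list of class `isa_options`.
#' @export
isa_options <- function(epsilon = 1e-4, step0 = 0.2, step_grow = 1.2,
                        step_shrink = 0.5, max_iter = 500, tol = 1e-7,
                        tol_consec = 5, init = c("ica", "random"),
                        ica_max_iter = 200, ica_tol = 1e-8, seed = 1L) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  init <- match.arg(init)
  structure(list(epsilon = epsilon, step0 = step0, step_grow = step_grow,
                 step_shrink = step_shrink, max_iter = as.integer(max_iter),
                 tol = tol, tol_consec = as.integer(tol_consec),
                 init = init, ica_max_iter = as.integer(ica_max_iter),
                 ica_tol = ica_tol, seed = as.integer(seed)),
            class = "isa_options")
}

# Symmetric fixed-point ICA (tanh contrast) on whitened data; returns a
# J x K matrix with orthonormal rows.
fastica_symmetric <- function(Zm, J, seed, max_iter = 200, tol = 1e-8) {
  n <- nrow(Zm)
  set.seed(seed)
  W <- sym_orth(matrix(stats::rnorm(J * ncol(Zm)), J, ncol(Zm)))
  for (it in seq_len(max_iter)) {
    S <- Zm %*% t(W)
    G <- tanh(S)
    W_new <- sym_orth(crossprod(G, Zm) / n -
                        diag(colMeans(1 - G^2), J) %*% W)
    drift <- max(1 - abs(diag(W_new %*% t(W))))
    W <- W_new
    if (drift < tol) break
  }
  W
}

# Reorder component rows into groups of size d by greedily clustering on
# the correlation of squared responses (within an ISA subspace the
# energies are strongly dependent, across subspaces nearly independent).
group_by_energy <- function(W, Zm, d) {
  E2 <- (Zm %*% t(W))^2
  C <- abs(stats::cor(E2))
  diag(C) <- -Inf
  J <- nrow(W)
  used <- rep(FALSE, J)
  order_idx <- integer(0)
  while (sum(!used) >= d) {
    Cm <- C
    Cm[used, ] <- -Inf
    Cm[, used] <- -Inf
    ij <- arrayInd(which.max(Cm), dim(Cm))
    grp <- as.integer(ij)
    used[grp] <- TRUE
    while (length(grp) < d) {
      cand <- which(!used)
      sc <- vapply(cand, function(c0) mean(C[c0, grp]), 0)
      nxt <- cand[which.max(sc)]
      grp <- c(grp, nxt)
      used[nxt] <- TRUE
    }
    order_idx <- c(order_idx, grp)
  }
  W[order_idx, , drop = FALSE]
}

as_whitened_matrix <- function(Z) {
  if (inherits(Z, "patch_matrix")) Z$data else as.matrix(Z)
}

# Per-subspace energies u_is = sum_{j in s} <w_j, z_i>^2 for all patches.
subspace_energies <- function(S, subspace_of, n_subspaces) {
  E <- matrix(0, length(subspace_of), n_subspaces)
  E[cbind(seq_along(subspace_of), subspace_of)] <- 1
  (S^2) %*% E
}

#' Subspace norm of a whitened vector
#'
#' The response of subspace `s` to a whitened vector `z`: the square root
#' of the sum of squared subunit responses, `sqrt(sum_j <w_j, z>^2)`.
#'
#' @param model An `isa_model`.
#' @param s Subspace index.
#' @param z Whitened vector.
#' @return A non-negative scalar.
#' @export
subspace_norm <- function(model, s, z) {
  stopifnot(inherits(model, "isa_model"))
  if (s < 1 || s > model$n_subspaces) stop("subspace index out of range")
  rows <- which(model$subspace_of == s)
  sqrt(sum((model$W[rows, , drop = FALSE] %*% z)^2))
}

#' ISA log-likelihood objective
#'
#' The mean over patches of `sum_s G(u_s)` with `G(u) = -sqrt(u + epsilon)`
#' and `u_s` the subspace energy.  Because the subspace density is a
#' heavy-tailed function of the norm alone, higher values mean sparser
#' subspace norms; the objective is invariant to rotations applied within a
#' subspace.
#'
#' @param model An `isa_model`, or a `J x K` matrix of components (rows) in
#'   whitened space together with `subspace_of`.
#' @param Z Whitened patch matrix (`patch_matrix` or plain matrix).
#' @param opts An `isa_options` (only `epsilon` is used).
#' @param subspace_of Component-to-subspace map when `model` is a matrix.
#' @return Scalar objective (higher is better).
#' @export
isa_objective <- function(model, Z, opts = isa_options(),
                          subspace_of = NULL) {
  if (inherits(model, "isa_model")) {
    W <- model$W
    subspace_of <- model$subspace_of
  } else {
    W <- as.matrix(model)
    if (is.null(subspace_of)) stop("subspace_of required for a raw matrix")
  }
  Z <- as_whitened_matrix(Z)
  S <- Z %*% t(W)
  U <- subspace_energies(S, subspace_of, max(subspace_of))
  -mean(rowSums(sqrt(U + opts$epsilon)))
}

#' Fit an Independent Subspace Analysis model
#'
#' Maximum-likelihood estimation of an orthonormal component matrix `W`
#' (rows = components in whitened space) whose components are grouped into
#' fixed consecutive subspaces, under the smoothed sparse subspace density
#' `G(u) = -sqrt(u + epsilon)` (Hyvarinen & Hoyer style).  Optimization is
#' full-batch gradient ascent with symmetric re-orthonormalization of `W`
#' after every step and backtracking when the objective decreases, so the
#' accepted objective trace is non-decreasing.  By default the ascent is
#' started from a symmetric fixed-point ICA solution whose components are
#' grouped into subspaces by the correlation of their energies (see
#' [isa_options()]).
#'
#' @param Z Whitened patch matrix (`patch_matrix` stage `"whitened"` or a
#'   plain matrix), rows = patches.
#' @param n_subspaces Number of subspaces.
#' @param subunits_per_subspace Components per subspace (2 for the classic
#'   complex-cell configuration).
#' @param opts An [isa_options()].
#' @param whitening Optional `whitening_transform` recorded in the model so
#'   components can be mapped back to pixel space.
#' @return An object of class `isa_model`: `W` (`J x K`, orthonormal rows),
#'   `A = t(W)` (mixing matrix in whitened space), `subspace_of`,
#'   `n_subspaces`, `subunits_per_subspace`, `whitening`, `objective`
#'   (trace of accepted values), `converged`, `iterations`, `opts`.
#' @export
fit_isa <- function(Z, n_subspaces, subunits_per_subspace = 2,
                    opts = isa_options(), whitening = NULL) {
  Zm <- as_whitened_matrix(Z)
  K <- ncol(Zm)
  J <- n_subspaces * subunits_per_subspace
  if (J > K)
    stop(sprintf("%d components exceed whitened dimension %d", J, K))
  subspace_of <- rep(seq_len(n_subspaces), each = subunits_per_subspace)
  E <- matrix(0, J, n_subspaces)
  E[cbind(seq_len(J), subspace_of)] <- 1
  n <- nrow(Zm)

  if (opts$init == "ica") {
    W <- fastica_symmetric(Zm, J, opts$seed, opts$ica_max_iter,
                           opts$ica_tol)
    W <- group_by_energy(W, Zm, subunits_per_subspace)
  } else {
    set.seed(opts$seed)
    W <- sym_orth(matrix(stats::rnorm(J * K), J, K))
  }

  obj_of <- function(W) {
    U <- subspace_energies(Zm %*% t(W), subspace_of, n_subspaces)
    -mean(rowSums(sqrt(U + opts$epsilon)))
  }

  obj <- obj_of(W)
  if (!is.finite(obj)) stop("ISA objective is not finite at initialization")
  trace <- obj
  step <- opts$step0
  consec <- 0L
  converged <- FALSE
  iter <- 0L

  while (iter < opts$max_iter) {
    iter <- iter + 1L
    S <- Zm %*% t(W)
    U <- (S^2) %*% E
    Gp <- -0.5 / sqrt(U + opts$epsilon)
    # d/dW of the objective: (2/n) t(S * Gp[, subspace]) %*% Z
    grad <- (2 / n) * crossprod(S * Gp[, subspace_of, drop = FALSE], Zm)
    accepted <- FALSE
    for (bt in 1:30) {
      W_new <- sym_orth(W + step * grad)
      obj_new <- obj_of(W_new)
      if (is.nan(obj_new)) stop("ISA objective diverged (NaN)")
      if (obj_new >= obj - 1e-15) {
        accepted <- TRUE
        break
      }
      step <- step * opts$step_shrink
    }
    if (!accepted) break # step underflow: no ascent direction left
    delta <- obj_new - obj
    W <- W_new
    obj <- obj_new
    trace <- c(trace, obj)
    step <- step * opts$step_grow
    consec <- if (abs(delta) < opts$tol) consec + 1L else 0L
    if (consec >= opts$tol_consec) {
      converged <- TRUE
      break
    }
  }

  structure(list(W = W, A = t(W), subspace_of = subspace_of,
                 n_subspaces = as.integer(n_subspaces),
                 subunits_per_subspace = as.integer(subunits_per_subspace),
                 whitening = whitening, objective = trace,
                 converged = converged, iterations = iter, opts = opts),
            class = "isa_model")
}

#' @export
print.isa_model <- function(x, ...) {
  cat(sprintf("isa_model: %d subspaces x %d subunits in %d whitened dims; %s after %d iterations (objective %.6f)\n",
              x$n_subspaces, x$subunits_per_subspace, ncol(x$W),
              if (x$converged) "converged" else "stopped",
              x$iterations, x$objective[length(x$objective)]))
  invisible(x)
}

#' Score recovery of a known subspace structure
#'
#' Compares the subspaces of a fitted `isa_model` against the ground truth
#' from [generate_isa_ground_truth_patches()].  True component directions
#' are mapped into the model's whitened space, each true subspace is
#' matched to a learned subspace (optimal assignment), and the score is the
#' mean cosine of the principal angles between matched subspace pairs
#' (1 = perfect recovery up to within-subspace rotation and permutation).
#'
#' @param model An `isa_model` fitted with a recorded `whitening`.
#' @param truth The list returned by [generate_isa_ground_truth_patches()].
#' @return A list with `score` (mean matched principal-angle cosine),
#'   `assignment` (learned subspace matched to each true subspace) and the
#'   full `score_matrix`.
#' @export
subspace_recovery <- function(model, truth) {
  stopifnot(inherits(model, "isa_model"))
  if (is.null(model$whitening))
    stop("model must carry its whitening transform")
  d <- model$subunits_per_subspace
  ns_true <- max(truth$subspace_of)
  ns_fit <- model$n_subspaces
  # true subspace directions in whitened coordinates
  Vw <- truth$components %*% t(model$whitening$forward) # J_true x K
  true_bases <- lapply(seq_len(ns_true), function(s) {
    B <- t(Vw[truth$subspace_of == s, , drop = FALSE])
    qr.Q(qr(B))
  })
  fit_bases <- lapply(seq_len(ns_fit), function(s) {
    t(model$W[model$subspace_of == s, , drop = FALSE])
  })
  score_matrix <- matrix(0, ns_true, ns_fit)
  for (i in seq_len(ns_true))
    for (j in seq_len(ns_fit))
      score_matrix[i, j] <-
        mean(svd(crossprod(true_bases[[i]], fit_bases[[j]]))$d)
  assignment <- best_assignment(score_matrix)
  score <- mean(score_matrix[cbind(seq_len(ns_true), assignment)])
  list(score = score, assignment = assignment, score_matrix = score_matrix)
}

# Maximum-total-score one-to-one assignment. Exhaustive for small problems,
# greedy otherwise (recovery benchmarks use <= 8 subspaces).
best_assignment <- function(score) {
  n <- nrow(score)
  m <- ncol(score)
  if (n <= 8 && m <= 8 && n <= m) {
    perms <- permutations_of(seq_len(m), n)
    totals <- vapply(perms, function(p) sum(score[cbind(seq_len(n), p)]), 0)
    return(perms[[which.max(totals)]])
  }
  assign <- integer(n)
  taken <- rep(FALSE, m)
  for (i in order(apply(score, 1, max), decreasing = TRUE)) {
    j <- order(score[i, ], decreasing = TRUE)
    j <- j[!taken[j]][1]
    assign[i] <- j
    taken[j] <- TRUE
  }
  assign
}

permutations_of <- function(items, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(items)) {
    rest <- permutations_of(items[-i], k - 1)
    out <- c(out, lapply(rest, function(p) c(items[i], p)))
  }
  out
}
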