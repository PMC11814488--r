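#' L1 (Lasso) penalty
#'
#' Sum of absolute values over all supplied weights, `||W||_1`.
#'
#' @param w Numeric vector/matrix or (nested) list of numerics.
#' @return Scalar penalty.
#' @export
l1_penalty <- function(w) {
  sum(abs(unlist(w, use.names = FALSE)))
}

#' Sparse-group-Lasso penalty
#'
#' `alpha * sum_g sqrt(|g|) * ||w_g||_2 + (1 - alpha) * ||w||_1`, where the
#' groups g are disjoint index sets into `w`. At `alpha = 0` this reduces
#' exactly to the L1 penalty; at `alpha = 1` it is the pure group Lasso.
#' The `sqrt(|g|)` factor puts groups of different sizes on the same
#' footing; it can be switched off.
#'
#' @param w Numeric vector (or matrix, treated as its vectorization).
#' @param groups List of integer index vectors into `w`; must be pairwise
#'   disjoint.
#' @param alpha Mixing weight in `[0, 1]` between the group term and L1.
#' @param size_scaling Multiply each group norm by `sqrt(|g|)` (default
#'   TRUE).
#' @return Scalar penalty.
#' @export
sgl_penalty <- function(w, groups, alpha = 0.5, size_scaling = TRUE) {
  stopifnot(alpha >= 0, alpha <= 1)
  w <- as.numeric(w)
  all_idx <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_idx) > 0) abort("groups overlap")
  if (length(all_idx) > 0 && (max(all_idx) > length(w) || min(all_idx) < 1)) {
    abort("group indices out of range")
  }
  grp <- sum(vapply(groups, function(g) {
    s <- if (size_scaling) sqrt(length(g)) else 1
    s * sqrt(sum(w[g]^2))
  }, numeric(1)))
  alpha * grp + (1 - alpha) * sum(abs(w))
}

# subgradient of sgl_penalty w.r.t. w (same length); 0 on a group at the
# origin and at w_i = 0 for the L1 part
sgl_subgrad <- function(w, groups, alpha = 0.5, size_scaling = TRUE) {
  w <- as.numeric(w)
  g_out <- (1 - alpha) * sign(w)
  for (g in groups) {
    nrm <- sqrt(sum(w[g]^2))
    if (nrm > 0) {
      s <- if (size_scaling) sqrt(length(g)) else 1
      g_out[g] <- g_out[g] + alpha * s * w[g] / nrm
    }
  }
  g_out
}

# --- model-level penalty ----------------------------------------------------
# reg_input penalizes the input weight matrix Wx (m x 4H); one group per
# input feature = its row across all four gate blocks. reg_hidden penalizes
# each hidden unit's outgoing weights: its row of the recurrent matrix Wh
# plus its row of the first post-recurrent dense matrix.

# list of row-index groups for an r x c matrix laid out column-major
row_groups <- function(r, c, offset = 0L) {
  lapply(seq_len(r), function(j) offset + j + (seq_len(c) - 1L) * r)
}

first_dense_name <- function(params) {
  if (length(params$dense) > 0) "dense1" else "out"
}

first_dense_W <- function(params) {
  if (length(params$dense) > 0) params$dense[[1]]$W else params$Wout
}

# penalty value R(W) for the configured regularization
model_penalty <- function(params, spec) {
  r <- 0
  if (spec$reg_input == "l1") {
    r <- r + l1_penalty(params$Wx)
  } else if (spec$reg_input == "sgl") {
    r <- r + sgl_penalty(params$Wx,
                         row_groups(nrow(params$Wx), ncol(params$Wx)),
                         alpha = spec$alpha,
                         size_scaling = spec$group_size_scaling)
  }
  if (spec$reg_hidden != "none") {
    W1 <- first_dense_W(params)
    wvec <- c(as.numeric(params$Wh), as.numeric(W1))
    if (spec$reg_hidden == "l1") {
      r <- r + l1_penalty(wvec)
    } else {
      groups <- Map(c,
                    row_groups(nrow(params$Wh), ncol(params$Wh)),
                    row_groups(nrow(W1), ncol(W1),
                               offset = length(params$Wh)))
      r <- r + sgl_penalty(wvec, groups, alpha = spec$alpha,
                           size_scaling = spec$group_size_scaling)
    }
  }
  r
}

# subgradient of model_penalty, as a params-shaped list (zero where
# unpenalized)
model_penalty_grad <- function(params, spec) {
  g <- zero_like_params(params)
  if (spec$reg_input == "l1") {
    g$Wx <- sign(params$Wx)
  } else if (spec$reg_input == "sgl") {
    gv <- sgl_subgrad(params$Wx,
                      row_groups(nrow(params$Wx), ncol(params$Wx)),
                      alpha = spec$alpha,
                      size_scaling = spec$group_size_scaling)
    g$Wx <- matrix(gv, nrow(params$Wx), ncol(params$Wx))
  }
  if (spec$reg_hidden != "none") {
    W1 <- first_dense_W(params)
    wvec <- c(as.numeric(params$Wh), as.numeric(W1))
    if (spec$reg_hidden == "l1") {
      gv <- sign(wvec)
    } else {
      groups <- Map(c,
                    row_groups(nrow(params$Wh), ncol(params$Wh)),
                    row_groups(nrow(W1), ncol(W1),
                               offset = length(params$Wh)))
      gv <- sgl_subgrad(wvec, groups, alpha = spec$alpha,
                        size_scaling = spec$group_size_scaling)
    }
    nWh <- length(params$Wh)
    g$Wh <- matrix(gv[seq_len(nWh)], nrow(params$Wh), ncol(params$Wh))
    gW1 <- matrix(gv[-seq_len(nWh)], nrow(W1), ncol(W1))
    if (first_dense_name(params) == "dense1") {
      g$dense[[1]]$W <- gW1
    } else {
      g$Wout <- gW1
    }
  }
  g
}
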