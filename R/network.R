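# Residue interaction-correlation network and Louvain community detection.
#
# Nodes are protein residues; the weight of edge (i, j) is the Pearson
# correlation of the two residues' ligand-interaction feature vectors,
# negatives clamped to zero. Communities of this network are the binding
# sites: groups of residues engaging the same ligand molecule at the same
# time.

#' Build the residue correlation network
#'
#' Each residue gets a feature vector concatenated over (ligand copy, frame,
#' repeat). With `features = "binary"` (default) the feature is the contact
#' indicator under the lower cutoff, which isolates the binding signal; with
#' `features = "distance"` it is the raw minimum distance, which also picks
#' up the ligand's global diffusion and can blur site boundaries (see the
#' package vignette).
#'
#' @param models A `system_model` or list of repeats.
#' @param cutoffs A [cutoff_pair()] (lower cutoff defines binary contacts).
#' @param features `"binary"` or `"distance"`.
#' @param n_workers Worker processes for the distance computation.
#' @return A `residue_network`: list with `weights` (symmetric matrix,
#'   entries in [0, 1], zero diagonal), `nodes` (residue serials), `degrees`
#'   and `m` (half the total edge weight).
#' @export
build_network <- function(models, cutoffs, features = c("binary", "distance"),
                          n_workers = 1L) {
  features <- match.arg(features)
  if (inherits(models, "system_model")) models <- list(models)
  if (nrow(models[[1]]$residues) < 2L) stop_ls("need at least two residues")
  if (nrow(models[[1]]$ligands) < 1L) stop_ls("need at least one ligand copy")

  dmls <- lapply(models, distance_matrix_list, n_workers = n_workers)
  nodes <- models[[1]]$residues$index
  feat <- vapply(as.character(nodes), function(rn) {
    v <- unlist(lapply(dmls, function(dml) as.numeric(t(dml[[rn]]))))
    if (features == "binary") as.numeric(v < cutoffs$lower) else v
  }, numeric(sum(vapply(models, function(m) m$n_frames, numeric(1)) *
    nrow(models[[1]]$ligands))))

  sds <- apply(feat, 2, sd)
  flat <- sds == 0
  if (any(flat)) {
    warn(sprintf(
      "%d residue feature vector(s) have zero variance; their edge weights are set to 0",
      sum(flat)
    ))
  }
  W <- matrix(0, length(nodes), length(nodes))
  ok <- which(!flat)
  if (length(ok) >= 2L) {
    cw <- suppressWarnings(cor(feat[, ok, drop = FALSE]))
    cw[cw < 0] <- 0
    W[ok, ok] <- cw
  }
  diag(W) <- 0
  dimnames(W) <- list(nodes, nodes)
  new_residue_network(W, nodes)
}

new_residue_network <- function(weights, nodes = seq_len(nrow(weights))) {
  stopifnot(isSymmetric(unname(weights)), all(weights >= 0))
  degrees <- rowSums(weights)
  structure(
    list(
      weights = weights, nodes = nodes,
      degrees = degrees, m = sum(degrees) / 2
    ),
    class = "residue_network"
  )
}

#' Construct a network from a weight matrix
#'
#' Mostly for tests and small examples: wraps a symmetric non-negative
#' weight matrix (zero diagonal) as a `residue_network`.
#'
#' @param weights Symmetric non-negative matrix.
#' @param nodes Node labels (default `1:n`).
#' @return A `residue_network`.
#' @export
residue_network <- function(weights, nodes = seq_len(nrow(weights))) {
  diag(weights) <- 0
  new_residue_network(weights, nodes)
}

#' @export
print.residue_network <- function(x, ...) {
  cat(sprintf(
    "<residue_network> %d nodes, total edge weight m = %.3f\n",
    length(x$nodes), x$m
  ))
  invisible(x)
}

#' Modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j]` on the
#' weighted graph. The all-in-one partition has `Q = 0` exactly.
#'
#' @param network A `residue_network`.
#' @param membership Integer community label per node.
#' @return The modularity `Q`.
#' @export
modularity_q <- function(network, membership) {
  if (network$m <= 0) stop_ls("modularity undefined: graph has no edges")
  stopifnot(length(membership) == nrow(network$weights))
  two_m <- 2 * network$m
  q <- 0
  for (comm in unique(membership)) {
    ix <- which(membership == comm)
    q <- q + sum(network$weights[ix, ix, drop = FALSE]) / two_m -
      (sum(network$degrees[ix]) / two_m)^2
  }
  q
}

# One Louvain local-move phase on (W, with self-loops allowed). Returns the
# membership after no single-node move improves Q. Ties in the best gain are
# broken toward the lowest community label; node order is shuffled once per
# phase from the RNG.
louvain_local_move <- function(W, node_order, min_gain = 1e-12) {
  n <- nrow(W)
  self_w <- diag(W)
  A <- W
  diag(A) <- 0
  # aggregated self-loops already hold twice the internal edge weight, so the
  # degree of (super-)node i is the plain row sum of W
  k <- rowSums(A) + self_w
  two_m <- sum(k)
  membership <- seq_len(n)
  sigma_tot <- k # per community: sum of degrees
  improved_any <- TRUE
  while (improved_any) {
    improved_any <- FALSE
    for (i in node_order) {
      ci <- membership[i]
      # weight from i to each community (excluding self-loop)
      nb <- which(A[i, ] > 0)
      if (length(nb) == 0L) next
      w_to <- tapply(A[i, nb], membership[nb], sum)
      comms <- as.integer(names(w_to))
      sigma_tot[ci] <- sigma_tot[ci] - k[i]
      w_own <- if (as.character(ci) %in% names(w_to)) w_to[[as.character(ci)]] else 0
      # gain of joining community c: w_to_c/m' - sigma_tot_c * k_i / (2m'^2) ...
      gain <- (w_to - w_own) / (two_m / 2) -
        (sigma_tot[comms] - sigma_tot[ci]) * k[i] / (two_m^2 / 2)
      best <- which(gain > min_gain)
      if (length(best) > 0L) {
        # highest gain; ties toward lowest community label
        gmax <- max(gain[best])
        cand <- comms[best][gain[best] >= gmax - 1e-15]
        new_c <- min(cand)
        if (new_c != ci) {
          membership[i] <- new_c
          sigma_tot[new_c] <- sigma_tot[new_c] + k[i]
          improved_any <- TRUE
          next
        }
      }
      sigma_tot[ci] <- sigma_tot[ci] + k[i]
    }
  }
  membership
}

#' Louvain community detection
#'
#' Repeats a local-move phase (single-node relocations while any move
#' increases modularity) and an aggregation phase (communities collapsed to
#' super-nodes, edge weights summed, within-community weight becoming a
#' self-loop) until the partition stops changing. Node order within each
#' phase is shuffled deterministically from `seed`; ties in the modularity
#' gain go to the lowest community label.
#'
#' @param network A `residue_network`.
#' @param seed Integer seed for the node-order shuffle.
#' @return A `partition`: list with `membership` (dense 1-based labels per
#'   node), `q` (modularity), and `q_trace` (modularity after each pass,
#'   non-decreasing).
#' @export
louvain_partition <- function(network, seed = 1L) {
  if (network$m <= 0) stop_ls("modularity undefined: graph has no edges")
  W <- network$weights
  n0 <- nrow(W)
  global_membership <- seq_len(n0)
  q_trace <- numeric()

  pass <- 0L
  repeat {
    pass <- pass + 1L
    n <- nrow(W)
    node_order <- with_seed(child_seed(seed, pass), sample.int(n))
    local <- louvain_local_move(W, node_order)
    # relabel densely
    local <- match(local, sort(unique(local)))
    global_membership <- local[global_membership]
    q_trace <- c(q_trace, modularity_q(
      list(weights = network$weights, degrees = network$degrees, m = network$m),
      global_membership
    ))
    n_comm <- max(local)
    if (n_comm == n) break
    # aggregate: super-node weights summed; within-community -> self-loops
    M <- matrix(0, n, n_comm)
    M[cbind(seq_len(n), local)] <- 1
    W <- t(M) %*% W %*% M
    if (n_comm == 1L) break
  }

  membership <- match(global_membership, sort(unique(global_membership)))
  structure(
    list(
      membership = membership,
      q = modularity_q(network, membership),
      q_trace = q_trace
    ),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf(
    "<partition> %d communities, Q = %.4f\n",
    length(unique(x$membership)), x$q
  ))
  invisible(x)
}
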