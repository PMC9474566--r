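#' Shared-patient networks
#'
#' A shared-patient network is an undirected binary graph over the roster's
#' physicians: adjacency `x[i, j] = 1` when the pair is tied in the given
#' channel, zero diagonal, rows/columns in roster order. The combined
#' network ties every pair that co-treated at least one patient; the
#' physician-induced channel keeps ties mediated by a documented referral;
#' the patient-induced channel keeps the remaining ties. A nonnegative
#' integer weight matrix (number of qualifying shared patients) may be
#' retained alongside the binary adjacency.
#'
#' @param adjacency binary symmetric matrix, zero diagonal.
#' @param channel one of `"combined"`, `"physician_induced"`,
#'   `"patient_induced"`.
#' @param ids character vector of physician ids in matrix order.
#' @param weights optional nonnegative integer matrix of co-treatment
#'   counts, same shape as `adjacency`.
#' @param threshold the dichotomization threshold the adjacency was derived
#'   with (weights >= threshold), when weights are retained.
#' @return an object of class `shared_patient_network` with fields
#'   `adjacency`, `weights`, `channel`, `ids`, `threshold`.
#' @export
shared_patient_network <- function(adjacency, channel, ids,
                                   weights = NULL, threshold = 1L) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (length(ids) != n) stop("ids must match adjacency dimension")
  if (!all(adjacency %in% c(0L, 1L))) stop("adjacency must be binary")
  if (any(diag(adjacency) != 0L)) stop("adjacency diagonal must be zero")
  if (!identical(adjacency, t(adjacency))) stop("adjacency must be symmetric")
  channel <- match.arg(channel,
                       c("combined", "physician_induced", "patient_induced"))
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(adjacency))) {
      stop("weights must have the same shape as adjacency")
    }
    if (any(weights < 0)) stop("weights must be nonnegative")
    dimnames(weights) <- list(ids, ids)
  }
  dimnames(adjacency) <- list(ids, ids)
  structure(list(adjacency = adjacency, weights = weights,
                 channel = channel, ids = as.character(ids),
                 threshold = as.integer(threshold)),
            class = "shared_patient_network")
}

#' @export
print.shared_patient_network <- function(x, ...) {
  s <- describe(x)
  cat(sprintf("shared_patient_network [%s]: %d physicians, %d ties, density %.3f, %d isolates\n",
              x$channel, s$n_nodes, s$edge_count, s$density, s$n_isolates))
  invisible(x)
}

#' Project a claims table onto the physician level
#'
#' Builds the weighted combined patient-sharing network: the weight of pair
#' \{i, j\} is the number of distinct patients with at least one encounter
#' at each of i and j (bipartite patient-physician incidence projected to
#' the physician mode). All roster physicians are retained as nodes, so
#' isolates are kept.
#'
#' @param claims a `claims_table` referencing only roster physicians.
#' @param roster the `physician_roster` defining node order.
#' @return a weighted `shared_patient_network` with `channel = "combined"`;
#'   the binary adjacency is the weight matrix dichotomized at 1.
#' @export
#' @examples
#' ros <- generate_roster(generator_config(n_physicians = 10, n_patients = 50))
#' cl <- generate_claims(ros$roster, ros$travel_time,
#'                       generator_config(n_physicians = 10, n_patients = 50))
#' net <- project_to_physicians(cl, ros$roster)
#' describe(net)
project_to_physicians <- function(claims, roster) {
  claims <- as_claims_table(claims, roster = roster)
  ids <- roster$physician_id
  pat <- factor(claims$patient_id)
  phy <- factor(claims$physician_id, levels = ids)
  # binary incidence: patient x physician, >=1 encounter
  B <- matrix(0L, nlevels(pat), length(ids))
  B[cbind(as.integer(pat), as.integer(phy))] <- 1L
  W <- crossprod(B)
  diag(W) <- 0L
  storage.mode(W) <- "integer"
  shared_patient_network((W >= 1L) * 1L, "combined", ids, weights = W)
}

#' Split the combined network into channels
#'
#' Classifies each patient-sharing tie by channel at the tie level. A pair
#' \{i, j\} is physician-induced when at least one shared patient has a
#' referral row connecting the two (one referred that patient to the other,
#' and the patient was treated by both); a tie is patient-induced when the
#' pair shares at least one patient but no such referral exists. The two
#' edge sets are disjoint and their union is the combined network's edge
#' set. A referral row between physicians whose patient never visited the
#' referrer creates no tie: co-treatment is required by definition.
#'
#' @inheritParams project_to_physicians
#' @return list with components `physician_induced` and `patient_induced`,
#'   each a binary `shared_patient_network`. The physician-induced weights
#'   count patients with a qualifying referral connection for the pair; the
#'   patient-induced weights are the combined co-treatment counts on its
#'   edges.
#' @export
split_channels <- function(claims, roster) {
  claims <- as_claims_table(claims, roster = roster)
  combined <- project_to_physicians(claims, roster)
  ids <- roster$physician_id
  n <- length(ids)
  idx <- function(x) match(x, ids)

  R <- matrix(0L, n, n)  # referral-connection patient counts
  ref <- claims[claims$referral_flag, , drop = FALSE]
  if (nrow(ref) > 0L) {
    # patient must also have an encounter with the referrer
    visited <- paste(claims$patient_id, claims$physician_id, sep = "\r")
    qualifies <- paste(ref$patient_id, ref$referring_physician_id,
                       sep = "\r") %in% visited
    ref <- ref[qualifies, , drop = FALSE]
    if (nrow(ref) > 0L) {
      i <- idx(ref$referring_physician_id)
      j <- idx(ref$physician_id)
      key <- unique(data.frame(p = ref$patient_id,
                               a = pmin(i, j), b = pmax(i, j)))
      tab <- table(key$a, key$b)
      cells <- cbind(as.integer(rownames(tab))[row(tab)],
                     as.integer(colnames(tab))[col(tab)])
      R[cells] <- R[cells] + as.integer(tab)
      R <- R + t(R)
    }
  }
  phys_adj <- (combined$adjacency == 1L & R >= 1L) * 1L
  pat_adj <- (combined$adjacency == 1L & R < 1L) * 1L
  Wpat <- combined$weights * pat_adj
  list(
    physician_induced = shared_patient_network(
      phys_adj, "physician_induced", ids, weights = R * phys_adj),
    patient_induced = shared_patient_network(
      pat_adj, "patient_induced", ids, weights = Wpat)
  )
}

#' Dichotomize a weighted network
#'
#' Sets `x[i, j] = 1` exactly when the co-treatment weight is at least
#' `threshold` (default 1: a tie is present when the pair shared at least
#' one patient in the observation window).
#'
#' @param net a weighted `shared_patient_network`.
#' @param threshold positive integer weight cutoff.
#' @return a binary `shared_patient_network`, weights retained.
#' @export
dichotomize <- function(net, threshold = 1L) {
  stopifnot(inherits(net, "shared_patient_network"))
  if (threshold < 1) stop("threshold must be at least 1")
  if (is.null(net$weights)) stop("dichotomize requires a weighted network")
  shared_patient_network((net$weights >= threshold) * 1L, net$channel,
                         net$ids, weights = net$weights,
                         threshold = as.integer(threshold))
}

#' Descriptive summary of a binary network
#'
#' @param net a binary `shared_patient_network`.
#' @return an object of class `network_summary`: `n_nodes`, `edge_count`,
#'   `density` (edges over n(n-1)/2), `n_isolates` (degree-zero nodes) and
#'   the `degree_sequence` in roster order.
#' @export
describe <- function(net) {
  stopifnot(inherits(net, "shared_patient_network"))
  A <- net$adjacency
  n <- nrow(A)
  deg <- rowSums(A)
  m <- sum(A) / 2
  structure(list(
    n_nodes = n,
    edge_count = as.integer(m),
    density = if (n > 1) m / (n * (n - 1) / 2) else 0,
    n_isolates = sum(deg == 0),
    degree_sequence = as.integer(deg),
    channel = net$channel
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("network summary [%s]\n", x$channel))
  cat(sprintf("  nodes: %d  ties: %d  density: %.4f  isolates: %d\n",
              x$n_nodes, x$edge_count, x$density, x$n_isolates))
  cat(sprintf("  degree: min %d, median %s, max %d\n",
              min(x$degree_sequence), format(stats::median(x$degree_sequence)),
              max(x$degree_sequence)))
  invisible(x)
}

#' Undirected triad census
#'
#' Classifies all `choose(n, 3)` node triples of a binary undirected network
#' into the four isomorphism classes of 3-node undirected graphs: empty
#' (no tie), single tie, open triad (a two-path whose endpoints are not
#' tied) and closed triad (triangle).
#'
#' @param net a binary `shared_patient_network`.
#' @return named integer vector `c(empty, one_edge, open, closed)`.
#' @export
triad_census <- function(net) {
  stopifnot(inherits(net, "shared_patient_network"))
  A <- net$adjacency
  n <- nrow(A)
  if (n < 3) stop("triad census requires at least 3 nodes")
  deg <- rowSums(A)
  m <- sum(A) / 2
  closed <- sum(diag(A %*% A %*% A)) / 6
  p2 <- sum(choose(deg, 2))           # all two-paths (center-based)
  open <- p2 - 3 * closed
  one <- m * (n - 2) - 2 * p2 + 3 * closed
  empty <- choose(n, 3) - one - open - closed
  c(empty = as.integer(empty), one_edge = as.integer(one),
    open = as.integer(open), closed = as.integer(closed))
}

#' Export a network as edge list and adjacency CSVs
#'
#' The edge list has columns `id_i`, `id_j`, `weight` (NA when the network
#' carries no weights) and `binary`; the adjacency CSV carries ids on both
#' margins.
#'
#' @param net a `shared_patient_network`.
#' @param edges_path,adjacency_path output paths (either may be `NULL` to
#'   skip).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, edges_path = NULL, adjacency_path = NULL) {
  stopifnot(inherits(net, "shared_patient_network"))
  if (!is.null(edges_path)) {
    up <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
    el <- data.frame(
      id_i = net$ids[up[, 1]], id_j = net$ids[up[, 2]],
      weight = if (is.null(net$weights)) NA_integer_ else net$weights[up],
      binary = 1L)
    write.csv(el[order(el$id_i, el$id_j), ], edges_path, row.names = FALSE)
  }
  if (!is.null(adjacency_path)) {
    write.csv(as.data.frame(net$adjacency), adjacency_path, row.names = TRUE)
  }
  invisible(net)
}

#' Summarise several channels into one table
#'
#' @param nets named list of binary `shared_patient_network` objects.
#' @param path optional CSV output path.
#' @return data frame with one row per network: channel, n, edges, density,
#'   isolates.
#' @export
summarise_channels <- function(nets, path = NULL) {
  rows <- lapply(nets, function(net) {
    s <- describe(net)
    data.frame(channel = net$channel, n = s$n_nodes, edges = s$edge_count,
               density = s$density, isolates = s$n_isolates)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
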