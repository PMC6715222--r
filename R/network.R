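# Scale-free friendship network and close-friend designation.

#' Build a scale-free network by preferential attachment
#'
#' Barabasi-Albert style growth: `m` unconnected seed nodes, then each of the
#' remaining `n - m` nodes attaches `m` edges to distinct existing nodes
#' chosen with probability proportional to current degree (the first arrival
#' necessarily links to all seeds). The edge count is therefore exactly
#' `m * (n - m)` and the graph is connected, undirected, simple.
#'
#' Degree-proportional sampling uses the standard repeated-node-list trick,
#' so construction is O(n m) and deterministic given `seed`.
#'
#' @param n number of nodes (agent ids `0 .. n-1`).
#' @param m edges added per arriving node; `1 <= m < n`.
#' @param seed integer seed.
#' @return A `social_network` list with elements `n`, `edges` (two-column
#'   integer matrix of 0-based agent ids), `closeFriends` (filled by
#'   [assign_close_friends()], initially `NULL`) and `discrepancy`.
#' @examples
#' net <- build_scale_free(100, m = 2, seed = 1)
#' nrow(net$edges)  # 2 * (100 - 2)
#' @export
build_scale_free <- function(n, m, seed) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2", call. = FALSE)
  if (is.na(m) || m < 1L || m >= n)
    stop("attachment count m must satisfy 1 <= m < n", call. = FALSE)
  set.seed(as.integer(seed))

  nEdges <- m * (n - m)
  from <- integer(nEdges)
  to <- integer(nEdges)
  bag <- integer(2L * nEdges)  # node repeated once per unit of degree
  bagLen <- 0L
  e <- 0L
  for (v in (m + 1L):n) {
    if (bagLen == 0L) {
      targets <- seq_len(m)        # first arrival links to every seed
    } else {
      targets <- unique(bag[sample.int(bagLen, m, replace = TRUE)])
      while (length(targets) < m) {
        extra <- bag[sample.int(bagLen, m - length(targets), replace = TRUE)]
        targets <- unique(c(targets, extra))
      }
    }
    idx <- e + seq_len(m)
    from[idx] <- v
    to[idx] <- targets
    e <- e + m
    bag[bagLen + seq_len(2L * m)] <- c(rep.int(v, m), targets)
    bagLen <- bagLen + 2L * m
  }
  structure(list(n = n,
                 edges = cbind(from = from - 1L, to = to - 1L),
                 closeFriends = NULL,
                 discrepancy = NULL),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network> %d nodes, %d edges", x$n, nrow(x$edges)))
  if (!is.null(x$closeFriends))
    cat(sprintf("; close friends assigned (mean |residual| = %.3f)",
                mean(x$discrepancy)))
  cat("\n")
  invisible(x)
}

# adjacency list on 1-based indices
adjacency_list <- function(net) {
  ends <- c(net$edges[, 1L], net$edges[, 2L]) + 1L
  starts <- c(net$edges[, 2L], net$edges[, 1L]) + 1L
  adj <- vector("list", net$n)
  split_adj <- split(ends, starts)
  adj[as.integer(names(split_adj))] <- split_adj
  adj
}

#' Node degrees
#'
#' @param net a `social_network`.
#' @return Integer vector of degrees, indexed by `agentId + 1`.
#' @export
network_degrees <- function(net) {
  tabulate(c(net$edges[, 1L], net$edges[, 2L]) + 1L, nbins = net$n)
}

#' Designate each agent's close friends
#'
#' Marks up to four neighbours of every agent as "close friends", chosen so
#' that the number of close friends who currently smoke cigarettes matches
#' the agent's surveyed `numSmokingFriends` whenever the neighbourhood
#' permits. Because designations are per-agent (an agent may regard a
#' neighbour as close without reciprocation), each agent's selection can be
#' made independently: take `min(numSmokingFriends, available smokers)`
#' smoking neighbours — or more if fewer than `4 - numSmokingFriends`
#' non-smoking neighbours exist — and fill the remaining slots with
#' non-smokers. This attains the per-agent optimum, so the achieved
#' mismatch `|smoking close friends - numSmokingFriends|` is the minimum
#' the topology allows; it is recorded per agent in `$discrepancy`.
#'
#' The edge set is never modified.
#'
#' @param net a `social_network` from [build_scale_free()].
#' @param profiles profile `data.frame` covering all nodes ([generate_profiles()]).
#' @param seed integer seed (which neighbours fill the slots is random).
#' @return The network with `closeFriends` (an `n x 4` integer matrix of
#'   0-based ids, `NA`-padded for degree < 4) and per-agent `discrepancy`.
#' @export
assign_close_friends <- function(net, profiles, seed) {
  if (nrow(profiles) != net$n)
    stop("profiles must cover all network nodes", call. = FALSE)
  set.seed(as.integer(seed))
  profiles <- profiles[order(profiles$agentId), ]
  smoker <- uses_cc(profiles$state)       # the survey item is cigarette-phrased
  desired <- profiles$numSmokingFriends
  adj <- adjacency_list(net)

  cf <- matrix(NA_integer_, nrow = net$n, ncol = 4L)
  disc <- integer(net$n)
  for (i in seq_len(net$n)) {
    nb <- adj[[i]]
    k <- min(4L, length(nb))
    if (k == 0L) { disc[i] <- desired[i]; next }
    sm <- nb[smoker[nb]]
    ns <- nb[!smoker[nb]]
    takeS <- min(desired[i], length(sm), k)
    takeS <- max(takeS, k - length(ns))   # forced smokers when non-smokers scarce
    takeN <- k - takeS
    chosen <- c(if (takeS > 0L) resample(sm, takeS),
                if (takeN > 0L) resample(ns, takeN))
    cf[i, seq_len(k)] <- chosen - 1L
    disc[i] <- abs(takeS - desired[i])
  }
  net$closeFriends <- cf
  net$discrepancy <- disc
  net
}

#' Export / import a network as plain text
#'
#' The edge list is written as two tab-separated integer columns; the
#' close-friend designations (if assigned) as a CSV `agentId, friend1..friend4`.
#'
#' @param net a `social_network`.
#' @param edgePath path for the edge-list file.
#' @param closeFriendsPath optional path for the close-friends CSV.
#' @return `edgePath`, invisibly.
#' @export
write_network <- function(net, edgePath, closeFriendsPath = NULL) {
  utils::write.table(net$edges, edgePath, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(closeFriendsPath) && !is.null(net$closeFriends)) {
    df <- data.frame(agentId = 0:(net$n - 1L), net$closeFriends)
    names(df) <- c("agentId", paste0("friend", 1:4))
    utils::write.csv(df, closeFriendsPath, row.names = FALSE, quote = FALSE)
  }
  invisible(edgePath)
}

#' @rdname write_network
#' @param n number of nodes (ids `0 .. n-1`); inferred as `max(id) + 1` when `NULL`.
#' @export
read_network <- function(edgePath, closeFriendsPath = NULL, n = NULL) {
  ed <- utils::read.table(edgePath, sep = "\t",
                          col.names = c("from", "to"))
  if (is.null(n)) n <- max(ed) + 1L
  net <- structure(list(n = as.integer(n),
                        edges = cbind(from = as.integer(ed$from),
                                      to = as.integer(ed$to)),
                        closeFriends = NULL, discrepancy = NULL),
                   class = "social_network")
  if (!is.null(closeFriendsPath)) {
    df <- utils::read.csv(closeFriendsPath)
    cf <- as.matrix(df[order(df$agentId), paste0("friend", 1:4)])
    dimnames(cf) <- NULL
    net$closeFriends <- matrix(as.integer(cf), nrow = net$n)
  }
  net
}
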