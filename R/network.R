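#' Build a homophilous peer network
#'
#' Random undirected graph over the women of a cohort in which edges
#' preferentially connect women of the same race/ethnicity.  Edges are
#' placed one at a time: one endpoint is drawn uniformly; with probability
#' `homophily` the partner is drawn from the same ethnicity group,
#' otherwise from the other group.  Self-edges and duplicates are redrawn,
#' so the degree distribution is approximately Poisson with mean
#' `mean_degree` and the realized same-group edge share approximates the
#' homophily parameter.  If a group is too small to supply a within-group
#' partner, the edge falls back to cross-group attachment and the count of
#' such fallbacks is recorded.
#'
#' @param cohort Cohort `data.frame` (uses `id`, `ethnicity`).
#' @param mean_degree Target mean degree (>= 0; 0 gives an empty edge set).
#' @param homophily Probability in \[0, 1\] that an edge stays within the
#'   same ethnicity group.
#' @param seed Optional integer seed.
#' @return An object of class `bf_network`: list with `edges` (2-column
#'   integer matrix of agent ids), `ids`, `group`, `mean_degree`,
#'   `homophily`, `fallback_cross` (count of forced cross-group edges).
#' @export
build_network <- function(cohort, mean_degree = 8, homophily = 0.9,
                          seed = NULL) {
  stopifnot(mean_degree >= 0, homophily >= 0, homophily <= 1)
  n <- nrow(cohort)
  ids <- cohort$id
  if (anyDuplicated(ids)) stop("cohort ids must be unique")
  group <- cohort$ethnicity
  if (!is.null(seed)) set.seed(seed)
  m_target <- round(n * mean_degree / 2)
  empty <- structure(
    list(edges = matrix(integer(), 0, 2,
                        dimnames = list(NULL, c("from", "to"))),
         ids = ids, group = group, mean_degree = mean_degree,
         homophily = homophily, fallback_cross = 0L),
    class = "bf_network")
  if (m_target == 0L || n < 2L) return(empty)

  by_group <- split(seq_len(n), group)
  fallback <- 0L
  edges <- matrix(integer(), 0, 2)
  have <- character(0)
  rounds <- 0L
  while (nrow(edges) < m_target && rounds < 50L) {
    rounds <- rounds + 1L
    need <- m_target - nrow(edges)
    a <- sample.int(n, need, replace = TRUE)
    within <- stats::runif(need) < homophily
    b <- integer(need)
    for (g in names(by_group)) {
      members <- by_group[[g]]
      sel_w <- which(within & group[a] == g)
      if (length(sel_w)) {
        if (length(members) < 2L) {       # cannot host a within-group edge
          others <- setdiff(seq_len(n), members)
          b[sel_w] <- others[sample.int(length(others), length(sel_w),
                                        replace = TRUE)]
          fallback <- fallback + length(sel_w)
        } else {
          b[sel_w] <- members[sample.int(length(members), length(sel_w),
                                         replace = TRUE)]
        }
      }
      sel_x <- which(!within & group[a] == g)
      if (length(sel_x)) {
        others <- setdiff(seq_len(n), members)
        if (length(others) == 0L) {       # single-group cohort
          b[sel_x] <- members[sample.int(length(members), length(sel_x),
                                         replace = TRUE)]
        } else {
          b[sel_x] <- others[sample.int(length(others), length(sel_x),
                                        replace = TRUE)]
        }
      }
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    ok <- lo != hi
    key <- paste(lo, hi)
    keep <- ok & !duplicated(key) & !(key %in% have)
    if (any(keep)) {
      edges <- rbind(edges, cbind(lo[keep], hi[keep]))
      have <- c(have, key[keep])
    }
  }
  if (nrow(edges) < m_target)
    message(sprintf("network: placed %d of %d requested edges",
                    nrow(edges), m_target))
  out <- empty
  out$edges <- matrix(as.integer(ids[edges]), ncol = 2,
                      dimnames = list(NULL, c("from", "to")))
  out$fallback_cross <- as.integer(fallback)
  out
}

#' Realized same-ethnicity edge share
#'
#' @param network A [build_network()] object.
#' @return Fraction of edges whose endpoints share an ethnicity group
#'   (NA for an empty network).
#' @export
same_group_share <- function(network) {
  stopifnot(inherits(network, "bf_network"))
  e <- network$edges
  if (nrow(e) == 0L) return(NA_real_)
  g <- network$group[match(as.vector(e), network$ids)]
  g <- matrix(g, ncol = 2)
  mean(g[, 1] == g[, 2])
}

#' Peer-intent fractions
#'
#' For each woman, the fraction of her network neighbours who intend to
#' breastfeed; isolated women (or all women, in an empty network) fall back
#' to the population intent fraction.
#'
#' `peer_intent_fraction()` is the single-agent accessor; it rejects
#' unknown ids.
#'
#' @param network A [build_network()] object.
#' @param intents Logical/0-1 vector of intent flags aligned with
#'   `network$ids`.
#' @param id A single agent id present in the network.
#' @return `peer_intent_fractions()`: numeric vector in \[0, 1\] aligned
#'   with `network$ids`; `peer_intent_fraction()`: a single proportion.
#' @export
peer_intent_fractions <- function(network, intents) {
  stopifnot(inherits(network, "bf_network"))
  n <- length(network$ids)
  stopifnot(length(intents) == n)
  intents <- as.numeric(intents)
  pop <- mean(intents)
  e <- network$edges
  if (nrow(e) == 0L) return(rep(pop, n))
  i <- match(e[, 1], network$ids)
  j <- match(e[, 2], network$ids)
  deg <- tabulate(c(i, j), nbins = n)
  node <- c(i, j)
  val <- c(intents[j], intents[i])
  agg <- rowsum(val, node)
  s <- numeric(n)
  s[as.integer(rownames(agg))] <- agg
  ifelse(deg > 0, s / deg, pop)
}

#' @rdname peer_intent_fractions
#' @export
peer_intent_fraction <- function(network, id, intents) {
  stopifnot(inherits(network, "bf_network"), length(id) == 1L)
  pos <- match(id, network$ids)
  if (is.na(pos)) stop("unknown agent id: ", id)
  peer_intent_fractions(network, intents)[pos]
}
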