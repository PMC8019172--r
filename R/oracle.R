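#' Exact minimum-total-distance assignment (test oracle)
#'
#' Independent reference solvers for the without-replacement assignment
#' problem: find the assignment of controls to cases (each control at
#' most once, each case at most `n_controls` slots) that minimises the
#' total distance. Used to audit the production matcher, never as the
#' production path.
#'
#' Two interchangeable backends guard against oracle bugs:
#' * `"exhaustive"` — a dynamic program over subsets of controls,
#'   exact for every cardinality; refuses instances with more than 16
#'   controls or 24 case slots.
#' * `"igraph"` — maximum-weight bipartite matching on edge weights
#'   `C - distance` with `C` large enough that maximum weight implies
#'   maximum cardinality first, minimum total distance second.
#'
#' @param candidates Data frame of feasible pairs with columns
#'   `case_id`, `control_id`, `distance` (infeasible pairs are simply
#'   absent).
#' @param n_controls Slots per case.
#' @param method `"exhaustive"` or `"igraph"`.
#' @return A list with `assignment` (data frame `case_id`,
#'   `control_id`, `distance`), `t_star` (minimum total distance at
#'   maximum cardinality), `cardinality` (the maximum number of
#'   matchable slots) and, for the exhaustive backend,
#'   `min_cost_by_cardinality` (named vector: minimum total distance
#'   achievable with exactly k slots filled, k = 0, 1, ...).
#' @export
min_total_distance_assignment <- function(candidates, n_controls = 1L,
                                          method = c("exhaustive",
                                                     "igraph")) {
  method <- match.arg(method)
  cand <- unique(candidates[, c("case_id", "control_id", "distance")])
  case_ids <- sort(unique(cand$case_id))
  control_ids <- sort(unique(cand$control_id))
  if (method == "exhaustive")
    oracle_exhaustive(cand, case_ids, control_ids, n_controls)
  else
    oracle_igraph(cand, case_ids, control_ids, n_controls)
}

oracle_exhaustive <- function(cand, case_ids, control_ids, n_controls) {
  m <- length(control_ids)
  n_slots <- length(case_ids) * n_controls
  if (m > 16 || n_slots > 24)
    stop("instance too large for the exhaustive oracle (",
         m, " controls, ", n_slots, " slots)")
  nmask <- bitwShiftL(1L, m)
  masks <- 0:(nmask - 1L)
  popcnt <- integer(nmask)
  for (b in 0:(m - 1L))
    popcnt <- popcnt + (bitwAnd(masks, bitwShiftL(1L, b)) != 0L)
  # pseudo-case list: each case replicated once per slot
  pseudo <- rep(case_ids, each = n_controls)
  feas <- lapply(case_ids, function(cid) {
    r <- cand[cand$case_id == cid, , drop = FALSE]
    list(j = match(r$control_id, control_ids), cost = r$distance)
  })
  names(feas) <- case_ids
  layers <- vector("list", length(pseudo) + 1L)
  dp <- rep(Inf, nmask)
  dp[1] <- 0
  layers[[1]] <- dp
  for (s in seq_along(pseudo)) {
    f <- feas[[pseudo[s]]]
    new <- dp  # skipping this slot is always allowed
    for (t in seq_along(f$j)) {
      bit <- bitwShiftL(1L, f$j[t] - 1L)
      with_j <- masks[bitwAnd(masks, bit) != 0L]
      cand_cost <- dp[with_j - bit + 1L] + f$cost[t]
      new[with_j + 1L] <- pmin(new[with_j + 1L], cand_cost)
    }
    dp <- new
    layers[[s + 1L]] <- dp
  }
  by_card <- vapply(0:max(popcnt), function(k) {
    v <- dp[popcnt == k]
    if (length(v) == 0) Inf else min(v)
  }, numeric(1))
  names(by_card) <- 0:max(popcnt)
  kmax <- max(which(is.finite(by_card))) - 1L
  t_star <- by_card[[kmax + 1L]]
  # backtrack an optimal assignment at maximum cardinality
  mask <- masks[popcnt == kmax][which.min(dp[popcnt == kmax])]
  rows <- list()
  for (s in rev(seq_along(pseudo))) {
    prev <- layers[[s]]
    cur_val <- layers[[s + 1L]][mask + 1L]
    if (is.finite(prev[mask + 1L]) && prev[mask + 1L] == cur_val) next
    f <- feas[[pseudo[s]]]
    for (t in seq_along(f$j)) {
      bit <- bitwShiftL(1L, f$j[t] - 1L)
      if (bitwAnd(mask, bit) == 0L) next
      if (is.finite(prev[mask - bit + 1L]) &&
          abs(prev[mask - bit + 1L] + f$cost[t] - cur_val) < 1e-9) {
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = pseudo[s], control_id = control_ids[f$j[t]],
          distance = f$cost[t], stringsAsFactors = FALSE)
        mask <- mask - bit
        break
      }
    }
  }
  assignment <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(case_id = character(0), control_id = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  list(assignment = assignment, t_star = unname(t_star),
       cardinality = kmax, min_cost_by_cardinality = by_card)
}

oracle_igraph <- function(cand, case_ids, control_ids, n_controls) {
  pseudo <- paste0(rep(case_ids, each = n_controls), "#",
                   rep(seq_len(n_controls), length(case_ids)))
  pseudo_case <- rep(case_ids, each = n_controls)
  edges <- do.call(rbind, lapply(seq_along(pseudo), function(s) {
    r <- cand[cand$case_id == pseudo_case[s], , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    data.frame(from = pseudo[s], to = paste0("ctl:", r$control_id),
               cost = r$distance, stringsAsFactors = FALSE)
  }))
  verts <- data.frame(name = c(pseudo, paste0("ctl:", control_ids)),
                      type = rep(c(FALSE, TRUE),
                                 c(length(pseudo), length(control_ids))),
                      stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0)
    return(list(assignment = data.frame(case_id = character(0),
                                        control_id = character(0),
                                        distance = numeric(0)),
                t_star = 0, cardinality = 0L))
  cmax <- max(edges$cost)
  big <- (length(pseudo) + 1) * (cmax + 1)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  mm <- igraph::max_bipartite_match(
    g, types = igraph::V(g)$type,
    weights = big - igraph::E(g)$cost)
  mate <- mm$matching[pseudo]
  hit <- !is.na(mate)
  assignment <- data.frame(
    case_id = pseudo_case[hit],
    control_id = sub("^ctl:", "", mate[hit]),
    stringsAsFactors = FALSE)
  key <- paste(assignment$case_id, assignment$control_id)
  lk <- setNames(cand$distance, paste(cand$case_id, cand$control_id))
  assignment$distance <- unname(lk[key])
  list(assignment = assignment,
       t_star = sum(assignment$distance),
       cardinality = nrow(assignment))
}
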