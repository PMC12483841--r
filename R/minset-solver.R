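#' Minimum-set prioritization problem
#'
#' Bundles everything the optimizer needs: the planning units, a per-unit
#' cost vector, named per-unit feature vectors with per-feature targets,
#' a boundary penalty with its edge factor, locked-in units, and the
#' allowed relative optimality gap. The problem solved is
#'
#' minimize  sum_i c_i x_i + b * boundary(x)
#' subject to  sum_i f_ki x_i >= t_k  for every feature k,
#'             x_i = 1 for locked-in units,  x binary,
#'
#' where `boundary(x)` is the exposed perimeter of the selected set with
#' study-area edges down-weighted by the edge factor. Targets are hard
#' constraints; the gap only bounds how far the returned objective may sit
#' above the proven lower bound.
#'
#' @param units A `planning_units` object (see [build_units()]).
#' @param cost Finite numeric vector, one cost per unit.
#' @param features Named list of per-unit numeric vectors (or a matrix with
#'   named columns), values `>= 0`; `NA` means "undefined here" and drops
#'   the unit from that feature's totals (treated as 0).
#' @param targets Either a single number or per-feature vector of
#'   *relative* targets in `[0, 1]` (fraction of each feature's total), or
#'   a named list of `list(kind = "relative"|"absolute", value = ...)`.
#' @param boundary_penalty Non-negative boundary penalty `b`.
#' @param edge_factor Multiplier in `[0, 1]` applied to study-area-edge
#'   segments of the boundary (default 0.5).
#' @param locked_in Integer indices of units forced into every solution.
#' @param gap Relative optimality gap tolerance (default 0.01).
#' @return A `problem_spec` object.
#' @export
problem_spec <- function(units, cost, features, targets = 0.2,
                         boundary_penalty = 0, edge_factor = 0.5,
                         locked_in = integer(0), gap = 0.01) {
  stopifnot(inherits(units, "planning_units"))
  n <- units$n
  cost <- as.numeric(cost)
  if (length(cost) != n || any(!is.finite(cost)))
    stop("`cost` must be finite, one value per unit", call. = FALSE)
  if (is.matrix(features)) features <- as.list(as.data.frame(features))
  if (is.null(names(features)) || any(!nzchar(names(features))))
    stop("features must be named", call. = FALSE)
  features <- lapply(features, function(f) {
    f <- as.numeric(f)
    if (length(f) != n) stop("feature length must match unit count", call. = FALSE)
    if (any(f < 0, na.rm = TRUE)) stop("feature values must be >= 0", call. = FALSE)
    f[is.na(f)] <- 0
    f
  })
  fmat <- matrix(unlist(features, use.names = FALSE), nrow = n,
                 ncol = length(features),
                 dimnames = list(NULL, names(features)))
  K <- ncol(fmat)
  if (is.numeric(targets)) {
    tv <- rep_len(as.numeric(targets), K)
    targets <- lapply(tv, function(v) list(kind = "relative", value = v))
    names(targets) <- colnames(fmat)
  }
  targets <- targets[colnames(fmat)]
  for (k in seq_len(K)) {
    tg <- targets[[k]]
    if (!tg$kind %in% c("relative", "absolute"))
      stop("target kind must be 'relative' or 'absolute'", call. = FALSE)
    if (tg$kind == "relative" && (tg$value < 0 || tg$value > 1))
      stop("relative target values must lie in [0, 1]", call. = FALSE)
  }
  if (boundary_penalty < 0) stop("boundary penalty must be >= 0", call. = FALSE)
  if (edge_factor < 0 || edge_factor > 1)
    stop("edge factor must lie in [0, 1]", call. = FALSE)
  locked_in <- sort(unique(as.integer(locked_in)))
  if (length(locked_in) && (min(locked_in) < 1L || max(locked_in) > n))
    stop("locked_in indices must reference existing units", call. = FALSE)
  if (gap < 0) stop("gap must be >= 0", call. = FALSE)
  structure(list(units = units, cost = cost, features = fmat,
                 targets = targets, boundary_penalty = boundary_penalty,
                 edge_factor = edge_factor, locked_in = locked_in, gap = gap),
            class = "problem_spec")
}

# absolute targets; a relative target against a zero-total feature is
# vacuous (t = 0) rather than infeasible, with a warning
absolute_targets <- function(spec) {
  tot <- colSums(spec$features)
  t_abs <- vapply(seq_along(spec$targets), function(k) {
    tg <- spec$targets[[k]]
    if (tg$kind == "absolute") tg$value else {
      if (tot[k] == 0 && tg$value > 0)
        warning("feature '", colnames(spec$features)[k],
                "' has zero total; its relative target is vacuous")
      tg$value * tot[k]
    }
  }, numeric(1))
  names(t_abs) <- colnames(spec$features)
  t_abs
}

#' Boundary length of a selection
#'
#' Geometric exposed-boundary accounting of a selected set: the shared
#' perimeter of selected units minus twice the internal shared edges, with
#' study-area-edge segments weighted by `edge_factor`. Equals the boundary
#' term of the optimization objective exactly.
#'
#' @param units A `planning_units` object.
#' @param selected Logical vector over units.
#' @param edge_factor Study-edge weight in `[0, 1]`.
#' @return Boundary length in map units.
#' @export
boundary_length <- function(units, selected, edge_factor = 0.5) {
  stopifnot(length(selected) == units$n)
  pstar <- (units$perimeter - units$study_edge) + edge_factor * units$study_edge
  adj <- units$adjacency
  both <- if (nrow(adj)) sum(selected[adj[, 1L]] & selected[adj[, 2L]]) else 0L
  sum(pstar[selected]) - 2 * units$shared_edge_length * both
}

#' Formulate the integer program
#'
#' Exposes the abstract program implied by a [problem_spec()]: the
#' effective linear objective coefficients `c_i + b * p*_i` (with
#' `p*_i` = shared-edge perimeter + edge_factor * study-edge length), the
#' adjacency pairs whose joint selection earns back `2 b L_ij` via linking
#' variables `y_ij <= x_i, y_ij <= x_j` (exact at the optimum for
#' `b >= 0`), the per-feature coverage rows, and the absolute targets.
#'
#' @param spec A [problem_spec()].
#' @return A list describing the program (`linear_cost`, `pstar`, `pairs`,
#'   `pair_bonus`, `features`, `targets_abs`, `locked_in`).
#' @export
formulate <- function(spec) {
  u <- spec$units
  b <- spec$boundary_penalty
  pstar <- (u$perimeter - u$study_edge) + spec$edge_factor * u$study_edge
  list(linear_cost = spec$cost + b * pstar,
       pstar = pstar,
       pairs = u$adjacency,
       pair_bonus = rep(2 * b * u$shared_edge_length, nrow(u$adjacency)),
       features = spec$features,
       targets_abs = absolute_targets(spec),
       locked_in = spec$locked_in,
       sense = "min")
}

# exact objective of a selection
selection_objective <- function(spec, selected) {
  cost_comp <- sum(spec$cost[selected])
  bnd <- boundary_length(spec$units, selected, spec$edge_factor)
  list(objective = cost_comp + spec$boundary_penalty * bnd,
       cost_component = cost_comp,
       boundary_component = spec$boundary_penalty * bnd,
       boundary_length = bnd)
}

#' Per-feature capture of a solution
#'
#' For every feature — targeted or not — the absolute amount held by the
#' selected units and the proportion of the feature's study-wide total,
#' reported exactly (captured / total). Features with zero total report a
#' proportion of 0.
#'
#' @param solution A `minset_solution` (or a logical selection vector).
#' @param features Feature matrix or named list of per-unit vectors.
#' @return Data frame with `feature`, `captured`, `total`, `proportion`.
#' @export
capture_report <- function(solution, features) {
  selected <- if (inherits(solution, "minset_solution")) solution$selected else solution
  if (!is.matrix(features)) {
    features <- vapply(features, function(f) {
      f <- as.numeric(f); f[is.na(f)] <- 0; f
    }, numeric(length(selected)))
  }
  tot <- colSums(features)
  cap <- colSums(features[selected, , drop = FALSE])
  data.frame(feature = colnames(features), captured = as.numeric(cap),
             total = as.numeric(tot),
             proportion = ifelse(tot > 0, cap / tot, 0),
             row.names = NULL)
}

new_solution <- function(spec, selected, status, bound, backend,
                         violated = character(0), nodes = NA_integer_) {
  if (status == "infeasible") {
    return(structure(list(selected = rep(FALSE, spec$units$n), objective = NA_real_,
                          cost_component = NA_real_, boundary_component = NA_real_,
                          captured = capture_report(rep(FALSE, spec$units$n),
                                                    spec$features),
                          status = "infeasible", bound = NA_real_,
                          gap_achieved = NA_real_, backend = backend,
                          violated_features = violated, nodes = nodes,
                          spec = spec),
                     class = "minset_solution"))
  }
  obj <- selection_objective(spec, selected)
  gap_a <- if (is.na(bound)) NA_real_ else
    (obj$objective - bound) / max(abs(obj$objective), 1e-12)
  structure(list(selected = selected, objective = obj$objective,
                 cost_component = obj$cost_component,
                 boundary_component = obj$boundary_component,
                 captured = capture_report(selected, spec$features),
                 status = status, bound = bound,
                 gap_achieved = gap_a, backend = backend,
                 violated_features = character(0), nodes = nodes,
                 spec = spec),
            class = "minset_solution")
}

#' @export
print.minset_solution <- function(x, ...) {
  cat(sprintf("<minset_solution> [%s] status %s", x$backend, x$status))
  if (x$status == "infeasible") {
    cat("; violated:", paste(x$violated_features, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat(sprintf("\n  %d unit(s) selected; objective %.6g (cost %.6g + boundary %.6g)\n",
              sum(x$selected), x$objective, x$cost_component, x$boundary_component))
  if (!is.na(x$bound))
    cat(sprintf("  lower bound %.6g (relative gap %.3g)\n", x$bound, x$gap_achieved))
  cat(sprintf("  capture: %s\n",
              paste(sprintf("%s %.3f", x$captured$feature, x$captured$proportion),
                    collapse = ", ")))
  invisible(x)
}

# lexicographic order on selections: the selection whose sorted index
# sequence is lexicographically smaller (prefix rule: shorter wins)
lex_less <- function(sel_a, sel_b) {
  a <- which(sel_a); b <- which(sel_b)
  m <- min(length(a), length(b))
  if (m > 0L) {
    d <- which(a[seq_len(m)] != b[seq_len(m)])
    if (length(d)) return(a[d[1L]] < b[d[1L]])
  }
  length(a) < length(b)
}

#' Solve a minimum-set problem
#'
#' Three backends: `"milp"` — branch-and-bound with Lagrangian-dual lower
#' bounds and greedy/local-search incumbents, terminating when the relative
#' gap reaches `spec$gap` (status `"within_gap"`), the tree is exhausted
#' (status `"optimal"`), or a node budget is hit (status `"feasible"`, with
#' the honestly achieved gap reported); `"exhaustive"` — complete
#' enumeration for up to 22 units, returning the true optimum with
#' deterministic tie-breaking (lexicographically smallest selection);
#' `"greedy"` — cost-effectiveness greedy with redundancy pruning (feasible
#' but unproven). All backends agree on feasibility; an infeasible problem
#' reports the violated features by name.
#'
#' @param spec A [problem_spec()].
#' @param backend `"milp"`, `"exhaustive"`, or `"greedy"`.
#' @param node_limit Branch-and-bound node budget (default scales with
#'   problem size).
#' @param time_limit Branch-and-bound wall-clock budget in seconds
#'   (default 20); on expiry the incumbent is returned with the achieved
#'   gap.
#' @return A `minset_solution`.
#' @export
solve_minset <- function(spec, backend = c("milp", "exhaustive", "greedy"),
                         node_limit = NULL, time_limit = 20) {
  backend <- match.arg(backend)
  t_abs <- withCallingHandlers(absolute_targets(spec),
                               warning = function(w) invokeRestart("muffleWarning"))
  tot <- colSums(spec$features)
  violated <- colnames(spec$features)[t_abs > tot + 1e-9]
  if (length(violated) > 0L || (spec$units$n == 0L))
    return(new_solution(spec, NULL, "infeasible", NA, backend,
                        violated = if (length(violated)) violated else
                          colnames(spec$features)[t_abs > 0]))
  switch(backend,
         exhaustive = solve_exhaustive(spec, t_abs),
         greedy = solve_greedy(spec, t_abs),
         milp = solve_bnb(spec, t_abs, node_limit, time_limit))
}

# ---- exhaustive enumeration ------------------------------------------------

solve_exhaustive <- function(spec, t_abs) {
  n <- spec$units$n
  if (n > 22L) stop("exhaustive backend limited to 22 units", call. = FALSE)
  form <- formulate(spec)
  lin <- form$linear_cost
  adj <- form$pairs
  bonus2 <- 2 * spec$boundary_penalty * spec$units$shared_edge_length
  Fm <- spec$features
  lock <- spec$locked_in
  low_bits <- min(n, 14L)
  n_low <- 2^low_bits
  n_high <- 2^(n - low_bits)
  low_pat <- matrix(FALSE, n_low, low_bits)
  cnt <- 0:(n_low - 1L)
  for (j in seq_len(low_bits)) low_pat[, j] <- bitwAnd(cnt, bitwShiftL(1L, j - 1L)) > 0L
  best_obj <- Inf; best_sel <- NULL
  for (h in 0:(n_high - 1L)) {
    X <- matrix(FALSE, n_low, n)
    X[, seq_len(low_bits)] <- low_pat
    if (n > low_bits) for (j in (low_bits + 1L):n)
      X[, j] <- bitwAnd(h, bitwShiftL(1L, j - low_bits - 1L)) > 0L
    feas <- rep(TRUE, n_low)
    if (length(lock)) for (i in lock) feas <- feas & X[, i]
    cap <- X %*% Fm
    for (k in seq_len(ncol(Fm))) feas <- feas & (cap[, k] >= t_abs[k] - 1e-9)
    if (!any(feas)) next
    obj <- as.numeric(X %*% lin)
    if (nrow(adj)) for (e in seq_len(nrow(adj)))
      obj <- obj - bonus2 * (X[, adj[e, 1L]] & X[, adj[e, 2L]])
    obj[!feas] <- Inf
    m <- min(obj)
    if (m < best_obj - 1e-12) {
      cand <- which(obj <= m + 1e-12)
      best_sel <- X[cand[1L], ]
      for (i in cand[-1L]) if (lex_less(X[i, ], best_sel)) best_sel <- X[i, ]
      best_obj <- m
    } else if (m <= best_obj + 1e-12) {
      cand <- which(obj <= m + 1e-12)
      for (i in cand) if (lex_less(X[i, ], best_sel)) best_sel <- X[i, ]
    }
  }
  if (is.null(best_sel))
    return(new_solution(spec, NULL, "infeasible", NA, "exhaustive",
                        violated = colnames(Fm)))
  new_solution(spec, best_sel, "optimal", best_obj, "exhaustive")
}

# ---- greedy ----------------------------------------------------------------

greedy_complete <- function(spec, t_abs, start_selected) {
  Fm <- spec$features; n <- spec$units$n
  selected <- start_selected
  fsum <- colSums(Fm[selected, , drop = FALSE])
  resid <- pmax(0, t_abs - fsum)
  cost_eff <- pmax(spec$cost, 1e-12)
  while (any(resid > 1e-9)) {
    gain <- rep(0, n)
    for (k in which(resid > 1e-9)) gain <- gain + pmin(Fm[, k], resid[k])
    gain[selected] <- 0
    if (max(gain) <= 0) return(NULL)         # cannot cover: infeasible
    pick <- which.max(gain / cost_eff)
    selected[pick] <- TRUE
    fsum <- fsum + Fm[pick, ]
    resid <- pmax(0, t_abs - fsum)
  }
  selected
}

prune_redundant <- function(spec, t_abs, selected) {
  Fm <- spec$features
  fsum <- colSums(Fm[selected, , drop = FALSE])
  removable <- setdiff(which(selected), spec$locked_in)
  form_cost <- spec$cost
  for (i in removable[order(form_cost[removable], decreasing = TRUE)]) {
    if (all(fsum - Fm[i, ] >= t_abs - 1e-9)) {
      selected[i] <- FALSE
      fsum <- fsum - Fm[i, ]
    }
  }
  selected
}

# deterministic flip-descent on the exact objective (used to polish
# incumbents when a boundary penalty is active)
polish_local <- function(spec, t_abs, selected, max_pass = 8L) {
  if (spec$boundary_penalty == 0) return(selected)
  u <- spec$units; n <- u$n
  b <- spec$boundary_penalty; L <- u$shared_edge_length
  pstar <- (u$perimeter - u$study_edge) + spec$edge_factor * u$study_edge
  adj <- u$adjacency
  nb <- split(c(adj[, 2L], adj[, 1L]),
              factor(c(adj[, 1L], adj[, 2L]), levels = seq_len(n)))
  Fm <- spec$features
  fsum <- colSums(Fm[selected, , drop = FALSE])
  locked <- rep(FALSE, n); locked[spec$locked_in] <- TRUE
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      sel_nb <- if (length(nb[[i]])) sum(selected[nb[[i]]]) else 0L
      if (selected[i]) {
        if (locked[i]) next
        delta <- -spec$cost[i] - b * (pstar[i] - 2 * L * sel_nb)
        if (delta < -1e-12 && all(fsum - Fm[i, ] >= t_abs - 1e-9)) {
          selected[i] <- FALSE; fsum <- fsum - Fm[i, ]; changed <- TRUE
        }
      } else {
        delta <- spec$cost[i] + b * (pstar[i] - 2 * L * sel_nb)
        if (delta < -1e-12) {
          selected[i] <- TRUE; fsum <- fsum + Fm[i, ]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  selected
}

solve_greedy <- function(spec, t_abs) {
  start <- rep(FALSE, spec$units$n)
  start[spec$locked_in] <- TRUE
  sel <- greedy_complete(spec, t_abs, start)
  if (is.null(sel))
    return(new_solution(spec, NULL, "infeasible", NA, "greedy",
                        violated = colnames(spec$features)))
  sel <- prune_redundant(spec, t_abs, sel)
  sel <- polish_local(spec, t_abs, sel)
  new_solution(spec, sel, "feasible", NA, "greedy")
}

# ---- branch and bound ------------------------------------------------------

# Valid lower bound for the restriction {x_i = 1 on F1, x_i = 0 on F0}:
# boundary earn-back of each unit is credited optimistically against every
# neighbour not excluded, which makes the per-unit coefficients
#   a~_i = c_i + b p*_i - b L #(neighbours outside F0)
# separable; the covering LP over the free units is then bounded from below
# by its Lagrangian dual, maximized by exact cyclic coordinate ascent (any
# dual point yields a valid bound).
lagrangian_dual <- function(atil, Fm, resid, sweeps = 4L) {
  K <- ncol(Fm)
  lambda <- numeric(K)
  r <- atil
  if (nrow(Fm) == 0L) return(list(bound = 0, lambda = lambda, reduced = r))
  for (s in seq_len(sweeps)) {
    for (k in seq_len(K)) {
      if (resid[k] <= 1e-12) { r <- r + lambda[k] * Fm[, k]; lambda[k] <- 0; next }
      fk <- Fm[, k]
      pos <- which(fk > 0)
      if (!length(pos)) next
      r0 <- r + lambda[k] * fk
      rho <- r0[pos] / fk[pos]
      base_active <- sum(fk[pos][rho <= 0])
      if (resid[k] - base_active <= 0) { lambda[k] <- 0; r <- r0; next }
      ppos <- rho > 0
      ord <- order(rho[ppos])
      f_s <- fk[pos][ppos][ord]; rho_s <- rho[ppos][ord]
      csum <- base_active + cumsum(f_s)
      idx <- which(csum >= resid[k])[1L]
      lambda[k] <- if (is.na(idx)) max(rho_s) else rho_s[idx]
      r <- r0 - lambda[k] * fk
    }
  }
  list(bound = sum(resid * lambda) + sum(pmin(0, r)), lambda = lambda, reduced = r)
}

node_bound <- function(spec, t_abs, status, pstar, nb_deg_free, sweeps = 8L) {
  # nb_deg_free[i]: number of rook neighbours of i not fixed to 0
  b <- spec$boundary_penalty; L <- spec$units$shared_edge_length
  atil <- spec$cost + b * pstar - b * L * nb_deg_free
  f1 <- status == 1L; free <- status == -1L
  Fm <- spec$features
  fixed_cover <- colSums(Fm[f1, , drop = FALSE])
  resid <- pmax(0, t_abs - fixed_cover)
  free_tot <- colSums(Fm[free, , drop = FALSE])
  if (any(free_tot < resid - 1e-9)) return(list(bound = Inf))
  ld <- lagrangian_dual(atil[free], Fm[free, , drop = FALSE], resid,
                        sweeps = sweeps)
  list(bound = sum(atil[f1]) + ld$bound, reduced = ld$reduced,
       free_idx = which(free), resid = resid)
}

incumbent_from_node <- function(spec, t_abs, status, reduced, free_idx) {
  sel <- status == 1L
  if (length(free_idx)) sel[free_idx[reduced < 0]] <- TRUE
  sel <- greedy_complete(spec, t_abs, sel)
  if (is.null(sel)) return(NULL)
  prune_redundant(spec, t_abs, sel)
}

solve_bnb <- function(spec, t_abs, node_limit = NULL, time_limit = 20) {
  t_start <- Sys.time()
  u <- spec$units; n <- u$n
  if (is.null(node_limit)) {
    node_limit <- if (n <= 500L) 200000L else if (n <= 2000L) 1000L else 50L
  }
  b <- spec$boundary_penalty; L <- u$shared_edge_length
  pstar <- (u$perimeter - u$study_edge) + spec$edge_factor * u$study_edge
  adj <- u$adjacency
  deg <- tabulate(c(adj[, 1L], adj[, 2L]), nbins = n)

  status0 <- rep(-1L, n)
  status0[spec$locked_in] <- 1L

  nb_deg <- function(status) {
    if (!nrow(adj) || b == 0) return(rep(0L, n))
    out0 <- status == 0L
    d <- deg
    if (any(out0)) {
      drop1 <- tabulate(adj[out0[adj[, 2L]], 1L], nbins = n)
      drop2 <- tabulate(adj[out0[adj[, 1L]], 2L], nbins = n)
      d <- d - drop1 - drop2
    }
    d
  }

  # root (extra dual sweeps: the root bound anchors the reported gap)
  root <- node_bound(spec, t_abs, status0, pstar, nb_deg(status0), sweeps = 40L)
  inc_sel <- incumbent_from_node(spec, t_abs, status0,
                                 root$reduced, root$free_idx)
  if (is.null(inc_sel))
    return(new_solution(spec, NULL, "infeasible", NA, "milp",
                        violated = colnames(spec$features)))
  inc_sel <- polish_local(spec, t_abs, inc_sel)
  inc_obj <- selection_objective(spec, inc_sel)$objective

  queue <- list(list(status = status0, bound = root$bound,
                     reduced = root$reduced, free_idx = root$free_idx))
  bounds <- root$bound
  nodes <- 1L
  status_out <- "feasible"
  lb_final <- root$bound
  big_n <- n > 1000L

  rel_gap <- function(inc, lb) (inc - lb) / max(abs(inc), 1e-12)

  while (length(queue) > 0L) {
    j <- which.min(bounds)
    nd <- queue[[j]]
    queue[[j]] <- NULL
    bounds <- bounds[-j]
    lb_global <- min(nd$bound, if (length(bounds)) min(bounds) else Inf)
    lb_final <- min(lb_global, inc_obj)
    if (rel_gap(inc_obj, lb_global) <= spec$gap + 1e-12) {
      status_out <- if (rel_gap(inc_obj, lb_global) <= 1e-9) "optimal" else "within_gap"
      break
    }
    if (nd$bound >= inc_obj) { status_out <- "optimal"; lb_final <- inc_obj; break }
    if (nodes >= node_limit ||
        as.numeric(difftime(Sys.time(), t_start, units = "secs")) > time_limit) {
      status_out <- "feasible"; break
    }
    if (length(nd$free_idx) == 0L) next
    # branch on the most critical free unit (reduced cost nearest zero
    # among units contributing to unmet coverage)
    contrib <- rowSums(spec$features[nd$free_idx, , drop = FALSE]) > 0
    cand <- if (any(contrib)) nd$free_idx[contrib] else nd$free_idx
    red <- nd$reduced[match(cand, nd$free_idx)]
    bv <- cand[which.min(abs(red))]
    for (val in c(1L, 0L)) {
      st <- nd$status
      st[bv] <- val
      nb <- node_bound(spec, t_abs, st, pstar, nb_deg(st))
      nodes <- nodes + 1L
      if (!is.finite(nb$bound) || nb$bound >= inc_obj) next
      if (length(nb$free_idx) == 0L) {
        # leaf: the bound is the exact objective of the fixed selection
        if (nb$bound < inc_obj - 1e-12) { inc_obj <- nb$bound; inc_sel <- st == 1L }
        next
      }
      if (!big_n || nodes %% 10L == 0L) {
        cand_sel <- incumbent_from_node(spec, t_abs, st, nb$reduced, nb$free_idx)
        if (!is.null(cand_sel)) {
          cand_sel <- polish_local(spec, t_abs, cand_sel,
                                   max_pass = if (big_n) 2L else 8L)
          cobj <- selection_objective(spec, cand_sel)$objective
          if (cobj < inc_obj - 1e-12) { inc_obj <- cobj; inc_sel <- cand_sel }
        }
      }
      queue[[length(queue) + 1L]] <- list(status = st, bound = nb$bound,
                                          reduced = nb$reduced,
                                          free_idx = nb$free_idx)
      bounds <- c(bounds, nb$bound)
    }
    if (length(queue) == 0L) { status_out <- "optimal"; lb_final <- inc_obj }
  }
  if (length(queue) == 0L && status_out == "feasible") {
    status_out <- "optimal"; lb_final <- inc_obj
  }
  new_solution(spec, inc_sel, status_out, lb_final, "milp", nodes = nodes)
}

#' Calibrate the boundary penalty
#'
#' Solves the `b = 0` problem, then each candidate penalty, and returns the
#' largest candidate whose pure-cost component inflates over the `b = 0`
#' optimum by at most `inflation_tolerance` (relative). Per-candidate
#' metrics — cost inflation, number of connected selected clumps, total
#' exposed boundary — are reported so the trade-off is visible. If no
#' candidate qualifies, `b = 0` is returned with a warning.
#'
#' @param spec A [problem_spec()] (its `boundary_penalty` is ignored).
#' @param candidates Ascending candidate penalties.
#' @param inflation_tolerance Allowed relative cost inflation.
#' @param backend Solver backend for the sweep.
#' @return List: `chosen_b`, `report` (one row per candidate).
#' @export
calibrate_boundary_penalty <- function(spec, candidates,
                                       inflation_tolerance = 0.1,
                                       backend = "milp") {
  stopifnot(!is.unsorted(candidates))
  base <- spec; base$boundary_penalty <- 0
  sol0 <- solve_minset(base, backend)
  if (sol0$status == "infeasible")
    stop("calibration requires the b = 0 problem to be feasible", call. = FALSE)
  cost0 <- sol0$cost_component
  rows <- lapply(candidates, function(b) {
    s <- base; s$boundary_penalty <- b
    sol <- if (b == 0) sol0 else solve_minset(s, backend)
    n_clump <- if (sum(sol$selected) == 0L) 0L else {
      adj <- spec$units$adjacency
      both <- adj[sol$selected[adj[, 1L]] & sol$selected[adj[, 2L]], , drop = FALSE]
      sel_ids <- which(sol$selected)
      if (nrow(both) == 0L) length(sel_ids) else {
        g <- igraph::graph_from_edgelist(
          matrix(match(both, sel_ids), ncol = 2L), directed = FALSE)
        if (igraph::vcount(g) < length(sel_ids))
          g <- igraph::add_vertices(g, length(sel_ids) - igraph::vcount(g))
        igraph::components(g)$no
      }
    }
    data.frame(b = b, cost_component = sol$cost_component,
               inflation = (sol$cost_component - cost0) / max(cost0, 1e-12),
               n_clumps = n_clump,
               exposed_boundary = boundary_length(spec$units, sol$selected,
                                                  edge_factor = 1),
               n_selected = sum(sol$selected))
  })
  report <- do.call(rbind, rows)
  ok <- report$inflation <= inflation_tolerance + 1e-12
  chosen <- if (any(ok)) max(report$b[ok]) else {
    warning("no candidate met the inflation tolerance; returning b = 0")
    0
  }
  list(chosen_b = chosen, report = report)
}
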