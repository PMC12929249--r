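#' Latent class models for categorical indicators
#'
#' A latent class model with `C` classes over `J` categorical items is
#' parameterized by mixing weights `pi` (the class prevalences) and
#' item-response probabilities `theta`, where `theta[[j]][l, c]` is the
#' probability that a member of class `c` shows level `l` of item `j`. Rows of
#' observations are assumed independent; items are conditionally independent
#' given class (the standard local-independence assumption).
#'
#' @param pi Numeric vector of mixing weights, length `C`, summing to 1.
#' @param theta List of `L_j x C` matrices, one per item; each column sums
#'   to 1.
#' @param item_levels Integer vector of per-item level counts `L_j`.
#' @return An object of class `lca_model`.
#' @export
lca_model <- function(pi, theta, item_levels) {
  C <- length(pi)
  stopifnot(C >= 1L, length(theta) == length(item_levels))
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1", call. = FALSE)
  if (C > 1L && (any(pi <= 0) || any(pi >= 1)))
    stop("pi entries must lie in (0,1)", call. = FALSE)
  for (j in seq_along(theta)) {
    th <- theta[[j]]
    if (!is.matrix(th) || nrow(th) != item_levels[j] || ncol(th) != C)
      stop("theta[[", j, "]] must be a ", item_levels[j], " x ", C, " matrix", call. = FALSE)
    if (any(abs(colSums(th) - 1) > 1e-9))
      stop("theta[[", j, "]] columns must sum to 1", call. = FALSE)
  }
  structure(list(C = C, pi = as.numeric(pi), theta = theta,
                 item_levels = as.integer(item_levels)),
            class = "lca_model")
}

#' @export
print.lca_model <- function(x, ...) {
  cat("<lca_model> ", x$C, " classes, ", length(x$item_levels), " items; pi = ",
      paste(sprintf("%.3f", x$pi), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# validate integer data matrix against item_levels; values are 1..L_j
.check_lca_data <- function(data, item_levels) {
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (ncol(data) != length(item_levels))
    stop("data has ", ncol(data), " columns; model expects ", length(item_levels), call. = FALSE)
  if (anyNA(data)) stop("LCA data must have no missing cells", call. = FALSE)
  for (j in seq_len(ncol(data))) {
    bad <- data[, j] < 1L | data[, j] > item_levels[j]
    if (any(bad))
      stop("item ", j, ": level outside declared set 1..", item_levels[j],
           " in rows ", paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  data
}

#' E-step: posterior responsibilities and log-likelihood
#'
#' Computes, in log space, `r[i, c] proportional to pi[c] * prod_j
#' theta[[j]][x_ij, c]` with rows normalized to 1, and the observed-data
#' log-likelihood `sum_i log sum_c pi[c] prod_j theta[[j]][x_ij, c]`.
#'
#' @param model An `lca_model`.
#' @param data Integer matrix (rows = observations) with `data[i, j]` in
#'   `1..item_levels[j]`; see [lca_data()].
#' @return List with `resp` (n x C matrix, rows summing to 1) and `logLik`.
#' @export
e_step <- function(model, data) {
  data <- .check_lca_data(data, model$item_levels)
  n <- nrow(data); C <- model$C
  lw <- matrix(rep(log(model$pi), each = n), n, C)
  for (j in seq_along(model$theta)) {
    lth <- log(model$theta[[j]])
    lw <- lw + lth[data[, j], , drop = FALSE]
  }
  m <- apply(lw, 1L, max)
  w <- exp(lw - m)
  rs <- rowSums(w)
  list(resp = w / rs, logLik = sum(m + log(rs)))
}

#' M-step: maximum-likelihood update from responsibilities
#'
#' `pi[c]` becomes the mean responsibility of class `c`; `theta[[j]][l, c]`
#' the responsibility-weighted frequency of level `l`, clipped to
#' `[clip, 1 - clip]` and renormalized to avoid absorbing boundaries and
#' `log(0)` in the next E-step.
#'
#' @param resp n x C responsibility matrix with rows summing to 1.
#' @param data Integer data matrix as in [e_step()].
#' @param item_levels Per-item level counts.
#' @param clip Lower probability bound (default `1e-6`).
#' @return An `lca_model`.
#' @export
m_step <- function(resp, data, item_levels, clip = 1e-6) {
  data <- .check_lca_data(data, item_levels)
  n <- nrow(data); C <- ncol(resp)
  tot <- colSums(resp)
  if (any(tot < 1e-8))
    stop("degenerate class (total responsibility < 1e-8): class ",
         paste(which(tot < 1e-8), collapse = ", "), call. = FALSE)
  pi <- tot / n
  theta <- vector("list", length(item_levels))
  for (j in seq_along(item_levels)) {
    L <- item_levels[j]
    th <- matrix(0, L, C)
    for (l in seq_len(L)) {
      idx <- data[, j] == l
      th[l, ] <- if (any(idx)) colSums(resp[idx, , drop = FALSE]) / tot else 0
    }
    th <- pmin(pmax(th, clip), 1 - clip)
    th <- sweep(th, 2L, colSums(th), "/")
    theta[[j]] <- th
  }
  # pi of a surviving class can only be degenerate via the tot check above;
  # keep pi strictly inside (0,1) for C > 1
  if (C > 1L) {
    pi <- pmin(pmax(pi, clip), 1 - clip)
    pi <- pi / sum(pi)
  }
  lca_model(pi, theta, item_levels)
}

#' Information criteria for a fitted latent class model
#'
#' Free-parameter count `k = (C - 1) + C * sum_j (L_j - 1)`. Criteria:
#' `AIC = -2 logLik + 2k`; `BIC = -2 logLik + k log(n)`;
#' `SABIC = -2 logLik + k log((n + 2) / 24)` (Sclove's sample-size
#' adjustment); `CAIC = -2 logLik + k (log(n) + 1)`.
#'
#' @param logLik Log-likelihood at convergence.
#' @param C Class count.
#' @param item_levels Per-item level counts.
#' @param n Observation count.
#' @return List with `logLik`, `k`, `n`, `AIC`, `BIC`, `SABIC`, `CAIC`.
#' @export
fit_statistics <- function(logLik, C, item_levels, n) {
  stopifnot(n >= 1, C >= 1)
  k <- (C - 1L) + C * sum(item_levels - 1L)
  d <- -2 * logLik
  list(logLik = logLik, k = k, n = n,
       AIC = d + 2 * k,
       BIC = d + k * log(n),
       SABIC = d + k * log((n + 2) / 24),
       CAIC = d + k * (log(n) + 1))
}

# one EM run from a given starting model; returns model, trace, convergence flag
.em_run <- function(data, model, tol, max_iter, clip) {
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- e_step(model, data)
    trace <- c(trace, es$logLik)
    if (is.finite(ll_old) &&
        abs(es$logLik - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- es$logLik
    model <- m_step(es$resp, data, model$item_levels, clip = clip)
  }
  list(model = model, logLik = trace[length(trace)], trace = trace,
       converged = converged, iterations = length(trace))
}

# random starting model: Dirichlet(1) responsibilities pushed through one M-step
.random_start <- function(data, C, item_levels, clip) {
  n <- nrow(data)
  r <- matrix(stats::rgamma(n * C, shape = 1), n, C)
  r <- r / rowSums(r)
  m_step(r, data, item_levels, clip = clip)
}

#' Fit a latent class model by EM with random restarts
#'
#' Runs `n_restarts` EM optimizations from random starting points and keeps
#' the one with the highest final log-likelihood. Convergence is declared when
#' the relative change in log-likelihood falls below `tol`. Classes are
#' relabelled in order of descending prevalence before return, so repeated
#' runs are comparable.
#'
#' @param data Integer matrix with entries in `1..L_j` (see [lca_data()]), or
#'   a `feature_matrix` (converted automatically).
#' @param C Number of latent classes (>= 1). `C = 1` is fitted in closed form
#'   (one EM iteration suffices).
#' @param n_restarts Random restarts (default 20; ignored for `C = 1`).
#' @param tol Relative log-likelihood convergence tolerance (default `1e-6`).
#' @param max_iter Maximum EM iterations per restart (default 1000).
#' @param seed Optional integer seed; identical seed gives identical results.
#' @param clip Boundary clip for theta (default `1e-6`).
#' @return An object of class `lca_fit`: `model`, `stats` (see
#'   [fit_statistics()]), `trace` (log-likelihood per iteration of the winning
#'   restart), `converged`, `seed`.
#' @export
fit_lca <- function(data, C, n_restarts = 20L, tol = 1e-6, max_iter = 1000L,
                    seed = NULL, clip = 1e-6) {
  if (inherits(data, "feature_matrix")) data <- lca_data(data)
  item_levels <- attr(data, "item_levels")
  if (is.null(item_levels)) item_levels <- apply(data, 2L, max)
  data <- .check_lca_data(data, item_levels)
  n <- nrow(data)
  if (n < C) stop("need at least as many observations (", n, ") as classes (", C, ")",
                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  n_starts <- if (C == 1L) 1L else as.integer(n_restarts)
  failures <- character(0)
  for (s in seq_len(n_starts)) {
    run <- tryCatch({
      start <- if (C == 1L) {
        m_step(matrix(1, n, 1L), data, item_levels, clip = clip)
      } else {
        .random_start(data, C, item_levels, clip)
      }
      .em_run(data, start, tol, max_iter, clip)
    }, error = function(e) e)
    if (inherits(run, "error")) { failures <- c(failures, conditionMessage(run)); next }
    if (is.null(best) || run$logLik > best$logLik) best <- run
  }
  if (is.null(best))
    stop("all ", n_starts, " restarts failed: ", failures[1L], call. = FALSE)
  # relabel classes by descending prevalence
  ord <- order(best$model$pi, decreasing = TRUE)
  model <- lca_model(best$model$pi[ord],
                     lapply(best$model$theta, function(th) th[, ord, drop = FALSE]),
                     item_levels)
  structure(list(model = model,
                 stats = fit_statistics(best$logLik, C, item_levels, n),
                 trace = best$trace, converged = best$converged,
                 iterations = best$iterations, seed = seed),
            class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<lca_fit> C=%d  logLik=%.3f  k=%d  n=%d  BIC=%.2f  %s\n",
              x$model$C, s$logLik, s$k, s$n, s$BIC,
              if (isTRUE(x$converged)) "converged" else "max_iter reached"))
  invisible(x)
}

#' Model selection over a range of class counts
#'
#' Fits every `C` in `C_range` and tabulates all four information criteria;
#' the selected class count per criterion is the argmin, ties broken toward
#' the smaller `C`.
#'
#' @inheritParams fit_lca
#' @param C_range Integer vector of class counts (default `1:10`).
#' @param criterion Criterion driving `selected_C` (default `"BIC"`).
#' @return An object of class `lca_selection`: `table` (data.frame of
#'   criteria by `C`), `selected` (named integer vector per criterion),
#'   `selected_C`, `criterion`, `fits` (list of `lca_fit`).
#' @export
select_lca <- function(data, C_range = 1:10, criterion = c("BIC", "AIC", "SABIC", "CAIC"),
                       n_restarts = 20L, tol = 1e-6, max_iter = 1000L, seed = NULL) {
  criterion <- match.arg(criterion)
  if (length(C_range) == 0L) stop("C_range must be non-empty", call. = FALSE)
  C_range <- sort(unique(as.integer(C_range)))
  if (inherits(data, "feature_matrix")) data <- lca_data(data)
  fits <- vector("list", length(C_range))
  for (i in seq_along(C_range)) {
    fits[[i]] <- tryCatch(
      fit_lca(data, C_range[i], n_restarts = n_restarts, tol = tol,
              max_iter = max_iter,
              seed = if (is.null(seed)) NULL else seed + C_range[i]),
      error = function(e) stop("fit failed at C=", C_range[i], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(C = f$model$C, logLik = f$stats$logLik, k = f$stats$k,
               AIC = f$stats$AIC, BIC = f$stats$BIC,
               SABIC = f$stats$SABIC, CAIC = f$stats$CAIC)))
  crits <- c("AIC", "BIC", "SABIC", "CAIC")
  selected <- vapply(crits, function(cr) tab$C[which.min(tab[[cr]])], integer(1))
  structure(list(table = tab, selected = selected,
                 selected_C = selected[[criterion]], criterion = criterion,
                 fits = fits),
            class = "lca_selection")
}

#' @export
print.lca_selection <- function(x, ...) {
  cat("<lca_selection> criterion =", x$criterion, "-> C =", x$selected_C, "\n")
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
plot.lca_selection <- function(x, ...) {
  tab <- x$table
  crits <- c("AIC", "BIC", "SABIC", "CAIC")
  graphics::matplot(tab$C, as.matrix(tab[, crits]), type = "b", pch = 1:4,
                    lty = 1, xlab = "number of latent classes",
                    ylab = "criterion value", ...)
  graphics::legend("topright", legend = crits, pch = 1:4, col = 1:4, lty = 1)
  invisible(x)
}

#' Maximum-posterior class assignment
#'
#' Each observation is assigned to the class with the highest posterior
#' membership probability; ties are broken toward the lower class index.
#'
#' @param model An `lca_model` (or `lca_fit`).
#' @param data Integer data matrix or `feature_matrix`.
#' @return List with `class` (integer vector) and `posterior` (n x C matrix).
#' @export
assign_classes <- function(model, data) {
  if (inherits(model, "lca_fit")) model <- model$model
  if (inherits(data, "feature_matrix")) data <- lca_data(data)
  es <- e_step(model, data)
  resp <- unname(es$resp)
  list(class = as.integer(apply(resp, 1L, which.max)), posterior = resp)
}

#' Align the classes of two models (label-switching resolution)
#'
#' Finds the permutation `p` of `model_b`'s classes minimizing the total
#' absolute difference `sum_j sum_l |theta_a[[j]][l, c] -
#' theta_b[[j]][l, p(c)]|`. The search over permutations is exact
#' (branch-and-bound over a precomputed pairwise cost matrix).
#'
#' @param model_a,model_b Two `lca_model`s (or `lca_fit`s) with the same `C`
#'   and `item_levels`.
#' @return Integer permutation `p` such that class `c` of `model_a`
#'   corresponds to class `p[c]` of `model_b`.
#' @export
align_classes <- function(model_a, model_b) {
  if (inherits(model_a, "lca_fit")) model_a <- model_a$model
  if (inherits(model_b, "lca_fit")) model_b <- model_b$model
  if (model_a$C != model_b$C || !identical(model_a$item_levels, model_b$item_levels))
    stop("models must share C and item_levels", call. = FALSE)
  C <- model_a$C
  cost <- matrix(0, C, C)
  for (j in seq_along(model_a$theta))
    for (a in seq_len(C)) for (b in seq_len(C))
      cost[a, b] <- cost[a, b] + sum(abs(model_a$theta[[j]][, a] - model_b$theta[[j]][, b]))
  .assignment_min(cost)
}

# exact minimum-cost assignment by depth-first search with bound pruning;
# rows are assigned in order, `best` tracks the incumbent total cost
.assignment_min <- function(cost) {
  C <- nrow(cost)
  lb_tail <- rev(cumsum(rev(apply(cost, 1L, min))))  # lower bound for rows r..C
  best_perm <- seq_len(C)
  best_cost <- sum(cost[cbind(seq_len(C), best_perm)])
  perm <- integer(C)
  used <- logical(C)
  rec <- function(r, acc) {
    if (r > C) {
      if (acc < best_cost) { best_cost <<- acc; best_perm <<- perm[seq_len(C)] }
      return(invisible())
    }
    if (acc + lb_tail[r] >= best_cost) return(invisible())
    ord <- order(cost[r, ])
    for (b in ord) {
      if (used[b]) next
      used[b] <<- TRUE; perm[r] <<- b
      rec(r + 1L, acc + cost[r, b])
      used[b] <<- FALSE
    }
  }
  rec(1L, 0)
  best_perm
}

#' Serialize / load a latent class model as JSON
#'
#' @param fit An `lca_fit` or `lca_model`.
#' @param path Output path.
#' @export
write_lca_model <- function(fit, path) {
  model <- if (inherits(fit, "lca_fit")) fit$model else fit
  meta <- if (inherits(fit, "lca_fit"))
    list(stats = fit$stats, converged = fit$converged, seed = fit$seed) else NULL
  # theta stored as per-item {L, values} with column-major values, which
  # survives JSON round-trips without shape-dependent simplification
  obj <- list(C = model$C, pi = model$pi,
              theta = lapply(model$theta, function(th)
                list(L = nrow(th), values = as.numeric(th))),
              item_levels = model$item_levels, meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lca_model
#' @export
read_lca_model <- function(path) {
  obj <- jsonlite::read_json(path)  # no simplification; rebuild shapes by hand
  theta <- lapply(obj$theta, function(e)
    matrix(as.numeric(unlist(e$values)), nrow = as.integer(e$L)))
  lca_model(as.numeric(unlist(obj$pi)), theta, as.integer(unlist(obj$item_levels)))
}
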