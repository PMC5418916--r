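#' Assign centripetal and centrifugal branch orders
#'
#' Centripetal order counts from the tips with the Strahler convention:
#' every tip has order 1; a parent takes the maximum of its children's
#' orders, plus one when that maximum is attained by at least two children.
#' The trunk therefore carries the maximum order, and on an equally
#' dichotomous tree the order increments at every junction. This is the
#' ordering under which the bifurcation ratio of a geometric branch-count
#' series is meaningful (R_b = 2 for equal dichotomy).
#' Centrifugal order counts the other way: the trunk is 1 and each child
#' adds one, so a tip's centrifugal order is its generation count.
#'
#' @param x a `villous_tree` or a data frame with integer columns `id` and
#'   `parent` (`NA` parent marks a root).
#' @return `x` with columns `centripetal` and `centrifugal` added to the
#'   branch table.
#' @export
#' @examples
#' tb <- tibble::tibble(id = 1:3, parent = c(NA, 1L, 1L))
#' assign_orders(tb)
assign_orders <- function(x) {
  if (inherits(x, "villous_tree")) {
    x$branches <- assign_orders(x$branches)
    return(x)
  }
  branches <- x
  n <- nrow(branches)
  id <- branches$id
  parent <- branches$parent
  pos <- match(parent, id)
  if (anyNA(pos[!is.na(parent)])) stop("parent ids not found in branch table")

  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(pos[i])) children[[pos[i]]] <- c(children[[pos[i]]], i)
  }
  roots <- which(is.na(parent))
  if (length(roots) == 0) stop("no root branch (all parents set): cyclic graph?")

  # breadth-first order from the roots; also detects cycles/disconnection
  bfs <- integer(0)
  frontier <- roots
  centrifugal <- rep(NA_integer_, n)
  centrifugal[roots] <- 1L
  while (length(frontier)) {
    bfs <- c(bfs, frontier)
    nxt <- integer(0)
    for (f in frontier) {
      ch <- children[[f]]
      centrifugal[ch] <- centrifugal[f] + 1L
      nxt <- c(nxt, ch)
    }
    frontier <- nxt
  }
  if (length(bfs) != n) stop("branch graph is not a forest reachable from its roots")

  centripetal <- rep(1L, n)
  for (i in rev(bfs)) {
    ch <- children[[i]]
    if (length(ch)) {
      m <- max(centripetal[ch])
      centripetal[i] <- if (sum(centripetal[ch] == m) >= 2L) m + 1L else m
    }
  }
  branches$centripetal <- centripetal
  branches$centrifugal <- centrifugal
  branches
}

#' Count branches per centripetal order
#'
#' @param branches a branch table with a `centripetal` column (see
#'   [assign_orders()]); optionally filtered by `tier` first.
#' @param tier if given, restrict to branches of this tier.
#' @return A tibble with columns `u` (centripetal order) and `n` (count).
#' @export
order_counts <- function(branches, tier = NULL) {
  if (inherits(branches, "villous_tree")) branches <- branches$branches
  if (!is.null(tier)) branches <- branches[branches$tier %in% tier, ]
  if (!"centripetal" %in% names(branches)) branches <- assign_orders(branches)
  dplyr::count(branches, u = .data$centripetal, name = "n")
}

#' Estimate the bifurcation ratio R_b
#'
#' Under constant branching ratio the branch counts form a geometric series
#' `N_u = R_b^(u_max - u)`, i.e. `ln N_u = (u_max - u) ln R_b`. `R_b` is
#' fitted by least squares of `ln N_u` on `(u_max - u)` through the origin
#' (the model has no intercept). `R_b = 2` means equal dichotomy.
#'
#' @param counts a data frame with columns `u` and `n`, or a numeric vector
#'   of counts named (or ordered) by centripetal order `1..u_max`.
#' @return An object of class `rb_fit` with components `r_b`, `log_r_b`,
#'   `data`, `fitted`, `r_squared`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' estimate_bifurcation_ratio(c(8, 4, 2, 1))   # R_b = 2
estimate_bifurcation_ratio <- function(counts) {
  if (is.data.frame(counts)) {
    u <- counts$u
    n <- counts$n
  } else {
    n <- as.numeric(counts)
    u <- if (!is.null(names(counts))) as.numeric(names(counts)) else seq_along(n)
  }
  keep <- n >= 1
  u <- u[keep]
  n <- n[keep]
  if (length(unique(u)) < 2) {
    stop("R_b is undefined for a single centripetal order")
  }
  u_max <- max(u)
  x <- u_max - u
  y <- log(n)
  slope <- sum(x * y) / sum(x * x)
  fitted <- slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      r_b = exp(slope),
      log_r_b = slope,
      u_max = u_max,
      data = tibble::tibble(u = u, n = n, x = x, log_n = y, fitted = fitted),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    ),
    class = "rb_fit"
  )
}

#' @export
print.rb_fit <- function(x, ...) {
  cat("Bifurcation-ratio fit: R_b =", format(x$r_b, digits = 4),
      " (u_max =", x$u_max, ")\n")
  invisible(x)
}

#' @rdname estimate_bifurcation_ratio
#' @param x an `rb_fit` object.
#' @param ... unused.
#' @export
tidy.rb_fit <- function(x, ...) {
  tibble::tibble(term = c("log_r_b", "r_b"),
                 estimate = c(x$log_r_b, x$r_b))
}

#' @rdname estimate_bifurcation_ratio
#' @export
glance.rb_fit <- function(x, ...) {
  tibble::tibble(r_b = x$r_b, u_max = x$u_max,
                 n_orders = nrow(x$data), r.squared = x$r_squared)
}
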