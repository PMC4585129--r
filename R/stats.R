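# Group-comparison statistics used on the activity and growth readouts:
# Welch's unequal-variance t-test and a compact letter display over the
# pairwise significance structure.

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p-value, via [stats::t.test()]. The degenerate case of two
#' constant groups with equal means returns `t = 0, p = 1` by convention;
#' constant groups with different means are a degenerate-variance error.
#'
#' @param a,b Numeric vectors of replicate values (each length >= 2).
#' @return A list with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t(c(10, 12, 14), c(20, 22, 24))
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    stop("degenerate variance: both groups constant with different means",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Pairwise Welch p-value matrix
#'
#' @param groups A named list of numeric replicate vectors.
#' @return A symmetric matrix of two-sided Welch p-values with unit
#'   diagonal.
#' @export
pairwise_welch <- function(groups) {
  n <- length(groups)
  p <- matrix(1, n, n, dimnames = list(names(groups), names(groups)))
  if (n < 2L) return(p)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pij <- welch_t(groups[[i]], groups[[j]])$p
    p[i, j] <- pij; p[j, i] <- pij
  }
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns letters so that two conditions share at least one letter if and
#' only if they are not significantly different (p > alpha). Uses the
#' insert-and-absorb sweep: start from one all-inclusive group; for every
#' significant pair, split any group containing both; absorb subset groups;
#' label the surviving groups alphabetically in order of their first member.
#' Deterministic given the input order.
#'
#' @param pairwise_p Symmetric matrix of p-values with unit diagonal.
#' @param alpha Significance level (pairs with p <= alpha are "different").
#' @return Character vector of letter labels, one per condition, named after
#'   the matrix rows.
#' @export
#' @examples
#' p <- matrix(c(1, .8, .01, .8, 1, .6, .01, .6, 1), 3, 3)
#' letter_groups(p)  # "a" "ab" "b"
letter_groups <- function(pairwise_p, alpha = 0.05) {
  p <- as.matrix(pairwise_p)
  n <- nrow(p)
  if (n != ncol(p) || any(abs(p - t(p)) > 1e-12))
    stop("pairwise_p must be a square symmetric matrix", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  if (n == 0L) return(character(0))
  groups <- list(seq_len(n))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (p[i, j] > alpha) next
    # significant pair: no group may keep both members
    new_groups <- list()
    for (g in groups) {
      if (i %in% g && j %in% g) {
        new_groups <- c(new_groups, list(setdiff(g, i)), list(setdiff(g, j)))
      } else new_groups <- c(new_groups, list(g))
    }
    # absorb groups that are subsets of another
    keep <- rep(TRUE, length(new_groups))
    for (a_ in seq_along(new_groups)) for (b_ in seq_along(new_groups)) {
      if (a_ != b_ && keep[a_] && keep[b_] &&
          all(new_groups[[a_]] %in% new_groups[[b_]]) &&
          !(all(new_groups[[b_]] %in% new_groups[[a_]]) && a_ < b_))
        keep[a_] <- FALSE
    }
    groups <- new_groups[keep]
  }
  groups <- groups[order(vapply(groups, min, 1L))]
  labels <- rep("", n)
  for (k in seq_along(groups)) {
    for (m in groups[[k]]) labels[m] <- paste0(labels[m], letters[k])
  }
  names(labels) <- rownames(p)
  labels
}
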