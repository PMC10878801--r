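#' Mann-Whitney U test with an exact small-sample null
#'
#' `U` counts pairs with `a_i > b_j`, ties counting one half (i.e. the
#' midrank form `U = R_a - n_a (n_a + 1) / 2`). The two-sided p-value
#' doubles the smaller one-sided tail (observed value included), capped
#' at 1. Null distribution:
#' \itemize{
#'   \item `n_a + n_b <= 14`: exact, by full enumeration of all label
#'     assignments of the pooled values (ties handled exactly);
#'   \item `14 < n_a + n_b <= 40`, or ties present: Monte-Carlo
#'     permutation with `n_perm` draws (add-one tail estimate), using
#'     the current R RNG stream, so results are reproducible under
#'     `set.seed()`;
#'   \item otherwise: tie-corrected normal approximation with
#'     continuity correction.
#' }
#'
#' @param a,b numeric samples (each non-empty).
#' @param n_perm Monte-Carlo permutation count (default `1e5`).
#' @param method `"auto"` (the size/tie policy above) or an explicit
#'   null-distribution method, mainly for cross-validating the methods
#'   against each other.
#' @return Object of class `pg_mwu`: one-row data frame with `n_a`,
#'   `n_b`, `U`, `p_two_sided`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b, n_perm = 1e5,
                           method = c("auto", "exact", "permutation",
                                      "normal_approx")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    insufficient_data_error("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) config_error("samples must not contain NA")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (method == "auto") {
    method <- if (n <= 14L) "exact"
      else if (n <= 40L || ties) "permutation"
      else "normal_approx"
  }

  if (method == "exact") {
    idx <- combn(n, na)
    u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p_one <- min(mean(u_all <= U + 1e-9), mean(u_all >= U - 1e-9))
    p <- min(1, 2 * p_one)
  } else if (method == "permutation") {
    # sorted ranks: the sampled null is then invariant to sample order
    cnt <- mw_perm_tail_cpp(sort(r), na, as.integer(n_perm), U)
    p_one <- min((1 + cnt[1]) / (n_perm + 1), (1 + cnt[2]) / (n_perm + 1))
    p <- min(1, 2 * p_one)
  } else {
    mu <- na * nb / 2
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - tie_term)
    z <- (abs(U - mu) - 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-max(0, z)))
  }
  out <- data.frame(n_a = na, n_b = nb, U = U, p_two_sided = p,
                    method = method)
  class(out) <- c("pg_mwu", "data.frame")
  out
}

#' Compare forward vs backward groups for every metric and condition
#'
#' One Mann-Whitney comparison per kinematic metric per gating
#' condition, contrasting subjects shown the forward-moving stimulus
#' against subjects shown the backward-moving stimulus.
#'
#' @param trials a trial table as returned in
#'   [run_experiment()]`$trials`: per-subject rows with `condition`,
#'   `direction` and metric columns.
#' @param metrics which metric columns to compare.
#' @param conditions which conditions to include (default: all present).
#' @param correct `"none"` (per-panel testing) or `"holm"` to adjust the
#'   p-values across the emitted comparisons.
#' @param n_perm passed to [mann_whitney_u()].
#' @return Object of class `pg_comparisons`: data frame with `metric`,
#'   `condition`, `n_fwd`, `n_bwd`, `U`, `p`, `method`.
#' @export
compare_all <- function(trials,
                        metrics = c("walking_fraction", "mean_pause_duration",
                                    "total_side_motion", "total_distance"),
                        conditions = NULL,
                        correct = c("none", "holm"),
                        n_perm = 1e5) {
  correct <- match.arg(correct)
  if (is.null(conditions)) conditions <- unique(trials$condition)
  missing_m <- setdiff(metrics, names(trials))
  if (length(missing_m))
    config_error("trial table lacks metric column(s): %s",
                 paste(missing_m, collapse = ", "))
  rows <- list()
  for (cond in conditions) {
    fwd <- trials[trials$condition == cond & trials$direction == "FORWARD", ]
    bwd <- trials[trials$condition == cond & trials$direction == "BACKWARD", ]
    if (nrow(fwd) == 0L)
      pg_stop("pg_missing_cell_error", "no subjects in cell %s x FORWARD", cond)
    if (nrow(bwd) == 0L)
      pg_stop("pg_missing_cell_error", "no subjects in cell %s x BACKWARD", cond)
    for (m in metrics) {
      mw <- mann_whitney_u(fwd[[m]], bwd[[m]], n_perm = n_perm)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, condition = cond,
        n_fwd = mw$n_a, n_bwd = mw$n_b,
        U = mw$U, p = mw$p_two_sided, method = mw$method)
    }
  }
  out <- do.call(rbind, rows)
  if (correct == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  class(out) <- c("pg_comparisons", "data.frame")
  out
}

#' Write a comparison table to CSV
#' @param comparisons a `pg_comparisons`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(comparisons, path) {
  write.csv(as.data.frame(comparisons), path, row.names = FALSE)
  invisible(path)
}
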