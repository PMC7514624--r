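# Subset-keyed NRH cache used by the greedy search and the checkers.
# Caching is a pure speed optimization: keys are sorted index sets, so the
# cached value is exactly what nrh() would return.
nrh_cached <- function(data, delta, decision, cache) {
  function(B) {
    key <- paste0("s", paste(sort(B), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- nrh(data, B, delta, decision)
      cache[[key]] <- val
    }
    val
  }
}

#' Core attributes of a decision table
#'
#' An attribute is a core attribute when removing it alone from the full set
#' strictly decreases NRH, i.e. its internal significance within `C` exceeds
#' `epsilon` (a small tolerance absorbing floating-point noise in the
#' "strictly positive" test).
#'
#' @param data A decision table or data frame.
#' @param delta Neighborhood radius in `[0, 1]`.
#' @param epsilon Tolerance for "significance > 0" (default `1e-10`).
#' @param decision Decision column name.
#' @return A tibble with one row per core attribute in attribute order:
#'   `attribute`, `sig_inner`.
#' @export
core_attributes <- function(data, delta, epsilon = 1e-10, decision = NULL) {
  ctx <- dt_context(data, decision)
  full <- seq_len(ctx$m)
  nrh_full <- nrh(data, full, delta, decision)
  sig <- vapply(full, function(a) {
    nrh_full - nrh(data, setdiff(full, a), delta, decision)
  }, numeric(1))
  keep <- sig > epsilon
  tibble::tibble(attribute = ctx$attrs[full[keep]], sig_inner = sig[keep])
}

#' ARNRJE: greedy attribute reduction by neighborhood roughness joint entropy
#'
#' Heuristic reduct search. Starting from the attribute core, candidates are
#' added greedily, each step picking the candidate whose addition maximizes
#' NRH (ties broken by the earlier attribute), until NRH of the subset
#' reaches NRH of the full set within `epsilon`. A completeness pass then
#' walks the subset in addition order and drops any attribute whose removal
#' does not lower NRH below the full-set value, so every retained attribute
#' is necessary.
#'
#' @inheritParams core_attributes
#' @return An object of class `reduct_trace` with fields `reduct` (attribute
#'   names), `core` (tibble from [core_attributes()]), `additions` (tibble
#'   `attribute`, `nrh` after each greedy addition), `removals` (character),
#'   `nrh_full`, `nrh_reduct`, `delta`, `epsilon`, `n_attributes`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' dt <- simulate_decision_table(20, 2, n_irrelevant = 2, seed = 2)
#' arnrje(dt, delta = 0.2)
#' @export
arnrje <- function(data, delta, epsilon = 1e-10, decision = NULL) {
  stopifnot(epsilon > 0)
  ctx <- dt_context(data, decision)
  full <- seq_len(ctx$m)
  cache <- new.env(parent = emptyenv())
  NRH <- nrh_cached(data, delta, decision, cache)
  nrh_full <- NRH(full)

  sig <- vapply(full, function(a) nrh_full - NRH(setdiff(full, a)), numeric(1))
  core_idx <- full[sig > epsilon]
  core <- tibble::tibble(attribute = ctx$attrs[core_idx], sig_inner = sig[sig > epsilon])

  B <- core_idx
  R <- setdiff(full, B)
  additions <- list()
  while (NRH(B) < nrh_full - epsilon && length(R) > 0L) {
    gains <- vapply(R, function(a) NRH(c(B, a)), numeric(1))
    best <- R[which.max(gains)]  # which.max takes the first maximum; R is in
    B <- c(B, best)              # ascending index order, so ties pick the front
    R <- setdiff(R, best)
    additions[[length(additions) + 1L]] <-
      tibble::tibble(attribute = ctx$attrs[best], nrh = NRH(B))
  }
  additions <- if (length(additions)) dplyr::bind_rows(additions) else
    tibble::tibble(attribute = character(), nrh = numeric())

  # completeness pass: drop attributes (in addition order) whose removal
  # keeps NRH at the full-set value
  removals <- character()
  for (a in B) {
    if (NRH(setdiff(B, a)) >= nrh_full - epsilon) {
      B <- setdiff(B, a)
      removals <- c(removals, ctx$attrs[a])
    }
  }

  structure(
    list(reduct = ctx$attrs[sort(B)],
         core = core,
         nrh_core = NRH(core_idx),
         additions = additions,
         removals = removals,
         nrh_full = nrh_full,
         nrh_reduct = NRH(B),
         delta = delta,
         epsilon = epsilon,
         n_attributes = ctx$m,
         attribute_names = ctx$attrs),
    class = "reduct_trace"
  )
}

#' @export
print.reduct_trace <- function(x, ...) {
  cat("# ARNRJE reduct trace (delta = ", x$delta, ")\n", sep = "")
  cat("  NRH(full set)  : ", format(x$nrh_full, digits = 6), " bits over ",
      x$n_attributes, " attributes\n", sep = "")
  cat("  core           : {", paste(x$core$attribute, collapse = ", "), "}\n", sep = "")
  if (nrow(x$additions)) {
    cat("  greedy adds    : ",
        paste(sprintf("%s (NRH=%.4f)", x$additions$attribute, x$additions$nrh),
              collapse = ", "), "\n", sep = "")
  }
  if (length(x$removals)) {
    cat("  pruned         : {", paste(x$removals, collapse = ", "), "}\n", sep = "")
  }
  cat("  reduct         : {", paste(x$reduct, collapse = ", "), "} (",
      length(x$reduct), "/", x$n_attributes, " attributes, reduction rate ",
      format(reduction_rate(x$n_attributes, length(x$reduct)), digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' @describeIn arnrje One row per search event (core inclusion, greedy
#'   addition, pruning removal) with the NRH trajectory.
#' @param x A `reduct_trace`.
#' @param ... Unused.
#' @method tidy reduct_trace
#' @export
tidy.reduct_trace <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(step = "core", attribute = x$core$attribute,
                   sig_inner = x$core$sig_inner, nrh = NA_real_),
    tibble::tibble(step = "add", attribute = x$additions$attribute,
                   sig_inner = NA_real_, nrh = x$additions$nrh),
    tibble::tibble(step = "remove", attribute = x$removals,
                   sig_inner = NA_real_, nrh = NA_real_)
  )
}

#' @describeIn arnrje One-row summary of the search outcome.
#' @method glance reduct_trace
#' @export
glance.reduct_trace <- function(x, ...) {
  tibble::tibble(
    delta = x$delta,
    epsilon = x$epsilon,
    n_attributes = x$n_attributes,
    n_core = nrow(x$core),
    n_reduct = length(x$reduct),
    nrh_full = x$nrh_full,
    nrh_reduct = x$nrh_reduct,
    reduction_rate = reduction_rate(x$n_attributes, length(x$reduct))
  )
}

#' @describeIn arnrje NRH trajectory along the greedy path.
#' @param object A `reduct_trace`.
#' @method autoplot reduct_trace
#' @export
autoplot.reduct_trace <- function(object, ...) {
  steps <- dplyr::bind_rows(
    tibble::tibble(step = 0L, attribute = "core", nrh = object$nrh_core),
    tibble::tibble(step = seq_len(nrow(object$additions)),
                   attribute = object$additions$attribute,
                   nrh = object$additions$nrh)
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$step, y = .data$nrh)) +
    ggplot2::geom_hline(yintercept = object$nrh_full, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "greedy step", y = "NRH (bits)",
                  title = "NRH trajectory of the greedy reduct search",
                  subtitle = paste0("dashed: NRH of the full attribute set; delta = ",
                                    object$delta)) +
    ggplot2::theme_minimal()
}

#' Reduct checkers
#'
#' Three predicate views of what it means for a subset `B` to be a reduct of
#' the full attribute set `C` relative to the decision:
#'
#' * `is_nrh_reduct()`: `NRH(D,B) = NRH(D,C)` within `epsilon` and every
#'   member's removal drops NRH by more than `epsilon` (the joint
#'   algebra/information view).
#' * `is_positive_region_reduct()`: the positive region cardinality is
#'   preserved and every member's removal shrinks it (algebra view).
#' * `is_entropy_gain_reduct()`: the joint entropy with the decision is
#'   preserved within `epsilon` and every member's removal lowers it
#'   (information view).
#'
#' Every NRH reduct is a positive-region reduct, and NRH reducts coincide
#' with entropy-gain reducts; the package's test suite exercises both claims
#' by exhaustive subset enumeration.
#'
#' @param data A decision table or data frame.
#' @param attributes The candidate subset `B` (names or indices).
#' @param delta Neighborhood radius in `[0, 1]`.
#' @param epsilon Equality tolerance (default `1e-10`).
#' @param decision Decision column name.
#' @return A single logical.
#' @export
is_nrh_reduct <- function(data, attributes, delta, epsilon = 1e-10,
                          decision = NULL) {
  ctx <- dt_context(data, decision)
  B <- resolve_attrs(ctx, attributes)
  full <- seq_len(ctx$m)
  nrh_B <- nrh(data, B, delta, decision)
  if (abs(nrh_B - nrh(data, full, delta, decision)) > epsilon) return(FALSE)
  for (a in B) {
    if (nrh(data, setdiff(B, a), delta, decision) >= nrh_B - epsilon) return(FALSE)
  }
  TRUE
}

#' @rdname is_nrh_reduct
#' @export
is_positive_region_reduct <- function(data, attributes, delta, decision = NULL) {
  ctx <- dt_context(data, decision)
  B <- resolve_attrs(ctx, attributes)
  full <- seq_len(ctx$m)
  pos_B <- length(positive_region(data, B, delta, decision))
  if (pos_B != length(positive_region(data, full, delta, decision))) return(FALSE)
  for (a in B) {
    if (length(positive_region(data, setdiff(B, a), delta, decision)) >= pos_B) {
      return(FALSE)
    }
  }
  TRUE
}

#' @rdname is_nrh_reduct
#' @export
is_entropy_gain_reduct <- function(data, attributes, delta, epsilon = 1e-10,
                                   decision = NULL) {
  ctx <- dt_context(data, decision)
  B <- resolve_attrs(ctx, attributes)
  full <- seq_len(ctx$m)
  H_B <- joint_entropy(data, B, delta, decision)
  if (abs(H_B - joint_entropy(data, full, delta, decision)) > epsilon) return(FALSE)
  for (a in B) {
    if (joint_entropy(data, setdiff(B, a), delta, decision) >= H_B - epsilon) {
      return(FALSE)
    }
  }
  TRUE
}
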