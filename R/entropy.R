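#' Per-sample neighborhood entropy
#'
#' `-log2(m(n_B(x_i)) / m(U))` in bits, where `m` is the counting measure.
#' Always in `[0, log2 n]` since every neighborhood contains its own sample.
#'
#' @param model A [neighborhoods()] model.
#' @param i Sample index (default: all samples).
#' @return Numeric vector of entropies, one per requested sample.
#' @export
neighborhood_entropy <- function(model, i = seq_len(model$n)) {
  stopifnot(inherits(model, "neighborhood_model"))
  stopifnot(all(i >= 1L), all(i <= model$n))
  -log2(lengths(model$neighbors[i]) / model$n)
}

#' Mean neighborhood entropy of the sample set
#'
#' Average of the per-sample neighborhood entropies: the uncertainty of the
#' granulation induced by attribute subset `B` at radius `delta`.
#'
#' @param model A [neighborhoods()] model.
#' @return A single number in bits.
#' @export
mean_neighborhood_entropy <- function(model) {
  mean(neighborhood_entropy(model))
}

#' Joint entropy of an attribute subset and the decision
#'
#' `-(1/n) sum_i log2(m(n_B(x_i) intersect [x_i]_d) / n)` where `[x_i]_d` is
#' the decision class containing sample `i`. Finite always: the intersection
#' contains at least the sample itself.
#'
#' @param data A decision table or data frame.
#' @param attributes Attribute subset (default all).
#' @param delta Neighborhood radius in `[0, 1]`.
#' @param decision Decision column name.
#' @param model Optional precomputed [neighborhoods()] model.
#' @return A single number in bits.
#' @export
joint_entropy <- function(data, attributes = NULL, delta, decision = NULL,
                          model = NULL) {
  ctx <- dt_context(data, decision)
  if (is.null(model)) model <- neighborhoods(data, attributes, delta, decision)
  class_of <- integer(ctx$n)
  for (j in seq_along(ctx$classes)) class_of[ctx$classes[[j]]] <- j
  terms <- vapply(seq_len(ctx$n), function(i) {
    dj <- ctx$classes[[class_of[i]]]
    log2(sum(model$neighbors[[i]] %in% dj) / ctx$n)
  }, numeric(1))
  -mean(terms)
}

#' Neighborhood roughness joint entropy (NRH)
#'
#' The package's central uncertainty measure. For each decision class `d_j`
#' it weights a joint-entropy term (information view) by `log2(2 - gamma_j)`
#' where `gamma_j` is the class roughness (algebra view):
#'
#' `NRH(d, B) = -(1/n) sum_j log2(2 - gamma_j) * sum_{i in d_j} log2(m(n_B(x_i) intersect d_j) / n)`
#'
#' The inner sum runs over the members of class `d_j`, so every term is
#' finite (each sample belongs to its own neighborhood). NRH is nonnegative
#' and monotonically non-decreasing as attributes are added, which is what
#' makes greedy forward selection well-behaved. For the empty subset the
#' all-samples neighborhood convention gives `NRH = 0` whenever there are at
#' least two classes.
#'
#' @inheritParams joint_entropy
#' @return A single nonnegative number in bits.
#' @examples
#' dt <- simulate_decision_table(12, 2, seed = 4)
#' nrh(dt, delta = 0.2)
#' @export
nrh <- function(data, attributes = NULL, delta, decision = NULL, model = NULL) {
  ctx <- dt_context(data, decision)
  if (is.null(model)) model <- neighborhoods(data, attributes, delta, decision)
  ap <- class_approximations(data, attributes, delta, decision, model = model)
  total <- 0
  for (j in seq_along(ctx$classes)) {
    dj <- ctx$classes[[j]]
    inner <- sum(vapply(dj, function(i) {
      log2(sum(model$neighbors[[i]] %in% dj) / ctx$n)
    }, numeric(1)))
    total <- total + log2(2 - ap$roughness[j]) * inner
  }
  val <- -total / ctx$n
  # clamp tiny negative round-off; NRH >= 0 analytically
  if (val < 0 && val > -1e-12) val <- 0
  val
}

#' Entropy profile of an attribute subset
#'
#' One-row tibble collecting the entropy family for a subset at a radius:
#' per-sample entropies (list column), their mean, the joint entropy with the
#' decision, and NRH.
#'
#' @inheritParams joint_entropy
#' @return A one-row tibble: `subset` (list), `delta`, `per_sample` (list),
#'   `mean_entropy`, `joint_entropy`, `nrh`.
#' @export
entropy_profile <- function(data, attributes = NULL, delta, decision = NULL) {
  ctx <- dt_context(data, decision)
  B <- resolve_attrs(ctx, attributes)
  model <- neighborhoods(data, B, delta, decision)
  tibble::tibble(
    subset = list(ctx$attrs[B]),
    delta = delta,
    per_sample = list(neighborhood_entropy(model)),
    mean_entropy = mean_neighborhood_entropy(model),
    joint_entropy = joint_entropy(data, B, delta, decision, model = model),
    nrh = nrh(data, B, delta, decision, model = model)
  )
}

#' Internal attribute significance
#'
#' `sig_inner(a, B) = NRH(D, B) - NRH(D, B - {a})`: the NRH lost by removing
#' `a` from `B`. Nonnegative by monotonicity of NRH.
#'
#' @param data A decision table or data frame.
#' @param a A single attribute (name or index), member of `B`.
#' @param attributes The subset `B` containing `a` (default: all attributes).
#' @param delta Neighborhood radius.
#' @param decision Decision column name.
#' @return A single nonnegative number in bits.
#' @export
sig_inner <- function(data, a, attributes = NULL, delta, decision = NULL) {
  ctx <- dt_context(data, decision)
  B <- resolve_attrs(ctx, attributes)
  ai <- resolve_attrs(ctx, a)
  if (length(ai) != 1L) stop("'a' must be a single attribute", call. = FALSE)
  if (!ai %in% B) stop("attribute '", ctx$attrs[ai], "' is not in the subset", call. = FALSE)
  nrh(data, B, delta, decision) - nrh(data, setdiff(B, ai), delta, decision)
}

#' External attribute significance
#'
#' `sig_outer(a, B) = NRH(D, B + {a}) - NRH(D, B)`: the NRH gained by adding
#' the candidate `a` to `B`. Nonnegative by monotonicity of NRH.
#'
#' @inheritParams sig_inner
#' @param attributes The subset `B` not containing `a`. May be empty
#'   (`character(0)`), the greedy start.
#' @return A single nonnegative number in bits.
#' @export
sig_outer <- function(data, a, attributes, delta, decision = NULL) {
  ctx <- dt_context(data, decision)
  B <- resolve_attrs(ctx, attributes)
  ai <- resolve_attrs(ctx, a)
  if (length(ai) != 1L) stop("'a' must be a single attribute", call. = FALSE)
  if (ai %in% B) stop("attribute '", ctx$attrs[ai], "' is already in the subset", call. = FALSE)
  nrh(data, c(B, ai), delta, decision) - nrh(data, B, delta, decision)
}
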